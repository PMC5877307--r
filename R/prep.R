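#' Cut an accelerometer stream into fixed 3-second windows
#'
#' Non-overlapping, consecutive windows; a trailing partial window is
#' dropped rather than padded. Timestamps must be uniform: a gap larger
#' than 1.5 sample periods is a hard error.
#'
#' @param stream an [accel_stream()].
#' @param window_s window length in seconds (default 3).
#' @return A list of `accel_window` objects, each with `samples`
#'   (n x 3 matrix), `start_time_s` and `rate_hz`.
#' @export
window_accel <- function(stream, window_s = 3) {
  check_uniform(stream$time_s, stream$rate_hz, "window_accel")
  wlen <- round(window_s * stream$rate_hz)
  n <- length(stream$time_s)
  n_win <- n %/% wlen
  if (n_win == 0L) return(list())
  m <- accel_matrix(stream)
  lapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * wlen + 1):(i * wlen)
    structure(list(samples = m[idx, , drop = FALSE],
                   start_time_s = stream$time_s[idx[1]],
                   rate_hz = stream$rate_hz),
              class = "accel_window")
  })
}

check_uniform <- function(time_s, rate_hz, who) {
  if (length(time_s) > 1L) {
    gaps <- diff(time_s)
    if (any(gaps > 1.5 / rate_hz) || any(gaps <= 0))
      abort(sprintf("%s: non-uniform timestamps (gap beyond 1.5 sample periods at index %d)",
                    who, which(gaps > 1.5 / rate_hz | gaps <= 0)[1]))
  }
  invisible(TRUE)
}

#' Cut an audio stream into fixed 8-second segments
#'
#' @param stream an [audio_stream()].
#' @param segment_s segment length in seconds (default 8).
#' @return A list of `audio_segment` objects (`samples`, `start_time_s`,
#'   `rate_hz`); trailing partial segments dropped.
#' @export
segment_audio <- function(stream, segment_s = 8) {
  slen <- round(segment_s * stream$rate_hz)
  n <- length(stream$samples)
  n_seg <- n %/% slen
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * slen + 1):(i * slen)
    audio_segment(stream$samples[idx],
                  stream$start_time_s + (idx[1] - 1) / stream$rate_hz,
                  stream$rate_hz)
  })
}

audio_segment <- function(samples, start_time_s, rate_hz) {
  structure(list(samples = samples, start_time_s = start_time_s,
                 rate_hz = rate_hz),
            class = "audio_segment")
}

#' Estimate gravity over a window
#'
#' The static (gravity) component is estimated as the per-axis mean of
#' the window — adequate over 3 s because body motion averages out while
#' the orientation is effectively constant. A gravity magnitude below
#' 1 m/s^2 (free fall, or a corrupt window) is physically implausible and
#' raises a classed warning; the estimate is still returned.
#'
#' @param w an `accel_window` from [window_accel()].
#' @return Numeric 3-vector, the estimated gravity (m/s^2).
#' @export
estimate_gravity <- function(w) {
  if (!nrow(w$samples)) abort("estimate_gravity: zero-length window")
  g <- colMeans(w$samples)
  if (sqrt(sum(g^2)) < 1)
    warn(sprintf("estimate_gravity: |g| = %.3f m/s^2 is implausibly small",
                 sqrt(sum(g^2))))
  unname(g)
}

#' Decompose a window into vertical and horizontal dynamic components
#'
#' Orientation correction: subtracting the estimated gravity `g` from
#' each sample leaves the dynamic acceleration `d_t`, which is split into
#' a signed scalar projection onto the gravity direction (vertical) and
#' the magnitude of the remainder (horizontal). Both series are invariant
#' to any fixed rotation of the device, which is what makes features
#' computed on them pose-independent.
#'
#' @param w an `accel_window`.
#' @param g gravity 3-vector with `|g| >= 1` m/s^2 (see
#'   [estimate_gravity()]).
#' @return A `decomposed_window`: list with `vertical` (signed, m/s^2),
#'   `horizontal` (non-negative magnitudes, m/s^2) and `gravity`.
#' @export
decompose_dynamic <- function(w, g) {
  gn <- sqrt(sum(g^2))
  if (gn < 1)
    abort("decompose_dynamic: |g| < 1 m/s^2 - decomposition unstable")
  ghat <- g / gn
  d <- sweep(w$samples, 2, g)
  vertical <- as.numeric(d %*% ghat)
  resid <- d - outer(vertical, ghat)
  horizontal <- sqrt(rowSums(resid^2))
  structure(list(vertical = vertical, horizontal = horizontal, gravity = g),
            class = "decomposed_window")
}

#' Trim the edges of every contiguous same-label run
#'
#' Instances recorded at the start and end of an annotated context tend
#' not to represent the class (the participant is transitioning), so the
#' first and last `n_trim` instances of every run are discarded; runs of
#' length `<= 2 * n_trim` are removed entirely.
#'
#' @param labels character vector of instance labels, grouped into
#'   contiguous runs.
#' @param n_trim number of instances to drop from each run edge
#'   (default 2).
#' @return Logical keep-mask of `length(labels)`.
#' @export
trim_context_edges <- function(labels, n_trim = 2) {
  if (!is_count(n_trim)) abort("trim_context_edges: n_trim must be >= 0")
  keep <- logical(length(labels))
  if (!length(labels)) return(keep)
  r <- rle(labels)
  stop_idx <- cumsum(r$lengths)
  start_idx <- stop_idx - r$lengths + 1
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] > 2 * n_trim)
      keep[(start_idx[i] + n_trim):(stop_idx[i] - n_trim)] <- TRUE
  }
  keep
}
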