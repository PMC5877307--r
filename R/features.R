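#' Motion features of a decomposed window
#'
#' Mean (central tendency), population standard deviation (spread) and
#' energy (mean of squares) of the vertical and horizontal dynamic
#' series — six values per 3-s window. These cheap time-domain features
#' are enough to separate still from active because walking concentrates
#' energy in the vertical component.
#'
#' @param d a `decomposed_window` from [decompose_dynamic()].
#' @return Named numeric vector
#'   `(mean_v, sd_v, energy_v, mean_h, sd_h, energy_h)`; units m/s^2 for
#'   means/sds, (m/s^2)^2 for energies.
#' @export
motion_features <- function(d) {
  if (!length(d$vertical)) abort("motion_features: empty series")
  mom <- function(x) {
    m <- mean(x)
    c(mean = m, sd = sqrt(mean((x - m)^2)), energy = mean(x^2))
  }
  v <- mom(d$vertical); h <- mom(d$horizontal)
  c(mean_v = v[["mean"]], sd_v = v[["sd"]], energy_v = v[["energy"]],
    mean_h = h[["mean"]], sd_h = h[["sd"]], energy_h = h[["energy"]])
}

#' MFCC configuration
#'
#' Frame/filterbank parameters of the MFCC pipeline. The values follow
#' common speech-processing practice (25-ms frames at a 10-ms hop,
#' pre-emphasis 0.97, 26 mel filters, 13 retained coefficients excluding
#' the 0th) and are all overridable.
#'
#' @param frame_ms analysis frame length (ms).
#' @param hop_ms frame hop (ms); must satisfy `0 < hop_ms <= frame_ms`.
#' @param preemphasis pre-emphasis coefficient in `[0, 1)`.
#' @param n_mel_filters number of triangular mel filters.
#' @param n_coeffs number of DCT coefficients kept (indices
#'   `1..n_coeffs`, the 0th — overall log-energy — is excluded).
#' @param fmin_hz,fmax_hz filterbank frequency range; `fmax_hz = NULL`
#'   means the Nyquist frequency of the segment.
#' @param log_floor floor applied to filterbank outputs before the log,
#'   guarding silence.
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_ms = 25, hop_ms = 10, preemphasis = 0.97,
                        n_mel_filters = 26, n_coeffs = 13, fmin_hz = 0,
                        fmax_hz = NULL, log_floor = 1e-10) {
  if (hop_ms <= 0 || hop_ms > frame_ms)
    abort("mfcc_config: require 0 < hop_ms <= frame_ms")
  if (preemphasis < 0 || preemphasis >= 1)
    abort("mfcc_config: preemphasis must be in [0, 1)")
  if (n_coeffs > n_mel_filters)
    abort("mfcc_config: n_coeffs must not exceed n_mel_filters")
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms,
                 preemphasis = preemphasis, n_mel_filters = n_mel_filters,
                 n_coeffs = n_coeffs, fmin_hz = fmin_hz, fmax_hz = fmax_hz,
                 log_floor = log_floor),
            class = "mfcc_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, unit peak, evaluated at FFT bin centre
# frequencies. Returns an n_filters x n_bins matrix.
mel_filterbank <- function(n_filters, n_bins, nfft, rate_hz, fmin, fmax) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_f <- (seq_len(n_bins) - 1) * rate_hz / nfft
  fb <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_f - lo) / (mid - lo)
    down <- (hi - bin_f) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_keep + 1 rows including the 0th, x N).
dct2_matrix <- function(n_rows, N) {
  k <- 0:(n_rows - 1)
  M <- sqrt(2 / N) * cos(pi * outer(k, (0:(N - 1)) + 0.5) / N)
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' MFCC frame matrix of an audio segment
#'
#' Per frame: pre-emphasis, Hamming window, magnitude-squared FFT (next
#' power-of-two size), triangular mel filterbank with unit-peak filters
#' equally spaced on the mel scale `mel(f) = 2595 log10(1 + f/700)`,
#' natural log with a silence floor, orthonormal DCT-II, keeping
#' coefficients `1..n_coeffs`.
#'
#' @param seg an `audio_segment` from [segment_audio()] (or any list
#'   with `samples` and `rate_hz`).
#' @param cfg an [mfcc_config()].
#' @return Numeric matrix, `n_frames x n_coeffs`, where
#'   `n_frames = floor((length - frame) / hop) + 1`.
#' @export
mfcc_frames <- function(seg, cfg = mfcc_config()) {
  x <- seg$samples
  rate <- seg$rate_hz
  flen <- round(cfg$frame_ms * rate / 1000)
  hop <- round(cfg$hop_ms * rate / 1000)
  if (length(x) < flen)
    abort("mfcc_frames: segment shorter than one frame")
  y <- x - cfg$preemphasis * c(0, x[-length(x)])
  n_frames <- (length(y) - flen) %/% hop + 1
  starts <- (seq_len(n_frames) - 1) * hop
  frames <- matrix(y[rep(starts, each = flen) + seq_len(flen)],
                   nrow = flen)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  frames <- frames * ham
  nfft <- 2^ceiling(log2(flen))
  n_bins <- nfft %/% 2 + 1
  padded <- rbind(frames, matrix(0, nfft - flen, n_frames))
  spec <- stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE]
  power <- Mod(spec)^2  # n_bins x n_frames
  fmax <- if (is.null(cfg$fmax_hz)) rate / 2 else cfg$fmax_hz
  fb <- mel_filterbank(cfg$n_mel_filters, n_bins, nfft, rate,
                       cfg$fmin_hz, fmax)
  loge <- log(pmax(fb %*% power, cfg$log_floor))  # n_filters x n_frames
  D <- dct2_matrix(cfg$n_coeffs + 1, cfg$n_mel_filters)
  cc <- D[-1, , drop = FALSE] %*% loge  # drop the 0th coefficient
  t(cc)
}

#' Aggregate MFCC frames into one audio feature vector
#'
#' Per-coefficient mean and population standard deviation across all
#' frames of a segment, concatenated (means first): 26 values for the
#' default 13 coefficients. The aggregation compresses an 8-s segment
#' into a fixed-length descriptor for the k-NN stage.
#'
#' @inheritParams mfcc_frames
#' @return Named numeric vector of length `2 * n_coeffs`.
#' @export
audio_features <- function(seg, cfg = mfcc_config()) {
  M <- mfcc_frames(seg, cfg)
  if (nrow(M) < 2) abort("audio_features: need at least 2 frames")
  mu <- colMeans(M)
  sdv <- sqrt(colMeans(sweep(M, 2, mu)^2))
  stats::setNames(c(mu, sdv),
                  c(paste0("mfcc_mean_", seq_len(ncol(M))),
                    paste0("mfcc_sd_", seq_len(ncol(M)))))
}
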