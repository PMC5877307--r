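#' Raw sensor stream containers
#'
#' An `accel_stream` holds uniformly sampled tri-axial acceleration in
#' m/s^2; an `audio_stream` holds mono audio amplitudes in `[-1, 1]`.
#' Both are plain lists so they serialise to the package's text formats
#' without loss.
#'
#' @param time_s numeric vector of sample timestamps (seconds).
#' @param ax,ay,az numeric vectors of per-axis acceleration (m/s^2).
#' @param rate_hz sampling rate (Hz).
#' @return An object of class `accel_stream` with fields `time_s`, `ax`,
#'   `ay`, `az`, `rate_hz`.
#' @export
accel_stream <- function(time_s, ax, ay, az, rate_hz) {
  n <- length(time_s)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    abort("accel_stream: time_s, ax, ay, az must have equal length")
  if (!is_scalar_num(rate_hz) || rate_hz <= 0)
    abort("accel_stream: rate_hz must be a positive scalar")
  structure(
    list(time_s = as.numeric(time_s), ax = as.numeric(ax),
         ay = as.numeric(ay), az = as.numeric(az), rate_hz = rate_hz),
    class = "accel_stream"
  )
}

#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @rdname accel_stream
#' @return For `audio_stream`: an object of class `audio_stream` with
#'   fields `samples`, `rate_hz`, `start_time_s`.
#' @param start_time_s time of the first sample (seconds).
#' @export
audio_stream <- function(samples, rate_hz, start_time_s = 0) {
  if (!is_scalar_num(rate_hz) || rate_hz <= 0)
    abort("audio_stream: rate_hz must be a positive scalar")
  structure(
    list(samples = as.numeric(samples), rate_hz = rate_hz,
         start_time_s = start_time_s),
    class = "audio_stream"
  )
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream: %d samples @ %g Hz, %.1f s>\n",
              length(x$time_s), x$rate_hz, length(x$time_s) / x$rate_hz))
  invisible(x)
}

#' @export
print.audio_stream <- function(x, ...) {
  cat(sprintf("<audio_stream: %d samples @ %g Hz, %.1f s>\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz))
  invisible(x)
}

stream_duration_s <- function(x) {
  if (inherits(x, "accel_stream")) length(x$time_s) / x$rate_hz
  else length(x$samples) / x$rate_hz
}

# Matrix view (n x 3) of an accel stream or window sample block.
accel_matrix <- function(s) cbind(ax = s$ax, ay = s$ay, az = s$az)
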