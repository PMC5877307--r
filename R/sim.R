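#' Simulator configuration
#'
#' Parameters of the synthetic sensor generator. Defaults emulate a phone
#' on a seated user: gravity plus low sensor noise when still, plus a
#' gait-like oscillation when active; three spectrally distinct audio
#' surrogates stand in for TV sound, PC office work and ambient
#' environments.
#'
#' @param accel_rate_hz accelerometer sampling rate (Hz, default 50).
#' @param audio_rate_hz audio sampling rate (Hz, default 16000).
#' @param gravity_mps2 gravity magnitude (m/s^2, default 9.81).
#' @param still_noise_sd per-axis Gaussian sensor noise while still
#'   (m/s^2, default 0.05).
#' @param active_freq_hz gait oscillation frequency (Hz, default 2).
#' @param active_amp_mps2 vertical oscillation amplitude while active
#'   (m/s^2, default 2). Must exceed `3 * still_noise_sd` so the two
#'   motion classes are separable.
#' @param pc_click_rate_hz Poisson rate of keyboard/mouse click impulses
#'   in the PC surrogate (1/s, default 3).
#' @param pc_hum_rms RMS of the broadband hum floor under the clicks
#'   (default 0.01).
#' @param tv_band_hz passband of the TV (speech-band) surrogate
#'   (Hz, default `c(300, 3400)`).
#' @param unknown_noise_sd amplitude sd of the ambient white-noise
#'   surrogate (default 0.05).
#' @param seed integer seed; identical configurations (seed included)
#'   produce bit-identical streams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(accel_rate_hz = 50, audio_rate_hz = 16000,
                       gravity_mps2 = 9.81, still_noise_sd = 0.05,
                       active_freq_hz = 2.0, active_amp_mps2 = 2.0,
                       pc_click_rate_hz = 3, pc_hum_rms = 0.01,
                       tv_band_hz = c(300, 3400), unknown_noise_sd = 0.05,
                       seed = 1L) {
  cfg <- list(accel_rate_hz = accel_rate_hz, audio_rate_hz = audio_rate_hz,
              gravity_mps2 = gravity_mps2, still_noise_sd = still_noise_sd,
              active_freq_hz = active_freq_hz,
              active_amp_mps2 = active_amp_mps2,
              pc_click_rate_hz = pc_click_rate_hz, pc_hum_rms = pc_hum_rms,
              tv_band_hz = tv_band_hz, unknown_noise_sd = unknown_noise_sd,
              seed = as.integer(seed))
  if (cfg$accel_rate_hz <= 0 || cfg$audio_rate_hz <= 0)
    abort("sim_config: sampling rates must be > 0")
  if (cfg$still_noise_sd < 0)
    abort("sim_config: still_noise_sd must be >= 0")
  if (cfg$active_amp_mps2 <= 3 * cfg$still_noise_sd)
    abort("sim_config: active_amp_mps2 must exceed 3 * still_noise_sd")
  if (cfg$pc_click_rate_hz < 0)
    abort("sim_config: pc_click_rate_hz must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulation schedule
#'
#' An ordered sequence of contexts and durations describing a simulated
#' recording, e.g. ten minutes of walking followed by an hour at a PC.
#'
#' @param label character vector of context labels, each one of
#'   `"active"`, `"still_tv"`, `"still_pc"`, `"still_unknown"`.
#' @param duration_s positive numeric vector of segment durations (s).
#' @return A `data.frame` of class `sim_schedule` with columns `label`
#'   and `duration_s`.
#' @export
sim_schedule <- function(label, duration_s) {
  ok <- c("active", "still_tv", "still_pc", "still_unknown")
  if (length(label) == 0L) abort("sim_schedule: schedule must be non-empty")
  if (length(label) != length(duration_s))
    abort("sim_schedule: label and duration_s lengths differ")
  if (!all(label %in% ok))
    abort(sprintf("sim_schedule: unknown label(s): %s",
                  paste(setdiff(label, ok), collapse = ", ")))
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    abort("sim_schedule: durations must be positive")
  structure(data.frame(label = label, duration_s = as.numeric(duration_s),
                       stringsAsFactors = FALSE),
            class = c("sim_schedule", "data.frame"))
}

# Random unit 3-vector (uniform on the sphere), from the current RNG.
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# A unit vector orthogonal to u.
orthogonal_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  h <- a - sum(a * u) * u
  h / sqrt(sum(h^2))
}

#' Simulate an accelerometer stream
#'
#' Generates a tri-axial acceleration stream for a single motion context.
#' The phone's orientation (the direction gravity points in device
#' coordinates) is drawn at random per recording, so downstream code must
#' rely on the orientation correction rather than a fixed pose. `still` is
#' gravity plus Gaussian noise; `active` adds a sinusoid of
#' `active_freq_hz` along the gravity axis (amplitude `active_amp_mps2`)
#' and a quadrature half-amplitude horizontal component.
#'
#' @param label `"still"` or `"active"`.
#' @param duration_s duration in seconds (>= 3, one motion window).
#' @param cfg a [sim_config()].
#' @param seed seed for this recording; defaults to `cfg$seed`.
#' @param orientation optional unit 3-vector for the gravity direction;
#'   drawn at random when `NULL`.
#' @return An [accel_stream()] with attribute `gravity_dir`.
#' @export
simulate_accel <- function(label, duration_s, cfg = sim_config(),
                           seed = cfg$seed, orientation = NULL) {
  if (!label %in% c("still", "active"))
    abort(sprintf("simulate_accel: unknown motion label '%s'", label))
  if (duration_s < 3)
    abort("simulate_accel: duration_s must cover at least one 3-s window")
  with_seed(seed, {
    u <- if (is.null(orientation)) random_unit_vector()
         else orientation / sqrt(sum(orientation^2))
    n <- round(duration_s * cfg$accel_rate_hz)
    t <- (seq_len(n) - 1) / cfg$accel_rate_hz
    a <- matrix(cfg$gravity_mps2 * rep(u, each = n), ncol = 3)
    if (label == "active") {
      h <- orthogonal_unit(u)
      osc_v <- cfg$active_amp_mps2 * sin(2 * pi * cfg$active_freq_hz * t)
      osc_h <- (cfg$active_amp_mps2 / 2) *
        sin(2 * pi * cfg$active_freq_hz * t + pi / 2)
      a <- a + outer(osc_v, u) + outer(osc_h, h)
    }
    if (cfg$still_noise_sd > 0)
      a <- a + matrix(stats::rnorm(3 * n, sd = cfg$still_noise_sd), ncol = 3)
    out <- accel_stream(t, a[, 1], a[, 2], a[, 3], cfg$accel_rate_hz)
    attr(out, "gravity_dir") <- u
    out
  })
}

# FFT brick-wall bandpass of a real signal (band in Hz), applied in
# power-of-two chunks: long recordings would otherwise force a single
# slow mixed-radix transform over tens of millions of samples.
fft_bandpass <- function(x, rate_hz, band, chunk = 2^21) {
  n <- length(x)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    m <- j - i + 1L
    X <- stats::fft(x[i:j])
    f <- (seq_len(m) - 1) * (rate_hz / m)
    f <- pmin(f, rate_hz - f)  # fold to [0, rate/2]
    X[f < band[1] | f > band[2]] <- 0i
    out[i:j] <- Re(stats::fft(X, inverse = TRUE)) / m
    i <- j + 1L
  }
  out
}

#' Simulate an audio stream
#'
#' Parametric surrogates for the three micro-context sound environments:
#' `tv` is slowly amplitude-modulated noise band-limited to the speech
#' band; `pc` is sparse click impulses (Poisson arrivals) over a
#' low-level broadband hum; `unknown` is low-amplitude white noise.
#' Output amplitude is normalised to peak at most 1 (scaled only when the
#' peak exceeds 1).
#'
#' @param label `"tv"`, `"pc"` or `"unknown"`.
#' @param duration_s duration in seconds (>= 8, one audio segment).
#' @param cfg a [sim_config()].
#' @param seed seed for this recording; defaults to `cfg$seed`.
#' @return An [audio_stream()].
#' @export
simulate_audio <- function(label, duration_s, cfg = sim_config(),
                           seed = cfg$seed) {
  if (!label %in% c("tv", "pc", "unknown"))
    abort(sprintf("simulate_audio: unknown micro-context label '%s'", label))
  if (duration_s < 8)
    abort("simulate_audio: duration_s must cover at least one 8-s segment")
  with_seed(seed, {
    rate <- cfg$audio_rate_hz
    n <- round(duration_s * rate)
    t <- (seq_len(n) - 1) / rate
    x <- switch(label,
      tv = {
        carrier <- fft_bandpass(stats::rnorm(n), rate, cfg$tv_band_hz)
        env <- 1 + 0.6 * sin(2 * pi * 0.7 * t)  # slow loudness modulation
        y <- carrier * env
        0.25 * y / sqrt(mean(y^2))
      },
      pc = {
        hum <- stats::rnorm(n, sd = cfg$pc_hum_rms)
        y <- hum
        n_clicks <- stats::rpois(1, cfg$pc_click_rate_hz * duration_s)
        if (n_clicks > 0) {
          kl <- round(0.005 * rate)  # 5-ms decaying click kernel
          kt <- (seq_len(kl) - 1) / rate
          kernel <- exp(-kt / 0.001) * cos(2 * pi * 4500 * kt)
          starts <- sort(sample.int(n - kl, n_clicks, replace = TRUE))
          amps <- stats::runif(n_clicks, 0.4, 0.9)
          for (i in seq_len(n_clicks)) {
            idx <- starts[i]:(starts[i] + kl - 1)
            y[idx] <- y[idx] + amps[i] * kernel
          }
        }
        y
      },
      unknown = stats::rnorm(n, sd = cfg$unknown_noise_sd)
    )
    peak <- max(abs(x))
    if (peak > 1) x <- x / peak
    audio_stream(x, rate)
  })
}

#' Simulate a full day of labelled sensor data
#'
#' Runs the accelerometer and audio simulators segment by segment over a
#' [sim_schedule()] and concatenates the results, together with a
#' per-minute ground-truth timeline. Audio covers the full duration
#' (active segments get the ambient surrogate); deciding when to listen
#' is the recognition engine's job, not the simulator's. One phone
#' orientation is drawn for the whole recording.
#'
#' @param schedule a [sim_schedule()].
#' @param cfg a [sim_config()]; `cfg$seed` fixes the entire recording.
#' @return A list with `accel` ([accel_stream()]), `audio`
#'   ([audio_stream()]), and `ground_truth`: a data.frame with one row
#'   per whole minute (`minute_start_s`, `motion`, `micro`), where
#'   `micro` is `"none"` for active minutes. A minute spanning a segment
#'   boundary takes the label covering most of it (ties to the later
#'   segment).
#' @export
simulate_day <- function(schedule, cfg = sim_config()) {
  if (!inherits(schedule, "sim_schedule"))
    schedule <- sim_schedule(schedule$label, schedule$duration_s)
  seg_seeds <- with_seed(cfg$seed, {
    list(orientation = random_unit_vector(),
         accel = sample.int(.Machine$integer.max, nrow(schedule)),
         audio = sample.int(.Machine$integer.max, nrow(schedule)))
  })
  # Fill preallocated buffers segment by segment: a day of 16-kHz audio
  # is ~1e8 samples, so holding per-segment copies alongside the full
  # stream would double the peak memory.
  n_acc <- sum(round(schedule$duration_s * cfg$accel_rate_hz))
  n_aud <- sum(round(schedule$duration_s * cfg$audio_rate_hz))
  acc_m <- matrix(0, n_acc, 3)
  audio_samples <- numeric(n_aud)
  pos_a <- 0L; pos_s <- 0L
  for (i in seq_len(nrow(schedule))) {
    lab <- schedule$label[i]
    dur <- schedule$duration_s[i]
    motion <- if (lab == "active") "active" else "still"
    micro <- if (lab == "active") "unknown" else sub("^still_", "", lab)
    part_a <- simulate_accel(motion, dur, cfg, seed = seg_seeds$accel[i],
                             orientation = seg_seeds$orientation)
    acc_m[pos_a + seq_along(part_a$ax), ] <- accel_matrix(part_a)
    pos_a <- pos_a + length(part_a$ax)
    part_s <- simulate_audio(micro, dur, cfg, seed = seg_seeds$audio[i])
    audio_samples[pos_s + seq_along(part_s$samples)] <- part_s$samples
    pos_s <- pos_s + length(part_s$samples)
  }
  t_all <- (seq_len(n_acc) - 1) / cfg$accel_rate_hz
  accel <- accel_stream(t_all, acc_m[, 1], acc_m[, 2], acc_m[, 3],
                        cfg$accel_rate_hz)
  attr(accel, "gravity_dir") <- seg_seeds$orientation
  audio <- audio_stream(audio_samples, cfg$audio_rate_hz)
  list(accel = accel, audio = audio,
       ground_truth = schedule_ground_truth(schedule))
}

#' Ground-truth epoch timeline implied by a schedule
#'
#' @param schedule a [sim_schedule()].
#' @return data.frame (`minute_start_s`, `motion`, `micro`) with one row
#'   per whole minute of the schedule; trailing partial minutes dropped.
#' @export
schedule_ground_truth <- function(schedule) {
  bounds <- cumsum(c(0, schedule$duration_s))
  total <- bounds[length(bounds)]
  n_min <- floor(total / 60)
  if (n_min == 0L)
    return(data.frame(minute_start_s = numeric(0), motion = character(0),
                      micro = character(0), stringsAsFactors = FALSE))
  lab <- character(n_min)
  for (m in seq_len(n_min)) {
    lo <- (m - 1) * 60; hi <- lo + 60
    overlap <- pmin(hi, bounds[-1]) - pmax(lo, bounds[-length(bounds)])
    overlap[overlap < 0] <- 0
    best <- max(overlap)
    lab[m] <- schedule$label[max(which(overlap == best))]  # tie: later seg
  }
  motion <- ifelse(lab == "active", "active", "still")
  micro <- ifelse(lab == "active", "none", sub("^still_", "", lab))
  data.frame(minute_start_s = 60 * (seq_len(n_min) - 1), motion = motion,
             micro = micro, stringsAsFactors = FALSE)
}
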