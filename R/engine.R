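#' Engine configuration
#'
#' @param recheck_min minutes between audio re-checks while continuously
#'   still (default 15).
#' @param window_s motion window length (s, default 3).
#' @param segment_s audio listening duration (s, default 8).
#' @param k neighbours per k-NN query (default 3).
#' @param tie_motion label assigned when a minute's window vote is an
#'   exact tie (default `"active"`, biasing against over-counting
#'   sedentary time).
#' @param mfcc an [mfcc_config()] for the audio stage.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(recheck_min = 15, window_s = 3, segment_s = 8,
                          k = 3, tie_motion = "active",
                          mfcc = mfcc_config()) {
  if (recheck_min < 1) abort("engine_config: recheck_min must be >= 1")
  if (!tie_motion %in% c("active", "still"))
    abort("engine_config: tie_motion must be 'active' or 'still'")
  structure(list(recheck_min = recheck_min, window_s = window_s,
                 segment_s = segment_s, k = k, tie_motion = tie_motion,
                 mfcc = mfcc),
            class = "engine_config")
}

#' Aggregate window labels into a one-minute motion label
#'
#' Majority vote over the minute's 3-s window labels (normally 20);
#' exact ties resolve to the configured tie label.
#'
#' @param window_labels character vector of `"still"` / `"active"`.
#' @param tie label used on an exact tie (default `"active"`).
#' @return `"still"` or `"active"`.
#' @export
classify_minute_motion <- function(window_labels, tie = "active") {
  if (!length(window_labels))
    abort("classify_minute_motion: no window labels for this minute")
  n_active <- sum(window_labels == "active")
  n_still <- sum(window_labels == "still")
  if (n_active > n_still) "active"
  else if (n_still > n_active) "still"
  else tie
}

new_engine_state <- function() {
  structure(list(last_audio_check_s = NA_real_, carried_micro = NA_character_),
            class = "engine_state")
}

#' Advance the duty-cycled engine by one epoch
#'
#' One-minute step of the recognition state machine. Motion comes from
#' the minute's window votes. An active minute clears the carried
#' micro-context (so the next still minute re-samples immediately). A
#' still minute samples audio only when no check has happened yet or the
#' last check is at least `recheck_min` minutes old — that duty cycle is
#' what keeps the audio sensor (the expensive one) mostly off.
#'
#' @param state an engine state (from [new_engine_state()] or a previous
#'   step).
#' @param minute list with `minute_start_s`, `window_labels`
#'   (still/active per 3-s window), and `audio_segment` (an
#'   `audio_segment` for the first 8 s of the minute, or `NULL` when
#'   unavailable).
#' @param stores list with `motion` and `audio` [training_store()]s.
#' @param cfg an [engine_config()].
#' @return List with `record` (one epoch row: `minute_start_s`, `motion`,
#'   `micro`, `audio_sampled`) and `state`.
#' @export
step_epoch <- function(state, minute, stores, cfg = engine_config()) {
  motion <- classify_minute_motion(minute$window_labels, cfg$tie_motion)
  t0 <- minute$minute_start_s
  if (motion == "active") {
    state$carried_micro <- NA_character_
    state$last_audio_check_s <- NA_real_
    record <- list(minute_start_s = t0, motion = "active", micro = "none",
                   audio_sampled = FALSE)
    return(list(record = record, state = state))
  }
  due <- is.na(state$last_audio_check_s) ||
    (t0 - state$last_audio_check_s) >= cfg$recheck_min * 60
  sampled <- FALSE
  if (due) {
    if (is.null(minute$audio_segment)) {
      warn(sprintf("step_epoch: audio due at t=%gs but unavailable; micro set to 'unknown'", t0))
      micro <- "unknown"
    } else {
      micro <- knn_classify(audio_features(minute$audio_segment, cfg$mfcc),
                            stores$audio, cfg$k)$label
      sampled <- TRUE
      state$carried_micro <- micro
      state$last_audio_check_s <- t0
    }
  } else {
    micro <- state$carried_micro
  }
  record <- list(minute_start_s = t0, motion = "still", micro = micro,
                 audio_sampled = sampled)
  list(record = record, state = state)
}

#' Run the two-stage engine over whole sensor streams
#'
#' Iterates the epoch state machine minute by minute: each minute's
#' accelerometer samples are cut into 3-s windows, orientation-corrected,
#' featurised and classified against the motion store; when the engine
#' decides to listen, the first 8 s of the minute's audio go through the
#' MFCC stage and the audio store. A trailing partial minute is dropped.
#'
#' @param accel an [accel_stream()].
#' @param audio an [audio_stream()] covering the same span (mismatch
#'   beyond one minute is an error).
#' @param stores list with `motion` and `audio` [training_store()]s.
#' @param cfg an [engine_config()].
#' @return An epoch timeline: data.frame with columns `minute_start_s`,
#'   `motion`, `micro`, `audio_sampled`.
#' @export
run_timeline <- function(accel, audio, stores, cfg = engine_config()) {
  dur_a <- stream_duration_s(accel)
  dur_s <- stream_duration_s(audio)
  if (abs(dur_a - dur_s) > 60)
    abort(sprintf("run_timeline: stream spans differ by %.1f s (> 1 min)",
                  abs(dur_a - dur_s)))
  if (is.null(stores$motion))
    abort("run_timeline: no motion training store")
  if (is.null(stores$audio))
    abort("run_timeline: no audio training store; cannot assign micro-contexts")
  n_min <- floor(min(dur_a, dur_s) / 60 + 1e-9)  # guard rate round-off
  arate <- accel$rate_hz
  srate <- audio$rate_hz
  acc_m <- accel_matrix(accel)
  wlen <- round(cfg$window_s * arate)
  per_min <- floor(60 / cfg$window_s)
  seg_len <- round(cfg$segment_s * srate)
  state <- new_engine_state()
  records <- vector("list", n_min)
  for (m in seq_len(n_min)) {
    t0 <- (m - 1) * 60
    base <- round(t0 * arate)
    wl <- vapply(seq_len(per_min), function(w) {
      idx <- (base + (w - 1) * wlen + 1):(base + w * wlen)
      win <- structure(list(samples = acc_m[idx, , drop = FALSE],
                            start_time_s = t0 + (w - 1) * cfg$window_s,
                            rate_hz = arate),
                       class = "accel_window")
      g <- suppressWarnings(estimate_gravity(win))
      knn_classify(motion_features(decompose_dynamic(win, g)),
                   stores$motion, cfg$k)$label
    }, character(1))
    a0 <- round(t0 * srate)
    seg <- if (a0 + seg_len <= length(audio$samples))
      audio_segment(audio$samples[(a0 + 1):(a0 + seg_len)], t0, srate)
    else NULL
    stepped <- step_epoch(state,
                          list(minute_start_s = t0, window_labels = wl,
                               audio_segment = seg),
                          stores, cfg)
    records[[m]] <- stepped$record
    state <- stepped$state
  }
  epoch_timeline(do.call(rbind, lapply(records, as.data.frame)))
}

# Validate + class an epoch timeline data.frame.
epoch_timeline <- function(df) {
  need <- c("minute_start_s", "motion", "micro", "audio_sampled")
  if (!all(need %in% names(df)))
    abort("epoch_timeline: missing columns")
  bad <- (df$motion == "active") != (df$micro == "none")
  if (any(bad))
    abort("epoch_timeline: micro must be 'none' exactly for active epochs")
  if (any(df$audio_sampled & df$motion != "still"))
    abort("epoch_timeline: audio sampled during a non-still epoch")
  df <- df[order(df$minute_start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("epoch_timeline", "data.frame")
  df
}
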