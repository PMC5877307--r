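# Shared fixtures, built once per test run. Small sampling rates keep the
# plumbing tests fast; the acceptance suite exercises the default rates.

fast_sim <- function(seed = 11L, audio_rate_hz = 4000, ...) {
  sim_config(audio_rate_hz = audio_rate_hz, seed = seed, ...)
}

# Construct an epoch timeline from run-length (motion, micro, length)
# triples, e.g. make_tl(c("still", "tv", 15), c("active", "none", 2)).
make_tl <- function(..., start_min = 0) {
  runs <- list(...)
  motion <- unlist(lapply(runs, function(r) rep(r[1], as.integer(r[3]))))
  micro <- unlist(lapply(runs, function(r) rep(r[2], as.integer(r[3]))))
  data.frame(
    minute_start_s = 60 * (start_min + seq_along(motion) - 1),
    motion = motion, micro = micro,
    audio_sampled = FALSE, stringsAsFactors = FALSE)
}

# Tiny trained stores for engine plumbing tests (cached across tests).
tiny_stores <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- fast_sim(seed = 101L)
    eng <- engine_config()
    td <- simulate_training_data(
      cfg, spec = list(motion_s = c(still = 60, active = 60),
                       audio_s = c(tv = 32, pc = 32, unknown = 32)))
    mo <- build_stage_dataset(td$motion$stream, td$motion$annotations,
                              "motion", eng, n_trim = 0)
    au <- build_stage_dataset(td$audio$stream, td$audio$annotations,
                              "audio", eng, n_trim = 0)
    cache <<- list(
      motion = training_store(mo$features, mo$labels, "motion"),
      audio = training_store(au$features, au$labels, "audio"),
      sim = cfg, engine = eng)
    cache
  }
})

# One cached 8-s "unknown" segment at the fast audio rate.
tiny_unknown_segment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- simulate_audio("unknown", 8, fast_sim(seed = 77L))
      cache <<- segment_audio(s)[[1]]
    }
    cache
  }
})
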