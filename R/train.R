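#' Build a labelled feature dataset from an annotated recording
#'
#' Cuts the annotated spans out of a raw stream, windows them
#' (3-s accelerometer windows or 8-s audio segments), optionally trims
#' the first/last instances of every annotated run (transition instances
#' misrepresent their class), and extracts the stage's features.
#'
#' @param stream an [accel_stream()] or [audio_stream()].
#' @param annotations data.frame with `label`, `start_s`, `end_s` (see
#'   [read_annotations_csv()]); labels must belong to the stage.
#' @param stage `"motion"` or `"audio"`.
#' @param cfg an [engine_config()] (window/segment lengths, MFCC config).
#' @param n_trim instances trimmed from each end of every annotated
#'   trial (default 2; 0 disables trimming).
#' @return List with `features` (matrix) and `labels`.
#' @export
build_stage_dataset <- function(stream, annotations, stage,
                                cfg = engine_config(), n_trim = 2) {
  dur <- stream_duration_s(stream)
  if (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9))
    abort("build_stage_dataset: annotation span outside the recording")
  feats <- list(); labs <- character(0)
  for (i in seq_len(nrow(annotations))) {
    lab <- annotations$label[i]
    if (stage == "motion") {
      sub <- slice_accel(stream, annotations$start_s[i], annotations$end_s[i])
      wins <- window_accel(sub, cfg$window_s)
      fv <- lapply(wins, function(w) {
        g <- suppressWarnings(estimate_gravity(w))
        motion_features(decompose_dynamic(w, g))
      })
    } else {
      sub <- slice_audio(stream, annotations$start_s[i], annotations$end_s[i])
      segs <- segment_audio(sub, cfg$segment_s)
      fv <- lapply(segs, audio_features, cfg = cfg$mfcc)
    }
    if (!length(fv)) next
    keep <- trim_context_edges(rep(lab, length(fv)), n_trim)
    feats <- c(feats, fv[keep])
    labs <- c(labs, rep(lab, sum(keep)))
  }
  if (!length(labs))
    abort("build_stage_dataset: no instances survived windowing/trimming")
  list(features = do.call(rbind, feats), labels = labs)
}

slice_accel <- function(stream, start_s, end_s) {
  i0 <- round(start_s * stream$rate_hz) + 1
  i1 <- min(length(stream$time_s), round(end_s * stream$rate_hz))
  accel_stream(stream$time_s[i0:i1], stream$ax[i0:i1], stream$ay[i0:i1],
               stream$az[i0:i1], stream$rate_hz)
}

slice_audio <- function(stream, start_s, end_s) {
  i0 <- round(start_s * stream$rate_hz) + 1
  i1 <- min(length(stream$samples), round(end_s * stream$rate_hz))
  audio_stream(stream$samples[i0:i1], stream$rate_hz, start_s)
}

#' Train both classification stages from annotated recordings
#'
#' Runs the full training protocol for one stage or both: features from
#' annotated spans (edges trimmed), a stratified 60:10:30
#' train/validation/test split, stores built from the training portion,
#' accuracy reported on the held-out test portion. The validation part
#' is reserved (k stays fixed at 3).
#'
#' @param motion list with `stream` (an [accel_stream()]) and
#'   `annotations`, or `NULL` to skip the stage.
#' @param audio list with `stream` (an [audio_stream()]) and
#'   `annotations`, or `NULL` to skip the stage.
#' @param cfg an [engine_config()].
#' @param seed integer seed for the split shuffles.
#' @param n_trim instances trimmed per annotated-run edge (default 2).
#' @return List with `stores` (motion/audio [training_store()]s, `NULL`
#'   where skipped) and `report` (per-stage instance counts, split
#'   sizes, test accuracy and confusion matrix).
#' @export
train_models <- function(motion = NULL, audio = NULL,
                         cfg = engine_config(), seed = 1L, n_trim = 2) {
  train_stage <- function(input, stage) {
    ds <- build_stage_dataset(input$stream, input$annotations, stage,
                              cfg, n_trim)
    sp <- split_dataset(ds$labels, seed = seed)
    store <- training_store(ds$features[sp$train, , drop = FALSE],
                            ds$labels[sp$train], stage)
    ev <- evaluate_store(store, ds$features[sp$test, , drop = FALSE],
                         ds$labels[sp$test], cfg$k)
    list(store = store,
         report = list(n_instances = length(ds$labels),
                       split = lengths(sp), accuracy = ev$accuracy,
                       confusion = ev$confusion))
  }
  out <- list(stores = list(motion = NULL, audio = NULL), report = list())
  if (!is.null(motion)) {
    st <- train_stage(motion, "motion")
    out$stores$motion <- st$store
    out$report$motion <- st$report
  }
  if (!is.null(audio)) {
    st <- train_stage(audio, "audio")
    out$stores$audio <- st$store
    out$report$audio <- st$report
  }
  out
}

# Default training schedule: one annotated trial per context, long
# enough for ~100 motion windows / ~20 audio segments per class.
default_training_spec <- function() {
  list(motion_s = c(still = 300, active = 300),
       audio_s = c(tv = 160, pc = 160, unknown = 160))
}

#' Simulate annotated training recordings
#'
#' Generates one continuous accelerometer recording (still then active)
#' and one audio recording (tv, pc, unknown) with matching annotation
#' tables — the synthetic stand-in for participants miming short
#' annotated trials.
#'
#' @param cfg a [sim_config()]; `cfg$seed` fixes the recordings.
#' @param spec durations per context, as from `default_training_spec()`.
#' @return List with `motion` and `audio`, each a list of `stream` and
#'   `annotations` ready for [train_models()].
#' @export
simulate_training_data <- function(cfg = sim_config(),
                                   spec = default_training_spec()) {
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max, 5))
  m_labs <- names(spec$motion_s)
  m_parts <- lapply(seq_along(m_labs), function(i)
    simulate_accel(m_labs[i], spec$motion_s[i], cfg, seed = seeds[i]))
  acc_m <- do.call(rbind, lapply(m_parts, accel_matrix))
  t_all <- (seq_len(nrow(acc_m)) - 1) / cfg$accel_rate_hz
  m_stream <- accel_stream(t_all, acc_m[, 1], acc_m[, 2], acc_m[, 3],
                           cfg$accel_rate_hz)
  m_bounds <- cumsum(c(0, spec$motion_s))
  m_ann <- data.frame(label = m_labs,
                      start_s = m_bounds[-length(m_bounds)],
                      end_s = m_bounds[-1])
  a_labs <- names(spec$audio_s)
  a_parts <- lapply(seq_along(a_labs), function(i)
    simulate_audio(a_labs[i], spec$audio_s[i], cfg, seed = seeds[2 + i]))
  a_stream <- audio_stream(unlist(lapply(a_parts, `[[`, "samples")),
                           cfg$audio_rate_hz)
  a_bounds <- cumsum(c(0, spec$audio_s))
  a_ann <- data.frame(label = a_labs,
                      start_s = a_bounds[-length(a_bounds)],
                      end_s = a_bounds[-1])
  list(motion = list(stream = m_stream, annotations = m_ann),
       audio = list(stream = a_stream, annotations = a_ann))
}

# Default simulated day: morning commute, desk work with a short break,
# an unlabelled sedentary stretch, and TV in the evening. Two hours
# total — long enough to exercise every context and several audio
# re-checks while keeping a full pipeline run within a desk-scale
# compute budget.
default_day_schedule <- function() {
  sim_schedule(
    c("active", "still_pc", "active", "still_pc", "still_unknown",
      "active", "still_tv"),
    c(10, 40, 3, 15, 15, 7, 30) * 60)
}

#' End-to-end synthetic pipeline
#'
#' Simulate annotated training recordings, train both stages, simulate a
#' scheduled day with an independent seed, run the recognition engine
#' over it, and summarise the behaviour — the full desk-scale smoke test
#' of the framework. All artefacts are written under `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; training and day simulations derive distinct
#'   sub-seeds from it.
#' @param schedule a [sim_schedule()] for the evaluation day.
#' @param sim a [sim_config()] (its seed field is overridden by the
#'   derived sub-seeds).
#' @param engine an [engine_config()].
#' @param breaks a [break_config()].
#' @return List with `stores`, `train_report`, `timeline`,
#'   `ground_truth`, `summary`, `motion_accuracy`, `micro_accuracy` and
#'   the written `paths`.
#' @export
run_pipeline <- function(out_dir = tempfile("sedentr_run_"), seed = 42L,
                         schedule = default_day_schedule(),
                         sim = sim_config(), engine = engine_config(),
                         breaks = break_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub <- with_seed(seed, sample.int(.Machine$integer.max, 2))
  sim_train <- sim; sim_train$seed <- sub[1]
  sim_day <- sim; sim_day$seed <- sub[2]
  td <- simulate_training_data(sim_train)
  trained <- train_models(motion = td$motion, audio = td$audio,
                          cfg = engine, seed = seed)
  day <- simulate_day(schedule, sim_day)
  tl <- run_timeline(day$accel, day$audio, trained$stores, engine)
  summ <- behaviour_summary(tl, breaks)
  gt <- day$ground_truth
  motion_acc <- mean(tl$motion == gt$motion)
  still_idx <- gt$motion == "still"
  micro_acc <- mean(tl$micro[still_idx] == gt$micro[still_idx])
  paths <- list(
    motion_store = file.path(out_dir, "motion_store.json"),
    audio_store = file.path(out_dir, "audio_store.json"),
    timeline = file.path(out_dir, "timeline.jsonl"),
    summary = file.path(out_dir, "summary.json"))
  save_store_json(trained$stores$motion, paths$motion_store)
  save_store_json(trained$stores$audio, paths$audio_store)
  write_timeline_jsonl(tl, paths$timeline)
  write_summary_json(summ, paths$summary,
                     config_echo = list(seed = seed,
                                        recheck_min = engine$recheck_min,
                                        k = engine$k))
  list(stores = trained$stores, train_report = trained$report,
       timeline = tl, ground_truth = gt, summary = summ,
       motion_accuracy = motion_acc, micro_accuracy = micro_acc,
       paths = paths)
}
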