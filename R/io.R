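#' Read and write accelerometer CSV
#'
#' Format: header `time_s,ax,ay,az`, one sample per row, '.' decimal,
#' UTF-8. The sampling rate is recovered from the median timestamp
#' increment on read.
#'
#' @param stream an [accel_stream()].
#' @param path file path.
#' @return `read_accel_csv` returns an [accel_stream()];
#'   `write_accel_csv` returns `path` invisibly.
#' @export
write_accel_csv <- function(stream, path) {
  df <- data.frame(time_s = stream$time_s, ax = stream$ax, ay = stream$ay,
                   az = stream$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("read_accel_csv: no such file: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    abort(sprintf("read_accel_csv: %s: expected columns %s", path,
                  paste(need, collapse = ",")))
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))  # +1 for the header row
      abort(sprintf("read_accel_csv: %s: bad value '%s' in column %s at line %d",
                    path, df[[col]][bad[1]], col, bad[1] + 1L))
    df[[col]] <- v
  }
  rate <- 1 / stats::median(diff(df$time_s))
  # snap to the nearest integer rate: timestamps carry decimal round-off
  if (abs(rate - round(rate)) < 1e-3 * rate) rate <- round(rate)
  accel_stream(df$time_s, df$ax, df$ay, df$az, rate)
}

#' Read and write 16-bit PCM mono WAV
#'
#' Minimal RIFF/WAVE support: one `fmt ` chunk (PCM, mono, 16-bit) and
#' one `data` chunk. Amplitudes are mapped to/from `[-1, 1]` with
#' full-scale 32767.
#'
#' @param stream an [audio_stream()]; samples are clipped to `[-1, 1]`.
#' @param path file path.
#' @return `read_wav` returns an [audio_stream()]; `write_wav` returns
#'   `path` invisibly.
#' @export
write_wav <- function(stream, path) {
  x <- pmin(1, pmax(-1, stream$samples))
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(round(stream$rate_hz))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")    # PCM, mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")   # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    abort(sprintf("read_wav: no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    abort(sprintf("read_wav: %s: not a RIFF file", path))
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    abort(sprintf("read_wav: %s: not a WAVE file", path))
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ab <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]; bits <- ab[2]
      if (fmt[1] != 1L)
        abort(sprintf("read_wav: %s: only PCM supported", path))
      if (size > 16) invisible(readBin(con, raw(), n = size - 16L))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         endian = "little")
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(rate) || is.null(samples))
    abort(sprintf("read_wav: %s: missing fmt or data chunk", path))
  if (channels != 1L || bits != 16L)
    abort(sprintf("read_wav: %s: only 16-bit mono supported", path))
  audio_stream(samples / 32767, rate)
}

#' Read and write epoch timelines as JSONL
#'
#' One JSON object per line: `{"minute_start_s": ..., "motion": ...,
#' "micro": ..., "audio_sampled": ...}`.
#'
#' @param tl an epoch timeline data.frame.
#' @param path file path.
#' @return `read_timeline_jsonl` returns an epoch timeline;
#'   `write_timeline_jsonl` returns `path` invisibly.
#' @export
write_timeline_jsonl <- function(tl, path) {
  lines <- vapply(seq_len(nrow(tl)), function(i)
    as.character(jsonlite::toJSON(as.list(tl[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = I(17))),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_timeline_jsonl
#' @export
read_timeline_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  epoch_timeline(do.call(rbind, rows))
}

#' Serialise and load a training store as JSON
#'
#' `{stage, feature_length, instances: [{features, label}]}`; numeric
#' precision is preserved so a round trip is bit-exact.
#'
#' @param store a [training_store()].
#' @param path file path.
#' @return `load_store_json` returns a [training_store()];
#'   `save_store_json` returns `path` invisibly.
#' @export
save_store_json <- function(store, path) {
  obj <- list(stage = store$stage, feature_length = store$feature_length,
              instances = lapply(seq_len(store$n), function(i)
                list(features = store$features[i, ],
                     label = store$labels[i])))
  # digits = I(17): 17 significant digits round-trip doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_store_json
#' @export
load_store_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  feats <- do.call(rbind, lapply(obj$instances, function(i)
    as.numeric(i$features)))
  labs <- vapply(obj$instances, `[[`, character(1), "label")
  store <- training_store(feats, labs, obj$stage)
  if (store$feature_length != obj$feature_length)
    abort(sprintf("load_store_json: %s: feature_length mismatch", path))
  store
}

#' Read an annotation file
#'
#' CSV with header `label,start_s,end_s`, one annotated trial per row —
#' the machine version of the participants' paper notes of context start
#' and end times.
#'
#' @param path file path.
#' @return data.frame with `label`, `start_s`, `end_s`.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(df)))
    abort(sprintf("read_annotations_csv: %s: expected columns %s", path,
                  paste(need, collapse = ",")))
  if (any(df$end_s <= df$start_s))
    abort(sprintf("read_annotations_csv: %s: end_s must exceed start_s",
                  path))
  df[need]
}

#' Read a schedule file
#'
#' CSV with header `label,duration_s`.
#'
#' @param path file path.
#' @return A [sim_schedule()].
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "duration_s") %in% names(df)))
    abort(sprintf("read_schedule_csv: %s: expected columns label,duration_s",
                  path))
  sim_schedule(df$label, df$duration_s)
}

#' Read a run configuration file
#'
#' JSON file whose top-level keys are `sim`, `mfcc`, `engine`, `breaks`
#' and `seed`; keys inside each block mirror the corresponding config
#' constructor's arguments exactly. Unknown keys are rejected rather
#' than silently ignored.
#'
#' @param path file path (or `NULL` for all defaults).
#' @return List with `sim` ([sim_config()]), `mfcc` ([mfcc_config()]),
#'   `engine` ([engine_config()]), `breaks` ([break_config()]), `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("sim", "mfcc", "engine", "breaks", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    abort(sprintf("read_run_config: unknown key(s): %s",
                  paste(extra, collapse = ", ")))
  build <- function(ctor, args) {
    args <- if (is.null(args)) list() else as.list(args)
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      abort(sprintf("read_run_config: unknown key(s): %s",
                    paste(bad, collapse = ", ")))
    do.call(ctor, args)
  }
  mfcc <- build(mfcc_config, raw$mfcc)
  eng_args <- raw$engine
  eng_args$mfcc <- mfcc
  list(sim = build(sim_config, raw$sim),
       mfcc = mfcc,
       engine = build(engine_config, eng_args),
       breaks = build(break_config, raw$breaks),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Write a behaviour summary as JSON
#'
#' @param summary a [behaviour_summary()].
#' @param path file path.
#' @param config_echo optional configuration list echoed into the output
#'   for provenance.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, config_echo = NULL) {
  obj <- list(hourly = summary$hourly, daily = summary$daily,
              percentages = as.list(summary$percentages),
              short_breaks = summary$short_breaks,
              n_breaks = summary$n_breaks,
              break_minutes = summary$break_minutes,
              n_epochs = summary$n_epochs)
  if (!is.null(config_echo)) obj$config <- config_echo
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
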