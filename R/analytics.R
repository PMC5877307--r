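#' Short-break detection thresholds
#'
#' A short break is a brief bout of activity interrupting prolonged
#' sitting. The concept needs two thresholds: how short the active bout
#' must be to count as a "break" rather than a new activity, and how
#' much surrounding stillness makes the sitting "prolonged".
#'
#' @param max_break_min maximum break length in minutes (default 5).
#' @param min_flank_still_min minimum still minutes required immediately
#'   before and after the break (default 10).
#' @return A list of class `break_config`.
#' @export
break_config <- function(max_break_min = 5, min_flank_still_min = 10) {
  if (max_break_min < 1 || min_flank_still_min < 1)
    abort("break_config: both thresholds must be >= 1")
  structure(list(max_break_min = max_break_min,
                 min_flank_still_min = min_flank_still_min),
            class = "break_config")
}

#' Per-hour minutes by motion context
#'
#' Counts epochs per clock hour by motion label — the data behind an
#' hourly "bubble" view where a full sedentary hour shows still = 60.
#' Hours with no epochs are absent, not zero-filled.
#'
#' @param tl an epoch timeline (from [run_timeline()] or
#'   [read_timeline_jsonl()]).
#' @return data.frame with columns `hour` (integer hours since the
#'   timeline origin), `still_min`, `active_min`.
#' @export
hourly_summary <- function(tl) {
  if (!nrow(tl)) abort("hourly_summary: empty timeline")
  hour <- floor(tl$minute_start_s / 3600)
  agg <- stats::aggregate(list(still_min = tl$motion == "still",
                               active_min = tl$motion == "active"),
                          by = list(hour = hour), FUN = sum)
  agg$still_min <- as.integer(agg$still_min)
  agg$active_min <- as.integer(agg$active_min)
  agg[order(agg$hour), , drop = FALSE]
}

#' Detect short breaks in an epoch timeline
#'
#' A break is a maximal run of active epochs of length between 1 and
#' `max_break_min` minutes, immediately preceded AND followed by at
#' least `min_flank_still_min` still epochs.
#'
#' @param tl an epoch timeline.
#' @param cfg a [break_config()].
#' @return data.frame with `start_min` (minutes since origin) and
#'   `length_min`, in time order; zero rows when none qualify.
#' @export
detect_short_breaks <- function(tl, cfg = break_config()) {
  if (!nrow(tl)) abort("detect_short_breaks: empty timeline")
  r <- rle(tl$motion)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- logical(length(r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] != "active") next
    if (r$lengths[i] > cfg$max_break_min) next
    ok_before <- i > 1 && r$values[i - 1] == "still" &&
      r$lengths[i - 1] >= cfg$min_flank_still_min
    ok_after <- i < length(r$lengths) && r$values[i + 1] == "still" &&
      r$lengths[i + 1] >= cfg$min_flank_still_min
    hit[i] <- ok_before && ok_after
  }
  data.frame(start_min = tl$minute_start_s[starts[hit]] / 60,
             length_min = r$lengths[hit])
}

#' Daily totals and period percentages
#'
#' Hours per context per calendar day (day boundaries every 24 h from
#' the timeline origin, i.e. local midnight of the stated timezone;
#' default UTC) plus percentages of epochs per context over the whole
#' period. Hours are epoch counts / 60, unrounded. The micro-context
#' hours (tv + pc + unknown) partition the still hours exactly; the
#' motion percentages (active + still) sum to 100.
#'
#' @param tl an epoch timeline.
#' @return List with `daily` (data.frame: `day`, `active_h`, `still_h`,
#'   `tv_h`, `pc_h`, `unknown_h`) and `percentages` (named vector over
#'   active/still/tv/pc/unknown, percent of all epochs).
#' @export
period_summary <- function(tl) {
  if (!nrow(tl)) abort("period_summary: empty timeline")
  day <- floor(tl$minute_start_s / 86400)
  count_h <- function(mask) {
    v <- stats::aggregate(list(n = mask), by = list(day = day), FUN = sum)
    v$n / 60
  }
  days <- sort(unique(day))
  daily <- data.frame(
    day = days,
    active_h = count_h(tl$motion == "active"),
    still_h = count_h(tl$motion == "still"),
    tv_h = count_h(tl$micro == "tv"),
    pc_h = count_h(tl$micro == "pc"),
    unknown_h = count_h(tl$micro == "unknown"))
  n <- nrow(tl)
  pct <- c(active = sum(tl$motion == "active"),
           still = sum(tl$motion == "still"),
           tv = sum(tl$micro == "tv"),
           pc = sum(tl$micro == "pc"),
           unknown = sum(tl$micro == "unknown")) / n * 100
  list(daily = daily, percentages = pct)
}

#' Full behaviour summary of a timeline
#'
#' Bundles the hourly view, daily totals, period percentages and short
#' breaks into one object — the desk-scale equivalent of the weekly
#' behaviour dashboards. Short breaks are reported both as a count and
#' as total break minutes, since "time spent in short breaks" can mean
#' either.
#'
#' @param tl an epoch timeline.
#' @param cfg a [break_config()].
#' @return A list of class `behaviour_summary` with `hourly`, `daily`,
#'   `percentages`, `short_breaks`, `n_breaks`, `break_minutes`,
#'   `n_epochs`.
#' @export
behaviour_summary <- function(tl, cfg = break_config()) {
  ps <- period_summary(tl)
  br <- detect_short_breaks(tl, cfg)
  structure(list(hourly = hourly_summary(tl), daily = ps$daily,
                 percentages = ps$percentages, short_breaks = br,
                 n_breaks = nrow(br),
                 break_minutes = sum(br$length_min),
                 n_epochs = nrow(tl)),
            class = "behaviour_summary")
}

#' @export
print.behaviour_summary <- function(x, ...) {
  cat(sprintf("<behaviour_summary: %d epochs over %d day(s)>\n",
              x$n_epochs, nrow(x$daily)))
  cat("  percentages:",
      paste(sprintf("%s=%.1f%%", names(x$percentages), x$percentages),
            collapse = " "), "\n")
  cat(sprintf("  short breaks: %d (%d min total)\n",
              x$n_breaks, x$break_minutes))
  invisible(x)
}

#' Compare two behaviour summaries
#'
#' Week-over-week (or any equal-length period) comparison: absolute and
#' relative change per context plus short-break count and minutes.
#' Relative change is undefined when the baseline is zero and is
#' reported as `NA` with `rel_defined = FALSE`.
#'
#' @param a,b [behaviour_summary()] objects over equal-length periods
#'   (equal epoch counts).
#' @return data.frame with `metric`, `a`, `b`, `delta`,
#'   `rel_change_pct`, `rel_defined`.
#' @export
compare_periods <- function(a, b) {
  if (a$n_epochs != b$n_epochs)
    abort("compare_periods: periods have different lengths (epoch counts)")
  tot <- function(s) c(
    active_h = sum(s$daily$active_h), still_h = sum(s$daily$still_h),
    tv_h = sum(s$daily$tv_h), pc_h = sum(s$daily$pc_h),
    unknown_h = sum(s$daily$unknown_h),
    n_breaks = s$n_breaks, break_minutes = s$break_minutes)
  va <- tot(a); vb <- tot(b)
  delta <- vb - va
  rel_defined <- va > 0
  rel <- ifelse(rel_defined, delta / va * 100, NA_real_)
  data.frame(metric = names(va), a = unname(va), b = unname(vb),
             delta = unname(delta), rel_change_pct = unname(rel),
             rel_defined = unname(rel_defined))
}
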