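# Behaviour analytics: hourly totals, short breaks, periods, comparisons

test_that("hourly_summary counts epoch minutes per clock hour", {
  tl <- make_tl(c("still", "pc", 60))
  h <- hourly_summary(tl)
  expect_equal(h$still_min, 60L)
  expect_equal(h$active_min, 0L)

  tl2 <- make_tl(c("still", "tv", 30), c("active", "none", 30))
  h2 <- hourly_summary(tl2)
  expect_equal(h2$still_min, 30L)
  expect_equal(h2$active_min, 30L)

  # an empty hour is absent, not zero-filled
  tl3 <- rbind(make_tl(c("still", "tv", 60)),
               make_tl(c("active", "none", 60), start_min = 120))
  expect_equal(hourly_summary(tl3)$hour, c(0, 2))
})

test_that("detect_short_breaks applies length and flank rules", {
  cfg <- break_config()
  b1 <- detect_short_breaks(
    make_tl(c("still", "tv", 15), c("active", "none", 2),
            c("still", "tv", 15)), cfg)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$start_min, 15)
  expect_equal(b1$length_min, 2)

  b2 <- detect_short_breaks(
    make_tl(c("still", "tv", 15), c("active", "none", 8),
            c("still", "tv", 15)), cfg)
  expect_equal(nrow(b2), 0L)  # 8 > max_break_min

  b3 <- detect_short_breaks(
    make_tl(c("still", "tv", 5), c("active", "none", 2),
            c("still", "tv", 15)), cfg)
  expect_equal(nrow(b3), 0L)  # leading flank too short
})

test_that("short breaks agree with the scan oracle on random timelines", {
  set.seed(12)
  cfg <- break_config()
  for (i in 1:20) {
    motion <- sample(c("still", "active"), 200, replace = TRUE,
                     prob = c(0.8, 0.2))
    tl <- data.frame(minute_start_s = 60 * (seq_along(motion) - 1),
                     motion = motion,
                     micro = ifelse(motion == "active", "none", "unknown"),
                     audio_sampled = FALSE)
    got <- detect_short_breaks(tl, cfg)
    want <- oracle_breaks(motion, cfg$max_break_min, cfg$min_flank_still_min)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_min, vapply(want, `[[`, 0, "start") - 1)
      expect_equal(got$length_min, vapply(want, `[[`, 0, "len"))
    }
  }
})

test_that("period_summary reproduces constructed compositions", {
  # a 71% still / 29% active constructed period
  tl <- make_tl(c("still", "unknown", 71), c("active", "none", 29))
  ps <- period_summary(tl)
  expect_equal(unname(ps$percentages["still"]), 71)
  expect_equal(unname(ps$percentages["active"]), 29)
  expect_equal(sum(ps$percentages[c("active", "still")]), 100)

  # 7 h of PC work in one day
  tl2 <- make_tl(c("still", "pc", 7 * 60))
  expect_equal(period_summary(tl2)$daily$pc_h, 7)

  # everything unknown
  tl3 <- make_tl(c("still", "unknown", 120))
  expect_equal(unname(period_summary(tl3)$percentages["unknown"]), 100)
})

test_that("daily totals partition exactly", {
  set.seed(44)
  motion <- sample(c("still", "active"), 3000, replace = TRUE)
  micro <- ifelse(motion == "active", "none",
                  sample(c("tv", "pc", "unknown"), 3000, replace = TRUE))
  tl <- data.frame(minute_start_s = 60 * (seq_along(motion) - 1),
                   motion = motion, micro = micro, audio_sampled = FALSE)
  d <- period_summary(tl)$daily
  expect_equal(d$active_h + d$still_h,
               as.numeric(table(floor(tl$minute_start_s / 86400))) / 60)
  expect_equal(d$tv_h + d$pc_h + d$unknown_h, d$still_h)
})

test_that("summaries survive a serialisation round trip", {
  tl <- make_tl(c("still", "tv", 15), c("active", "none", 2),
                c("still", "pc", 20))
  tl <- sedentr:::epoch_timeline(tl)
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_timeline_jsonl(tl, path)
  tl2 <- read_timeline_jsonl(path)
  expect_equal(behaviour_summary(tl2), behaviour_summary(tl))
})

test_that("compare_periods reports absolute and relative change", {
  pad_still <- function(n) c("still", "unknown", n)
  # 10 breaks vs 15 breaks, both padded to the same period length
  brk <- function(k, total) {
    runs <- list(pad_still(10))
    for (i in seq_len(k)) {
      runs <- c(runs, list(c("active", "none", 1)), list(pad_still(10)))
    }
    tl <- do.call(make_tl, runs)
    pad <- total - nrow(tl)
    rbind(tl, make_tl(pad_still(pad), start_min = nrow(tl)))
  }
  a <- behaviour_summary(brk(10, 400))
  b <- behaviour_summary(brk(15, 400))
  expect_equal(a$n_breaks, 10)
  expect_equal(b$n_breaks, 15)
  cmp <- compare_periods(a, b)
  expect_equal(cmp$rel_change_pct[cmp$metric == "n_breaks"], 50)

  cmp0 <- compare_periods(a, a)
  expect_true(all(cmp0$delta == 0))

  # zero baseline: relative change undefined, absolute still reported
  x <- behaviour_summary(make_tl(c("still", "pc", 180)))
  y <- behaviour_summary(make_tl(c("still", "tv", 180)))
  cmp2 <- compare_periods(x, y)
  tv_row <- cmp2[cmp2$metric == "tv_h", ]
  expect_false(tv_row$rel_defined)
  expect_true(is.na(tv_row$rel_change_pct))
  expect_equal(tv_row$delta, 3)

  short <- behaviour_summary(make_tl(c("still", "pc", 60)))
  expect_error(compare_periods(x, short), class = "sedentr_error")
})
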