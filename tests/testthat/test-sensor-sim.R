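# Synthetic sensor simulator

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(accel_rate_hz = 0), class = "sedentr_error")
  expect_error(sim_config(still_noise_sd = -1), class = "sedentr_error")
  expect_error(sim_config(active_amp_mps2 = 0.1, still_noise_sd = 0.05),
               class = "sedentr_error")
})

test_that("still stream with zero noise is exactly the gravity vector", {
  cfg <- sim_config(still_noise_sd = 0, seed = 3L)
  s <- simulate_accel("still", 3, cfg)
  g <- attr(s, "gravity_dir") * cfg$gravity_mps2
  expect_equal(length(s$time_s), 150L)
  expect_true(all(s$ax == g[1] & s$ay == g[2] & s$az == g[3]))
})

test_that("active vertical component is a sinusoid with energy amp^2/2", {
  cfg <- sim_config(still_noise_sd = 0, active_amp_mps2 = 2,
                    active_freq_hz = 2, seed = 5L)
  s <- simulate_accel("active", 3, cfg)
  u <- attr(s, "gravity_dir")
  d <- sweep(cbind(s$ax, s$ay, s$az), 2, cfg$gravity_mps2 * u)
  vert <- as.numeric(d %*% u)
  expect_equal(mean(vert^2), 2.0, tolerance = 1e-6)
  t <- s$time_s
  expect_equal(vert, 2 * sin(2 * pi * 2 * t), tolerance = 1e-9)
})

test_that("still noise sd is recovered from a long recording", {
  cfg <- sim_config(seed = 7L)
  s <- simulate_accel("still", 60, cfg, seed = 7L)
  g <- attr(s, "gravity_dir") * cfg$gravity_mps2
  for (i in 1:3) {
    dyn <- cbind(s$ax, s$ay, s$az)[, i] - g[i]
    expect_gt(sd(dyn), 0.04)
    expect_lt(sd(dyn), 0.06)
  }
})

test_that("simulate_accel rejects bad labels and short durations", {
  expect_error(simulate_accel("jogging", 10), class = "sedentr_error")
  expect_error(simulate_accel("still", 2), class = "sedentr_error")
})

test_that("audio surrogates have the intended spectral signatures", {
  cfg <- fast_sim(seed = 21L, audio_rate_hz = 16000)
  tv <- simulate_audio("tv", 8, cfg, seed = 21L)
  unk <- simulate_audio("unknown", 8, cfg, seed = 21L)
  expect_gt(spectral_flatness(unk$samples), spectral_flatness(tv$samples))
  expect_gte(band_power_fraction(tv$samples, 16000, c(300, 3400)), 0.8)
  expect_lte(max(abs(tv$samples)), 1)
  expect_error(simulate_audio("radio", 8, cfg), class = "sedentr_error")
  expect_error(simulate_audio("tv", 4, cfg), class = "sedentr_error")
})

test_that("pc surrogate with zero click rate degenerates to the hum floor", {
  cfg <- fast_sim(seed = 9L, pc_click_rate_hz = 0)
  s <- simulate_audio("pc", 8, cfg, seed = 9L)
  hum <- sedentr:::with_seed(9L, stats::rnorm(8 * cfg$audio_rate_hz,
                                              sd = cfg$pc_hum_rms))
  expect_equal(sqrt(mean(s$samples^2)), sqrt(mean(hum^2)), tolerance = 1e-9)
})

test_that("simulate_day ground truth counts minutes per segment", {
  gt1 <- schedule_ground_truth(sim_schedule("active", 600))
  expect_equal(nrow(gt1), 10L)
  expect_true(all(gt1$motion == "active" & gt1$micro == "none"))

  gt2 <- schedule_ground_truth(sim_schedule("still_tv", 3600))
  expect_equal(nrow(gt2), 60L)
  expect_true(all(gt2$motion == "still" & gt2$micro == "tv"))

  sched <- sim_schedule(c("active", "still_pc", "active", "still_pc"),
                        c(300, 900, 120, 900))
  gt3 <- schedule_ground_truth(sched)
  expect_equal(nrow(gt3), 37L)
  expect_equal(rle(gt3$motion)$lengths, c(5L, 15L, 2L, 15L))
  expect_equal(gt3$micro[6:20], rep("pc", 15))
})

test_that("simulation is bit-reproducible and conserves duration", {
  sched <- sim_schedule(c("active", "still_tv"), c(120, 180))
  cfg <- fast_sim(seed = 33L)
  d1 <- simulate_day(sched, cfg)
  d2 <- simulate_day(sched, cfg)
  expect_identical(d1$accel, d2$accel)
  expect_identical(d1$audio$samples, d2$audio$samples)
  total <- sum(sched$duration_s)
  expect_lt(abs(length(d1$accel$time_s) / cfg$accel_rate_hz - total),
            1 / cfg$accel_rate_hz + 1e-12)
  expect_lt(abs(length(d1$audio$samples) / cfg$audio_rate_hz - total),
            1 / cfg$audio_rate_hz + 1e-12)
})

test_that("still and active are separable on vertical energy", {
  cfg <- sim_config(seed = 55L)
  energies <- function(label, seeds) {
    unlist(lapply(seeds, function(sd) {
      s <- simulate_accel(label, 30, cfg, seed = sd)
      wins <- window_accel(s)
      vapply(wins, function(w) {
        g <- suppressWarnings(estimate_gravity(w))
        motion_features(decompose_dynamic(w, g))[["energy_v"]]
      }, numeric(1))
    }))
  }
  e_still <- energies("still", 101:105)   # 50 windows
  e_active <- energies("active", 201:205) # 50 windows
  expect_equal(length(e_still) + length(e_active), 100L)
  expect_gt(min(e_active), max(e_still))
})
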