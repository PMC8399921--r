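test_that("session schedule arithmetic and determinism hold", {
  cfg <- protocol_config(n_laps = 2, seed = 7)
  s1 <- generate_session(cfg)
  # two seated blocks of sit_s seconds each
  sit_runs <- rle(s1$truth$activity == "sit")
  expect_equal(sum(sit_runs$values), 2)
  expect_equal(sit_runs$lengths[sit_runs$values], rep(cfg$sit_s, 2))
  expect_equal(s1$duration_s, session_duration(cfg))
  # stream alignment: counts match duration x rate (+/- 1)
  expect_lte(abs(nrow(s1$accel) - s1$duration_s * 100), 1)
  expect_lte(abs(nrow(s1$ecg) - s1$duration_s * 250), 1)
  expect_equal(nrow(s1$gps), s1$duration_s)
  expect_true(all(diff(s1$accel$time) > 0))
  # same config and seed twice: bit-identical streams
  s2 <- generate_session(protocol_config(n_laps = 2, seed = 7))
  expect_identical(s1$accel, s2$accel)
  expect_identical(s1$ecg, s2$ecg)
  expect_identical(s1$gps, s2$gps)
  expect_identical(s1$test_scores, s2$test_scores)
  # different seed changes the draw
  s3 <- generate_session(protocol_config(n_laps = 2, seed = 8))
  expect_false(identical(s1$accel$x, s3$accel$x))
})

test_that("default fatigue trajectory is monotone and bounded", {
  tr <- fatigue_trajectory(3600 * 11)
  t <- seq(0, 3600 * 11, by = 60)
  f <- fatigue_at(tr, t)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_gte(fatigue_at(tr, 3600 * 11), fatigue_at(tr, 0))
  # recovery component bounded and off by default
  tr2 <- fatigue_trajectory(3600 * 11, recovery_amp = 0.1)
  expect_true(all(abs(fatigue_at(tr2, t) - fatigue_at(tr, t)) <= 0.1 + 1e-12))
})

test_that("invalid configurations are rejected", {
  expect_error(protocol_config(n_laps = 0), class = "ff_config_error")
  expect_error(protocol_config(accel_rate_hz = -1), class = "ff_config_error")
  open_course <- default_course()
  open_course$dalt_m[5] <- open_course$dalt_m[5] + 50   # break the loop
  expect_error(protocol_config(course = open_course),
               class = "ff_config_error")
})

test_that("gait generator closes the loop with the cadence estimator", {
  a <- synth_gait_accel("run", "dirt", 160, fatigue = 0, duration_s = 60,
                        seed = 1)
  cad <- cadence_from_zero_crossings(a$x, 100, window_s = 60)
  expect_lte(abs(cad$cadence_spm[30] - 160), 2)
  b <- synth_gait_accel("walk", "tarseal", 110, fatigue = 0, duration_s = 60,
                        seed = 2)
  cadb <- cadence_from_zero_crossings(b$x, 100, window_s = 60)
  expect_lte(abs(cadb$cadence_spm[30] - 110), 2)
  # downstream class for a 110 spm walk is "walk"
  expect_equal(unique(classify_activity(
    cadence_from_zero_crossings(b$x, 100, 5)$cadence_spm[3:57])), "walk")
})

test_that("per-step peak amplitude decreases with fatigue", {
  peaks_at <- function(f) {
    a <- synth_gait_accel("run", "dirt", 160, fatigue = f, duration_s = 30,
                          seed = 3, noise_sd = 0)
    # mean per-step peak via 1-second maxima (steps are sub-second at 160)
    mean(tapply(a$x, floor(a$time), max))
  }
  p <- vapply(c(0, 0.3, 0.6, 0.9), peaks_at, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("gait generator validates its inputs", {
  expect_error(synth_gait_accel("swim", "dirt", 160, 0, 10),
               class = "ff_validation_error")
  expect_error(synth_gait_accel("run", "lava", 160, 0, 10),
               class = "ff_validation_error")
  expect_error(synth_gait_accel("run", "dirt", 30, 0, 10),
               class = "ff_validation_error")
})

test_that("ECG generator tracks the requested heart rate", {
  e <- synth_ecg(60, duration_s = 60, seed = 1)
  peaks <- detect_r_peaks(baseline_correct_ecg(e$ecg))
  expect_lte(abs(length(peaks) - 60), 1)
  # faster rate
  e2 <- synth_ecg(150, duration_s = 60, seed = 1)
  expect_lte(abs(length(detect_r_peaks(baseline_correct_ecg(e2$ecg))) - 150),
             3)
  # determinism
  expect_identical(e, synth_ecg(60, duration_s = 60, seed = 1))
  # out-of-range rejected
  expect_error(synth_ecg(20, 10), class = "ff_validation_error")
})

test_that("with zero wander, baseline correction is near-identity on ECG", {
  e <- synth_ecg(70, duration_s = 30, seed = 4, wander_amp = 0,
                 noise_sd = 0)
  corrected <- baseline_correct_ecg(e$ecg)
  qrs_amp <- max(e$ecg) - min(e$ecg)
  expect_lt(max(abs(corrected - e$ecg)), 0.1 * qrs_amp)
})

test_that("test scores follow the trajectory with configured sensitivity", {
  tr <- fatigue_trajectory(11 * 3600, f_end = 0.6)
  sched <- tibble::tibble(time = (0:10) * 3600 + 3000,
                          phase = "post_physical")
  # noiseless, negative slope: downstream sensitivity R^2 is exactly 1
  batt <- tibble::tibble(test_name = "ftt_dominant", intercept = 44,
                         slope = -10, noise_sd = 0)
  sc <- synth_test_scores(tr, sched, batt, seed = 5)
  expect_equal(sensitivity_r2(sc$time, sc$score)$r2, 1, tolerance = 1e-9)
  # zero slope: R^2 near zero
  batt0 <- tibble::tibble(test_name = "pvsat", intercept = 50, slope = 0,
                          noise_sd = 3)
  sc0 <- synth_test_scores(tr, sched, batt0, seed = 6)
  expect_lt(sensitivity_r2(sc0$time, sc0$score)$r2, 0.35)
  expect_error(synth_test_scores(tr, sched[0, ], batt),
               class = "ff_validation_error")
})

test_that("FTT-like noise level recovers the pre-registered mean R^2", {
  # Monte-Carlo target fixed in advance of the generator build: a decline of
  # 0.05 normalized units/hour over 12 hourly tests with score noise sd 0.11
  # has expected sensitivity R^2 0.74 (1000-replicate oracle)
  tr <- fatigue_trajectory(12 * 3600, f_start = 0, f_end = 1)  # f' = 1/12h
  sched <- tibble::tibble(time = (0:11) * 3600, phase = "post_physical")
  batt <- tibble::tibble(test_name = "ftt_dominant", intercept = 1,
                         slope = -0.6, noise_sd = 0.11)   # -0.05/h
  r2 <- vapply(1:120, function(i) {
    sc <- synth_test_scores(tr, sched, batt, seed = 1000 + i)
    sensitivity_r2(sc$time, sc$score)$r2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.74), 0.15)
})
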