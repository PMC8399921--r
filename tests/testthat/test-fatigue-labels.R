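test_that("score normalization hits the min-max identities", {
  expect_equal(normalize_scores(c(40, 35, 30)), c(1, 0.5, 0))
  expect_error(normalize_scores(rep(5, 4)), class = "ff_scaling_error")
  withr::with_seed(3, {
    for (i in 1:10) {
      y <- normalize_scores(rnorm(8, 50, 5))
      expect_equal(min(y), 0)
      expect_equal(max(y), 1)
    }
  })
})

test_that("LTLF is the least-squares line through normalized scores", {
  span <- 100
  t_obs <- c(10, 30, 50, 70, 90)
  # noiseless linear decline: label equals the generating line exactly
  sc <- 40 - 0.1 * t_obs
  lab <- build_ltlf(t_obs, sc, span, rate_hz = 10)
  grid <- (0:(span * 10 - 1)) / 10
  truth <- 1 - (grid - 10) / 80            # normalized line through obs
  expect_equal(lab$values, pmin(pmax(truth, 0), 1), tolerance = 1e-9)
  expect_equal(lab$fit$r2, 1, tolerance = 1e-12)
  # closed-form OLS oracle on noisy data
  withr::with_seed(5, {
    sc2 <- 40 - 0.1 * t_obs + rnorm(5, 0, 1)
    lab2 <- build_ltlf(t_obs, sc2, span, rate_hz = 10)
    y <- (sc2 - min(sc2)) / (max(sc2) - min(sc2))
    beta <- cov(t_obs, y) / var(t_obs)
    alpha <- mean(y) - beta * mean(t_obs)
    expect_equal(lab2$fit$slope, beta, tolerance = 1e-12)
    expect_equal(lab2$fit$intercept, alpha, tolerance = 1e-12)
  })
  expect_error(build_ltlf(c(1, 1), c(2, 3), span),
               class = "ff_label_error")
  expect_error(build_ltlf(5, 2, span), class = "ff_label_error")
})

test_that("LTLF slope recovery stays within its sampling error", {
  # OLS sampling-distribution oracle: sd 0.05 noise on normalized scores
  # over 11 hourly points; se(slope) = sd / sqrt(sum((t - tbar)^2))
  t_obs <- (0:10) * 3600
  slope_true <- -0.6 / (10 * 3600)
  se <- 0.05 / sqrt(sum((t_obs - mean(t_obs))^2))
  withr::with_seed(8, {
    hits <- replicate(200, {
      y <- 1 + slope_true * t_obs + rnorm(11, 0, 0.05)
      fit <- lm(y ~ t_obs)
      abs(coef(fit)[[2]] - slope_true) < 2 * se
    })
  })
  expect_gte(mean(hits), 0.9)   # nominal 95% coverage
})

test_that("ITI interpolates through every observation", {
  span <- 100
  t_obs <- c(10, 30, 50, 70)
  sc <- c(44, 40, 42, 36)
  lab <- build_iti(t_obs, sc, span, rate_hz = 10)
  y <- normalize_scores(sc)
  at <- function(tt) lab$values[round(tt * 10) + 1]
  expect_equal(at(t_obs), y, tolerance = 1e-9)
  # midway between normalized 0.8 and 0.6 lies 0.7
  lab2 <- build_iti(c(0, 10, 20, 30), c(1, 0.8, 0.6, 0), span, rate_hz = 10)
  expect_equal(lab2$values[round(15 * 10) + 1], 0.7, tolerance = 1e-9)
  # constant extrapolation outside the observation span
  expect_equal(at(0), y[1])
  expect_equal(at(99), y[4])
})

test_that("ITI of collinear observations equals LTLF pointwise", {
  t_obs <- c(5, 25, 45, 65, 85)
  sc <- 30 - 0.2 * t_obs
  iti <- build_iti(t_obs, sc, 90, rate_hz = 10)
  ltlf <- build_ltlf(t_obs, sc, 90, rate_hz = 10)
  inside <- seq(5 * 10 + 1, 85 * 10)   # both clip/extrapolate outside
  expect_equal(iti$values[inside], ltlf$values[inside], tolerance = 1e-9)
})

test_that("label builders return bounded series of the session length", {
  s <- ff_test_session()
  for (m in c("ITI", "LTLF")) {
    lab <- session_label(s, method = m)
    expect_length(lab$values, round(s$duration_s * 250))
    expect_true(all(lab$values >= 0 & lab$values <= 1))
  }
})

test_that("sensitivity R^2 behaves at its extremes and under affine maps", {
  t_obs <- (0:11) * 3600
  expect_equal(sensitivity_r2(t_obs, 50 - 0.001 * t_obs)$r2, 1,
               tolerance = 1e-9)
  withr::with_seed(12, {
    r2 <- sensitivity_r2(seq_len(400), rnorm(400))$r2
    expect_lt(r2, 0.05)
    # affine invariance in score and in time
    sc <- 40 - 0.002 * t_obs + rnorm(12, 0, 1)
    base <- sensitivity_r2(t_obs, sc)$r2
    expect_equal(sensitivity_r2(3 * t_obs + 7, -2 * sc + 100)$r2, base,
                 tolerance = 1e-12)
  })
  expect_error(sensitivity_r2(1:2, 1:2), class = "ff_validation_error")
})

test_that("phase subsetting and outlier removal work", {
  withr::with_seed(31, {
    t_obs <- rep((0:7) * 3600, each = 2)
    ph <- rep(c("post_physical", "post_cognitive"), 8)
    sc <- 40 - 0.0005 * t_obs + rnorm(16, 0, 0.5)
    sc[3] <- sc[3] + 30   # gross outlier
    all_r2 <- sensitivity_r2(t_obs, sc)$r2
    clean <- sensitivity_r2(t_obs, sc, outlier_rule = 3)
    expect_gt(clean$r2, all_r2)
    expect_true(3 %in% clean$removed)
    phys <- sensitivity_r2(t_obs, sc, phase = ph, subset = "post_physical")
    expect_equal(phys$n, 8)
  })
})

test_that("battery sensitivity ranking matches its design", {
  # Monte-Carlo rank oracle: jump and dominant-hand FTT rank above PVSAT in
  # >= 95% of 200 replicates of a full synthetic battery
  tr <- fatigue_trajectory(11 * 3600, f_end = 0.6)
  sched <- tibble::tibble(time = (0:10) * 3600 + 1800,
                          phase = "post_physical")
  wins <- vapply(1:200, function(i) {
    sc <- synth_test_scores(tr, sched, seed = 5000 + i)
    tab <- sensitivity_table(sc)
    r2 <- setNames(tab$r2_all, tab$test_name)
    r2[["jump"]] > r2[["pvsat"]] && r2[["ftt_dominant"]] > r2[["pvsat"]]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
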