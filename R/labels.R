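#' Normalize performance-test scores
#'
#' Min-max scales a test's observations onto `[0, 1]` over the protocol
#' (its own min and max), so tests with different units become comparable
#' label sources.
#'
#' @param scores Numeric score vector with at least two distinct values.
#' @return Scores scaled to `[0, 1]` (min maps to 0, max to 1).
#' @export
#' @examples
#' normalize_scores(c(40, 35, 30))   # 1, 0.5, 0
normalize_scores <- function(scores) {
  if (max(scores) <= min(scores)) {
    abort("Constant score series cannot be normalized.",
          class = "ff_scaling_error")
  }
  feature_scale(scores)
}

new_fatigue_label <- function(values, method, source_test, rate_hz, fit,
                              observations) {
  structure(
    list(values = values, method = method, source_test = source_test,
         rate_hz = rate_hz, fit = fit, observations = observations),
    class = "fatigue_label"
  )
}

check_test_series <- function(time, score) {
  if (length(time) < 2) {
    abort("Need at least 2 observations to build a label.",
          class = "ff_label_error")
  }
  if (any(diff(time) <= 0)) {
    abort("Observation times must be strictly increasing.",
          class = "ff_label_error")
  }
  if (max(time) - min(time) <= 0) {
    abort("Degenerate time spread.", class = "ff_label_error")
  }
}

#' Continuous fatigue label: long-term linear fit (LTLF)
#'
#' Fits an ordinary least-squares line through normalized (time, score)
#' observations of one performance test and evaluates it on the 250 Hz
#' sample grid, clipped to `[0, 1]`.  The label tracks normalized
#' performance: 1 is freshest.  LTLF represents long-term fatigue under a
#' constant hourly load.
#'
#' @param time Observation times, seconds, strictly increasing (`>= 2`).
#' @param score Raw scores at those times.
#' @param session_span Session duration in seconds (the grid runs over
#'   `[0, session_span)`).
#' @param rate_hz Label rate, default 250.
#' @param source_test Name recorded on the label (default
#'   `"ftt_dominant"`).
#' @param invert If `TRUE`, flips polarity so 1 = most fatigued.
#' @return A `fatigue_label` with `values` of length
#'   `round(session_span * rate_hz)`, the OLS `fit` (slope, intercept on
#'   normalized scores), and the normalized observations.
#' @export
build_ltlf <- function(time, score, session_span, rate_hz = 250,
                       source_test = "ftt_dominant", invert = FALSE) {
  check_test_series(time, score)
  y <- normalize_scores(score)
  if (invert) y <- 1 - y
  fit <- lm(y ~ time, data = data.frame(time = time, y = y))
  grid <- label_grid(session_span, rate_hz)
  vals <- pmin(pmax(coef(fit)[[1]] + coef(fit)[[2]] * grid, 0), 1)
  new_fatigue_label(vals, "LTLF", source_test, rate_hz,
                    list(intercept = coef(fit)[[1]], slope = coef(fit)[[2]],
                         r2 = cor(time, y)^2),
                    tibble::tibble(time = time, score = score, norm = y))
}

#' Continuous fatigue label: inter-test interpolation (ITI)
#'
#' Piecewise-linear interpolation between consecutive normalized
#' observations (constant extrapolation outside), evaluated at 250 Hz.
#' Unlike LTLF, ITI retains short-term fatigue and recovery between tests
#' and needs no constant-load assumption, so it suits unconstrained field
#' prediction.
#'
#' @inheritParams build_ltlf
#' @return A `fatigue_label`; its values pass exactly through every
#'   normalized observation.
#' @export
build_iti <- function(time, score, session_span, rate_hz = 250,
                      source_test = "ftt_dominant", invert = FALSE) {
  check_test_series(time, score)
  y <- normalize_scores(score)
  if (invert) y <- 1 - y
  grid <- label_grid(session_span, rate_hz)
  vals <- approx(time, y, grid, rule = 2)$y
  vals <- pmin(pmax(vals, 0), 1)
  new_fatigue_label(vals, "ITI", source_test, rate_hz, NULL,
                    tibble::tibble(time = time, score = score, norm = y))
}

label_grid <- function(session_span, rate_hz) {
  (seq_len(round(session_span * rate_hz)) - 1) / rate_hz
}

#' Build a label from a session's test-score table
#'
#' Convenience wrapper: selects one test (optionally one phase), then calls
#' [build_ltlf()] or [build_iti()].
#'
#' @param session A `sensor_session`.
#' @param method `"LTLF"` or `"ITI"`.
#' @param source_test Test name in `session$test_scores`.
#' @param phase Optional phase filter (`"post_physical"`/`"post_cognitive"`).
#' @param ... Passed on to the builder.
#' @return A `fatigue_label`.
#' @export
session_label <- function(session, method = c("ITI", "LTLF"),
                          source_test = "ftt_dominant", phase = NULL, ...) {
  method <- match.arg(method)
  obs <- dplyr::filter(session$test_scores, .data$test_name == source_test)
  if (!is.null(phase)) obs <- dplyr::filter(obs, .data$phase == !!phase)
  builder <- if (method == "LTLF") build_ltlf else build_iti
  builder(obs$time, obs$score, session$duration_s,
          rate_hz = session$ecg_rate_hz, source_test = source_test, ...)
}

#' @export
print.fatigue_label <- function(x, ...) {
  cat(sprintf("<fatigue_label> %s from %s: %d values @ %g Hz in [%.2f, %.2f]\n",
              x$method, x$source_test, length(x$values), x$rate_hz,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sensitivity of a performance test to the protocol
#'
#' Squared Pearson correlation of score against time, the per-test
#' sensitivity statistic.  Optionally restricts to one assessment phase and
#' removes outliers by absolute studentized residual (a reproducible proxy
#' for manual outlier screening).
#'
#' @param time,score Observations (time in seconds).
#' @param phase Optional per-observation phase tags.
#' @param subset `"all"`, `"post_physical"` or `"post_cognitive"`.
#' @param outlier_rule `NULL` (keep all) or a numeric threshold on
#'   `abs(rstudent)` (e.g. 3).
#' @return A list: `r2`, `n`, `removed` (indices of removed outliers).
#' @export
sensitivity_r2 <- function(time, score, phase = NULL, subset = "all",
                           outlier_rule = NULL) {
  if (subset != "all") {
    if (is.null(phase)) abort("`phase` needed to subset.",
                              class = "ff_validation_error")
    keep <- phase == subset
    time <- time[keep]
    score <- score[keep]
  }
  removed <- integer(0)
  if (!is.null(outlier_rule)) {
    fit <- lm(score ~ time)
    rs <- stats::rstudent(fit)
    removed <- which(abs(rs) > outlier_rule)
    if (length(removed) > 0) {
      time <- time[-removed]
      score <- score[-removed]
    }
  }
  if (length(time) < 3) {
    abort("Subset leaves fewer than 3 observations.",
          class = "ff_validation_error")
  }
  list(r2 = cor(time, score)^2, n = length(time), removed = removed)
}

#' Sensitivity table for a whole battery
#'
#' Computes [sensitivity_r2()] for every test in a score table, over all
#' observations and within each phase.
#'
#' @param test_scores Tibble `time`, `test_name`, `phase`, `score`.
#' @param outlier_rule Passed to [sensitivity_r2()] (applied to every test).
#' @return Tibble `test_name`, `r2_all`, `r2_post_physical`,
#'   `r2_post_cognitive`, `n`.
#' @export
sensitivity_table <- function(test_scores, outlier_rule = NULL) {
  test_scores |>
    dplyr::group_by(.data$test_name) |>
    dplyr::summarise(
      r2_all = safe_r2(.data$time, .data$score, NULL, "all", outlier_rule),
      r2_post_physical = safe_r2(.data$time, .data$score, .data$phase,
                                 "post_physical", outlier_rule),
      r2_post_cognitive = safe_r2(.data$time, .data$score, .data$phase,
                                  "post_cognitive", outlier_rule),
      n = dplyr::n(),
      .groups = "drop"
    )
}

safe_r2 <- function(time, score, phase, subset, outlier_rule) {
  tryCatch(
    sensitivity_r2(time, score, phase, subset, outlier_rule)$r2,
    error = function(e) NA_real_
  )
}
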