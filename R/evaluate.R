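#' Rolling average of an ordered prediction series
#'
#' Unweighted sliding mean with step 1: output `i` is
#' `mean(x[i..i + k - 1])`, giving `n - k + 1` values.
#'
#' @param x Ordered numeric series (per-window predictions, time order).
#' @param k Rolling length, `1 <= k <= length(x)`.
#' @return Numeric vector of length `n - k + 1`.
#' @export
#' @examples
#' rolling_average(1:5, 2)   # 1.5 2.5 3.5 4.5
rolling_average <- function(x, k) {
  n <- length(x)
  if (k < 1) abort("`k` must be >= 1.", class = "ff_eval_error")
  if (n < k) {
    abort(sprintf("Insufficient windows: need at least k = %d, have %d.",
                  k, n),
          class = "ff_eval_error")
  }
  cs <- cumsum(c(0, x))
  (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
}

#' Duration covered by one rolling estimate
#'
#' A rolling average of `k` window predictions spans `k * w` samples, i.e.
#' `k * w / rate` seconds — e.g. 200 windows of 128 samples at 250 Hz is
#' 102.4 s.
#'
#' @param k Rolling length (number of predictions averaged).
#' @param w Window width in samples.
#' @param rate_hz Sampling rate, default 250.
#' @return Duration in seconds.
#' @export
#' @examples
#' estimate_duration(200, 128)   # 102.4
estimate_duration <- function(k, w, rate_hz = 250) {
  stopifnot(k > 0, w > 0, rate_hz > 0)
  k * w / rate_hz
}

#' Rolling-error metrics: MAE and RAE
#'
#' Given rolled predictions and the aligned per-window labels, computes the
#' mean absolute error and the range of absolute error.  "Range" is read as
#' the largest absolute error (the worst error to expect from a future
#' rolled prediction); `rae_mode = "span"` gives `max - min` of the absolute
#' errors instead.
#'
#' @param rolled Rolled prediction series.
#' @param label Aligned label series, same length.
#' @param rae_mode `"max"` (default) or `"span"`.
#' @return Named list `mae` and `rae`.
#' @export
#' @examples
#' mae_rae(c(0.1, 0.3), c(0, 0))   # mae 0.2, rae 0.3
mae_rae <- function(rolled, label, rae_mode = c("max", "span")) {
  rae_mode <- match.arg(rae_mode)
  if (length(rolled) != length(label)) {
    abort("`rolled` and `label` must have equal length.",
          class = "ff_eval_error")
  }
  if (length(rolled) < 1) abort("Empty series.", class = "ff_eval_error")
  e <- abs(rolled - label)
  list(mae = mean(e),
       rae = if (rae_mode == "max") max(e) else max(e) - min(e))
}

#' Evaluate a trained model on one activity's test windows
#'
#' Runs the model over the test windows in time order, smooths the
#' predictions with a rolling average of `k`, and scores them against the
#' window labels aligned at the centre of each rolling block.  Activities
#' with fewer than `k` test windows are excluded, mirroring the exclusion
#' of sample-poor activities from rolled evaluation.
#'
#' @param model A `fatigue_cnn`.
#' @param ds_test Test `windowed_dataset` of one activity (scaled with the
#'   training parameters).
#' @param k Rolling length, default 200.
#' @param label_method Tag recorded in the result (`"ITI"`/`"LTLF"`).
#' @param rae_mode Passed to [mae_rae()].
#' @return A one-row `eval_result` tibble: `activity`, `label_method`, `k`,
#'   `n_windows`, `mae_k`, `rae_k`, `duration_s_per_estimate`, `excluded`.
#'   Excluded activities carry `NA` metrics.  The per-window detail (label,
#'   raw and rolled predictions) is attached as attribute `"detail"`.
#' @export
evaluate_activity <- function(model, ds_test, k = 200,
                              label_method = "ITI", rae_mode = "max") {
  stopifnot(inherits(ds_test, "windowed_dataset"))
  activity <- unique(ds_test$meta$activity)[1]
  d <- dim(ds_test$X)[1]
  w <- dim(ds_test$X)[2]
  base <- tibble::tibble(
    activity = activity, label_method = label_method, k = as.integer(k),
    n_windows = as.integer(d),
    duration_s_per_estimate = estimate_duration(k, w)
  )
  if (d < k) {
    out <- dplyr::mutate(base, mae_k = NA_real_, rae_k = NA_real_,
                         excluded = TRUE)
    class(out) <- c("eval_result", class(out))
    return(out)
  }
  pr <- predict(model, ds_test)
  rolled <- rolling_average(pr$.pred, k)
  centre <- seq_len(d - k + 1) + (k - 1) %/% 2
  m <- mae_rae(rolled, pr$y[centre], rae_mode = rae_mode)
  out <- dplyr::mutate(base, mae_k = m$mae, rae_k = m$rae, excluded = FALSE)
  attr(out, "detail") <- dplyr::mutate(
    pr,
    rolled = c(rep(NA_real_, (k - 1) %/% 2), rolled,
               rep(NA_real_, d - length(rolled) - (k - 1) %/% 2))
  )
  class(out) <- c("eval_result", class(out))
  out
}

#' Constant-predictor baseline MAE
#'
#' The error floor of an uninformative model: predict one constant derived
#' from the training labels everywhere and score it against the test labels
#' (optionally after the same rolling alignment as the model's evaluation).
#' `statistic = "mean"` is the conventional mean-predictor reference;
#' `"median"` is the MAE-optimal constant, and is the right null reference
#' for models trained with MAE loss (which converge to the label median in
#' the absence of signal, e.g. under label permutation).
#'
#' @param train_y Training window labels.
#' @param test_y Test window labels in time order.
#' @param k Rolling length applied to the (constant) predictions.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Baseline MAE.
#' @export
baseline_mae <- function(train_y, test_y, k = 1,
                         statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  mu <- if (statistic == "mean") mean(train_y) else median(train_y)
  if (k > 1) {
    if (length(test_y) < k) {
      abort("Insufficient windows for the rolling baseline.",
            class = "ff_eval_error")
    }
    centre <- seq_len(length(test_y) - k + 1) + (k - 1) %/% 2
    test_y <- test_y[centre]
  }
  mean(abs(mu - test_y))
}
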