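#' Min-max feature scaling
#'
#' Scales a series onto `[0, 1]` by `(x - x_min) / (x_max - x_min)`.  Values
#' outside the fitting range map outside `[0, 1]`; the transform is affine
#' and exactly invertible with [feature_unscale()].
#'
#' @param x Numeric series.
#' @param params A list with `x_min` and `x_max` (see
#'   [fit_scaling_params()]); `NULL` fits on `x` itself.
#' @return Scaled numeric series.
#' @export
#' @examples
#' feature_scale(c(2, 4, 6))           # 0, 0.5, 1
feature_scale <- function(x, params = NULL) {
  if (is.null(params)) params <- fit_scaling_params(x)
  check_scaling_params(params)
  (x - params$x_min) / (params$x_max - params$x_min)
}

#' @rdname feature_scale
#' @export
feature_unscale <- function(x, params) {
  check_scaling_params(params)
  x * (params$x_max - params$x_min) + params$x_min
}

#' Fit min-max scaling parameters
#'
#' @param x Numeric series (the fitting range, typically training data).
#' @return List with `x_min`, `x_max`.
#' @export
fit_scaling_params <- function(x) {
  p <- list(x_min = min(x), x_max = max(x))
  check_scaling_params(p)
  p
}

check_scaling_params <- function(params) {
  if (!is.finite(params$x_min) || !is.finite(params$x_max) ||
      params$x_max <= params$x_min) {
    abort("Degenerate scaling range: x_max must exceed x_min.",
          class = "ff_scaling_error")
  }
  invisible(params)
}

#' ECG baseline correction by two-stage median filtering
#'
#' Estimates slow baseline wander with a cascade of running medians (a short
#' window that steps over QRS complexes, then a longer smoothing window) and
#' subtracts it.  Drift below about 0.5 Hz is removed while QRS morphology
#' is preserved.
#'
#' @param ecg Numeric ECG series.
#' @param rate_hz Sampling rate, default 250 Hz.
#' @param win1_s,win2_s Median windows in seconds (defaults ~200 ms and
#'   ~600 ms).
#' @return Baseline-corrected series, same length.
#' @export
baseline_correct_ecg <- function(ecg, rate_hz = 250, win1_s = 0.2,
                                 win2_s = 0.6) {
  k1 <- odd_window(win1_s * rate_hz)
  k2 <- odd_window(win2_s * rate_hz)
  if (length(ecg) < max(k1, k2)) {
    abort("ECG series shorter than the correction window.",
          class = "ff_prep_error")
  }
  # endrule "constant": shrinking the window at the edges would swallow an
  # edge-adjacent QRS complex into the baseline estimate
  baseline <- runmed(runmed(ecg, k1, endrule = "constant"), k2,
                     endrule = "constant")
  as.numeric(ecg - baseline)
}

odd_window <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Linear resampling onto a new rate
#'
#' Linearly interpolates a uniformly sampled series onto a target rate,
#' preserving the first sample and total duration; output length is
#' `round(n * to_hz / from_hz)`.
#'
#' @param x Numeric series sampled at `from_hz`.
#' @param from_hz,to_hz Source and target rates, `> 0`.
#' @return Resampled numeric series.
#' @export
#' @examples
#' resample_linear(seq(0, 1, length.out = 100), 100, 250) |> length()  # 250
resample_linear <- function(x, from_hz, to_hz) {
  stopifnot(from_hz > 0, to_hz > 0)
  n <- length(x)
  if (n < 2) abort("Need at least 2 samples to resample.",
                   class = "ff_prep_error")
  if (from_hz == to_hz) return(x)
  m <- round(n * to_hz / from_hz)
  t_old <- (seq_len(n) - 1) / from_hz
  t_new <- seq(0, t_old[n], length.out = m)
  approx(t_old, x, t_new)$y
}

#' Align raw streams at the model rate
#'
#' Up-samples the 100 Hz accelerometer channels to the ECG rate (250 Hz) by
#' linear interpolation, baseline-corrects the ECG, and trims all channels
#' to a common length, yielding the F = 4 feature channels the network
#' consumes.
#'
#' @param session A `sensor_session` (see [generate_session()]), or any list
#'   with `accel` (`time`, `x`, `y`, `z`), `ecg` (`time`, `ecg`) tibbles and
#'   rates `accel_rate_hz`, `ecg_rate_hz`.
#' @param correct_baseline Apply [baseline_correct_ecg()] to the ECG channel.
#' @return An `aligned_streams` tibble with columns `time`, `accel_x`,
#'   `accel_y`, `accel_z`, `ecg`, at 250 Hz, attribute `rate_hz`.
#' @export
align_streams <- function(session, correct_baseline = TRUE) {
  from <- session$accel_rate_hz %||% 100
  to <- session$ecg_rate_hz %||% 250
  ax <- resample_linear(session$accel$x, from, to)
  ay <- resample_linear(session$accel$y, from, to)
  az <- resample_linear(session$accel$z, from, to)
  ecg <- session$ecg$ecg
  if (correct_baseline) ecg <- baseline_correct_ecg(ecg, rate_hz = to)
  n <- min(length(ax), length(ecg))
  out <- tibble::tibble(
    time = (seq_len(n) - 1) / to,
    accel_x = ax[seq_len(n)],
    accel_y = ay[seq_len(n)],
    accel_z = az[seq_len(n)],
    ecg = ecg[seq_len(n)]
  )
  attr(out, "rate_hz") <- to
  class(out) <- c("aligned_streams", class(out))
  out
}
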