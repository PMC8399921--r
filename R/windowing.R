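#' Non-overlapping window count
#'
#' The number of windows obtained when `n` concatenated samples are cut into
#' consecutive non-overlapping windows of width `w`: `floor(n / w)`.
#'
#' @param n Total sample count of an activity (at 250 Hz).
#' @param w Window width in samples.
#' @return Integer window count `D`.
#' @export
#' @examples
#' n_windows(1534500, 256)   # 5994
n_windows <- function(n, w) {
  stopifnot(n >= 0, w >= 1)
  as.integer(floor(n / w))
}

#' Window one activity into a (D, W, F) dataset
#'
#' Gathers all 250 Hz samples whose second belongs to the requested
#' composite activity, concatenates them in time order, and cuts them into
#' `D = floor(N / W)` consecutive non-overlapping windows.  Each window's
#' label is the mean of the fatigue label over its source samples.  Windows
#' may span concatenation seams between non-adjacent segments of the same
#' activity (which is what produces label discontinuities in time-ordered
#' prediction traces); `strict_seams = TRUE` instead restarts windowing at
#' every seam, losing the `floor(N / W)` accounting.
#'
#' @param streams An `aligned_streams` tibble ([align_streams()]).
#' @param timeline An `activity_timeline` ([label_session()]).
#' @param activity Composite activity name (one of [ff_activities]).
#' @param width_w Window width in samples (64, 128, 256 or 512 typically).
#' @param label A `fatigue_label` aligned with `streams`.
#' @param channels Which feature channels to keep: `"combined"` (all 4),
#'   `"accel"` (3) or `"ecg"` (1).
#' @param strict_seams Break windows at concatenation seams.
#' @return A `windowed_dataset`: `X` array `(D, W, F)`, `y` length-D label
#'   vector, `meta` tibble (`activity`, `start_s`, `order`), `width`,
#'   `channel_names`.
#' @export
window_activity <- function(streams, timeline, activity, width_w, label,
                            channels = c("combined", "accel", "ecg"),
                            strict_seams = FALSE) {
  channels <- match.arg(channels)
  rate <- attr(streams, "rate_hz") %||% 250
  secs <- timeline$t[!is.na(timeline$activity) &
                       timeline$activity == activity]
  secs <- sort(secs)
  if (length(secs) == 0) {
    abort(sprintf("Activity '%s' absent from the timeline.", activity),
          class = "ff_window_error")
  }
  # sample indices of every member second, in time order
  idx <- as.vector(outer(seq_len(rate), secs * rate, `+`))
  idx <- idx[idx <= nrow(streams)]
  n <- length(idx)
  if (n < width_w) {
    abort(sprintf("Activity '%s' has %d samples, fewer than one window (%d).",
                  activity, n, width_w),
          class = "ff_window_error")
  }
  if (strict_seams) {
    seam <- c(TRUE, diff(idx) != 1)
    run_id <- cumsum(seam)
    keep <- unlist(lapply(split(seq_len(n), run_id), function(ii) {
      ii[seq_len(n_windows(length(ii), width_w) * width_w)]
    }), use.names = FALSE)
    idx <- idx[keep]
    n <- length(idx)
    if (n < width_w) {
      abort("No complete window after seam splitting.",
            class = "ff_window_error")
    }
  }
  d <- n_windows(n, width_w)
  used <- idx[seq_len(d * width_w)]

  ch_names <- switch(channels,
    combined = c("accel_x", "accel_y", "accel_z", "ecg"),
    accel = c("accel_x", "accel_y", "accel_z"),
    ecg = "ecg"
  )
  f <- length(ch_names)
  X <- array(NA_real_, dim = c(d, width_w, f))
  for (j in seq_len(f)) {
    X[, , j] <- matrix(streams[[ch_names[j]]][used], nrow = d,
                       ncol = width_w, byrow = TRUE)
  }
  lab <- matrix(label$values[used], nrow = d, ncol = width_w, byrow = TRUE)
  y <- rowMeans(lab)
  start_s <- streams$time[used[seq(1, d * width_w, by = width_w)]]
  structure(
    list(
      X = X, y = y,
      meta = tibble::tibble(activity = activity, start_s = start_s,
                            order = seq_len(d)),
      width = as.integer(width_w), channel_names = ch_names,
      scaled = FALSE, scaling = NULL
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %s: D=%d, W=%d, F=%d%s\n",
              paste(unique(x$meta$activity), collapse = "+"),
              dim(x$X)[1], dim(x$X)[2], dim(x$X)[3],
              if (isTRUE(x$scaled)) " (scaled)" else ""))
  invisible(x)
}

#' Random window-level train/test split
#'
#' Uniformly random partition of windows into train and test sets with
#' `|test| = round(fraction * D)`.  Time order is retained in the metadata
#' for time-ordered evaluation.  Window-level random splitting leaks
#' temporal autocorrelation between adjacent windows; `blocked = TRUE`
#' instead assigns one contiguous block of windows to the test set.
#'
#' @param ds A `windowed_dataset`.
#' @param test_fraction Test proportion in (0, 1), default 0.33.
#' @param seed Seed for the partition.
#' @param blocked Use a contiguous test block instead of a random partition.
#' @return List with `train` and `test` `windowed_dataset`s.
#' @export
split_train_test <- function(ds, test_fraction = 0.33, seed = 1,
                             blocked = FALSE) {
  stopifnot(inherits(ds, "windowed_dataset"),
            test_fraction > 0, test_fraction < 1)
  d <- dim(ds$X)[1]
  if (d < 3) abort("Need at least 3 windows to split.",
                   class = "ff_window_error")
  n_test <- round(test_fraction * d)
  n_test <- min(max(n_test, 1), d - 1)
  test_idx <- withr::with_seed(seed, {
    if (blocked) {
      start <- sample.int(d - n_test + 1, 1)
      seq(start, length.out = n_test)
    } else {
      sort(sample.int(d, n_test))
    }
  })
  list(train = subset_windows(ds, setdiff(seq_len(d), test_idx)),
       test = subset_windows(ds, test_idx))
}

subset_windows <- function(ds, idx) {
  out <- ds
  out$X <- ds$X[idx, , , drop = FALSE]
  out$y <- ds$y[idx]
  out$meta <- ds$meta[idx, ]
  out
}

#' Per-channel min-max scaling of a windowed dataset
#'
#' Fits per-channel min/max on one dataset (normally the training split) and
#' applies the affine map to any dataset with the same channels.  Values of
#' the fitting set land exactly in `[0, 1]`; other data may exceed the range
#' slightly, which is deliberate (no clipping, to keep the map invertible).
#'
#' @param ds Dataset to fit on.
#' @return `fit_window_scaling`: a named list of per-channel
#'   [fit_scaling_params()] results.
#' @export
fit_window_scaling <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"))
  params <- lapply(seq_along(ds$channel_names), function(j) {
    fit_scaling_params(ds$X[, , j])
  })
  names(params) <- ds$channel_names
  params
}

#' @rdname fit_window_scaling
#' @param params Result of `fit_window_scaling()`.
#' @export
apply_window_scaling <- function(ds, params) {
  stopifnot(inherits(ds, "windowed_dataset"),
            identical(names(params), ds$channel_names))
  for (j in seq_along(params)) {
    ds$X[, , j] <- feature_scale(ds$X[, , j], params[[j]])
  }
  ds$scaled <- TRUE
  ds$scaling <- params
  ds
}
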