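#' Enumerate the hyperparameter-sweep grid
#'
#' The full experiment matrix: data group (accelerometer, ECG, combined)
#' crossed with the nine composite activities and the four window widths —
#' 3 x 9 x 4 = 108 cells.
#'
#' @param data_groups Character vector of channel groups.
#' @param activities Composite activity names.
#' @param widths Window widths in samples.
#' @return Tibble `data_group`, `activity`, `width`, one row per cell.
#' @export
#' @examples
#' nrow(sweep_grid())   # 108
sweep_grid <- function(data_groups = c("accel", "ecg", "combined"),
                       activities = ff_activities,
                       widths = c(64, 128, 256, 512)) {
  tidyr::crossing(data_group = data_groups, activity = activities,
                  width = widths) |>
    dplyr::arrange(
      match(.data$data_group, data_groups),
      match(.data$activity, activities),
      .data$width
    )
}

#' Run the window-width / activity / data-group sweep
#'
#' Trains one model per grid cell on the prepared session and records the
#' test-set MAE, window count and sample count.  Cells whose activity is
#' absent or shorter than one window are skipped and recorded as such
#' rather than failing the sweep.
#'
#' @param streams An `aligned_streams` tibble.
#' @param timeline An `activity_timeline`.
#' @param label A `fatigue_label`.
#' @param grid Tibble from [sweep_grid()] (or a subset of it).
#' @param spec A [cnn_spec()] used for every cell.
#' @param test_fraction,seed Split parameters (see [split_train_test()]).
#' @return Tibble with one row per cell: the grid columns plus `n_samples`,
#'   `d`, `test_mae`, `skipped`, `reason`.
#' @export
hyperparameter_sweep <- function(streams, timeline, label,
                                 grid = sweep_grid(), spec = cnn_spec(),
                                 test_fraction = 0.33, seed = 1) {
  purrr::pmap_dfr(grid, function(data_group, activity, width) {
    cell <- tibble::tibble(data_group = data_group, activity = activity,
                           width = as.integer(width))
    res <- tryCatch({
      ds <- window_activity(streams, timeline, activity, width, label,
                            channels = data_group)
      parts <- split_train_test(ds, test_fraction, seed = seed)
      sc <- fit_window_scaling(parts$train)
      train <- apply_window_scaling(parts$train, sc)
      test <- apply_window_scaling(parts$test, sc)
      model <- train_cnn(train, spec, seed = seed)
      preds <- predict(model, test)
      dplyr::mutate(cell,
                    n_samples = dim(ds$X)[1] * as.integer(width),
                    d = dim(ds$X)[1],
                    test_mae = mean(abs(preds$.pred - preds$y)),
                    skipped = FALSE, reason = NA_character_)
    }, ff_window_error = function(e) {
      dplyr::mutate(cell, n_samples = NA_integer_, d = NA_integer_,
                    test_mae = NA_real_, skipped = TRUE,
                    reason = conditionMessage(e))
    })
    res
  })
}
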