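#' Plot a session overview
#'
#' Down-sampled traces of the vertical acceleration, ECG and GPS altitude,
#' with the ground-truth fatigue trajectory overlaid.
#'
#' @param object A `sensor_session`.
#' @param max_points Maximum points per panel (down-sampling stride chosen
#'   accordingly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensor_session <- function(object, max_points = 4000, ...) {
  thin <- function(df) df[seq(1, nrow(df), by = max(1, nrow(df) %/% max_points)), ]
  panels <- dplyr::bind_rows(
    thin(object$accel) |>
      dplyr::transmute(time = .data$time, value = .data$x,
                       panel = "vertical accel (g)"),
    thin(object$ecg) |>
      dplyr::transmute(time = .data$time, value = .data$ecg,
                       panel = "ECG (mV)"),
    thin(object$gps) |>
      dplyr::transmute(time = .data$time, value = .data$alt,
                       panel = "altitude (m)"),
    tibble::tibble(time = object$truth$t, value = object$truth$fatigue,
                   panel = "true fatigue")
  )
  ggplot2::ggplot(panels, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "protocol time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuous fatigue label with its source observations
#'
#' @param object A `fatigue_label`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fatigue_label <- function(object, ...) {
  stride <- max(1, length(object$values) %/% 4000)
  df <- tibble::tibble(
    time = (seq(1, length(object$values), by = stride) - 1) / object$rate_hz,
    value = object$values[seq(1, length(object$values), by = stride)]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(
      data = object$observations,
      ggplot2::aes(.data$time, .data$norm), colour = "black", size = 2
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "protocol time (s)", y = "normalized performance",
                  title = sprintf("%s label from %s", object$method,
                                  object$source_test)) +
    ggplot2::theme_minimal()
}

#' Plot the training-loss trace of a fitted network
#'
#' @param object A `fatigue_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fatigue_cnn <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(.data$epoch, .data$train_mae)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training MAE") +
    ggplot2::theme_minimal()
}

#' Prediction trace plot for an evaluated activity
#'
#' Time-ordered test-window labels (red), raw per-window predictions
#' (grey) and the rolled prediction (black) — the standard way to inspect
#' how the smoothed estimate tracks the fatigue label.
#'
#' @param object An `eval_result` from [evaluate_activity()] (must carry
#'   its `"detail"` attribute, i.e. not an excluded activity).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_result <- function(object, ...) {
  detail <- attr(object, "detail")
  if (is.null(detail)) {
    abort("No prediction detail attached (activity excluded?).",
          class = "ff_eval_error")
  }
  detail <- dplyr::mutate(detail, idx = dplyr::row_number())
  ggplot2::ggplot(detail, ggplot2::aes(.data$idx)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$.pred), colour = "grey70",
                        size = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rolled), colour = "black",
                       na.rm = TRUE) +
    ggplot2::labs(
      x = "test window (time order)", y = "normalized performance",
      title = sprintf("%s / %s: MAE%d = %.3f, RAE%d = %.3f",
                      object$activity, object$label_method, object$k,
                      object$mae_k, object$k, object$rae_k)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eval_result
#' @export
plot_predictions <- function(object, ...) autoplot.eval_result(object, ...)
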