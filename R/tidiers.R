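#' Tidy the training trace of a fitted network
#'
#' @param x A `fatigue_cnn`.
#' @param ... Unused.
#' @return Tibble `epoch`, `train_mae`.
#' @export
tidy.fatigue_cnn <- function(x, ...) x$loss_trace

#' One-row summary of a fitted network
#'
#' @param x A `fatigue_cnn`.
#' @param ... Unused.
#' @return Tibble with topology, parameter count, epochs and final
#'   training MAE.
#' @export
glance.fatigue_cnn <- function(x, ...) {
  tibble::tibble(
    conv1_filters = x$spec$conv1_filters,
    conv2_filters = x$spec$conv2_filters,
    dense_width = x$spec$dense_width,
    kernel_size = x$spec$kernel_size,
    width = x$width,
    n_channels = x$n_channels,
    n_parameters = sum(vapply(x$par, length, integer(1))),
    epochs = x$spec$epochs,
    final_train_mae = tail(x$loss_trace$train_mae, 1)
  )
}

#' Tidy a continuous fatigue label
#'
#' @param x A `fatigue_label`.
#' @param ... Unused.
#' @return The normalized source observations (`time`, `score`, `norm`).
#' @export
tidy.fatigue_label <- function(x, ...) x$observations

#' One-row summary of a fatigue label
#'
#' @param x A `fatigue_label`.
#' @param ... Unused.
#' @return Tibble with method, source test, length, rate, range, and (for
#'   LTLF) the fitted slope and R-squared.
#' @export
glance.fatigue_label <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    source_test = x$source_test,
    n = length(x$values),
    rate_hz = x$rate_hz,
    min = min(x$values),
    max = max(x$values),
    slope = if (is.null(x$fit)) NA_real_ else x$fit$slope,
    r2 = if (is.null(x$fit)) NA_real_ else x$fit$r2
  )
}
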