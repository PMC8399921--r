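#' CNN specification
#'
#' Hyperparameters of the multi-channel 1-D convolutional regression
#' network: two same-padded convolution layers (ReLU), max-pooling over
#' time, a flatten, one ReLU dense layer and a single linear output.
#' Training uses the Adam optimizer with mean absolute error as the loss.
#'
#' The default is a desk-scale topology that trains in seconds on a CPU.
#' Two study-scale presets are provided: [cnn_spec_initial()] (the sweep
#' topology: 256/256 filters, dense 128, 50 epochs) and [cnn_spec_final()]
#' (the optimized topology: 128/128 filters, dense 128, 100 epochs).
#'
#' @param conv1_filters,conv2_filters Filters in the two conv layers.
#' @param dense_width Width of the hidden dense layer.
#' @param kernel_size Convolution kernel length in samples (odd).
#' @param pool Apply max-pooling (size 2) after the second conv layer.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(conv1_filters = 16, conv2_filters = 16,
                     dense_width = 32, kernel_size = 7, pool = TRUE,
                     epochs = 30, batch_size = 256, learning_rate = 1e-3) {
  stopifnot(conv1_filters > 0, conv2_filters > 0, dense_width > 0,
            kernel_size %% 2 == 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(
    list(conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         dense_width = as.integer(dense_width),
         kernel_size = as.integer(kernel_size), pool = pool,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate),
    class = "cnn_spec"
  )
}

#' @rdname cnn_spec
#' @param ... Overrides passed to [cnn_spec()].
#' @export
cnn_spec_initial <- function(...) {
  spec <- cnn_spec(conv1_filters = 256, conv2_filters = 256,
                   dense_width = 128, epochs = 50, batch_size = 256)
  utils::modifyList(spec, list(...))
}

#' @rdname cnn_spec
#' @export
cnn_spec_final <- function(...) {
  spec <- cnn_spec(conv1_filters = 128, conv2_filters = 128,
                   dense_width = 128, epochs = 100, batch_size = 256)
  utils::modifyList(spec, list(...))
}

# ---- internal layers -------------------------------------------------------

# im2col for 1-D same-padded convolution: input array (B, W, C) -> matrix
# (B*W, K*C); column (c-1)*K + k holds input position t + k - 1 (padded) for
# output position t.
im2col1d <- function(x, k) {
  d <- dim(x)
  .ff_im2col(x, d[1], d[2], d[3], k)
}

# scatter-add of im2col gradients back onto the (B, W, C) input
col2im1d <- function(dcol, b, w, cc, k) {
  .ff_col2im(dcol, b, w, cc, k)
}

cnn_init <- function(spec, width, f, seed) {
  k <- spec$kernel_size
  w2 <- if (spec$pool) width %/% 2L else width
  flat <- w2 * spec$conv2_filters
  withr::with_seed(seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    list(
      W1 = he(k * f, spec$conv1_filters), b1 = numeric(spec$conv1_filters),
      W2 = he(k * spec$conv1_filters, spec$conv2_filters),
      b2 = numeric(spec$conv2_filters),
      Wd1 = he(flat, spec$dense_width), bd1 = numeric(spec$dense_width),
      Wd2 = he(spec$dense_width, 1), bd2 = 0
    )
  })
}

cnn_forward <- function(par, spec, x, keep_cache = FALSE) {
  b <- dim(x)[1]; w <- dim(x)[2]; f <- dim(x)[3]
  k <- spec$kernel_size
  c1 <- im2col1d(x, k)
  a1 <- c1 %*% par$W1
  .ff_bias_relu(a1, par$b1)              # in place: a1 = relu(z1)
  a1_arr <- a1; dim(a1_arr) <- c(b, w, spec$conv1_filters)
  c2 <- im2col1d(a1_arr, k)
  a2 <- c2 %*% par$W2
  .ff_bias_relu(a2, par$b2)
  if (spec$pool) {
    pl <- .ff_maxpool2(a2, b, w, spec$conv2_filters)
    mask_odd <- pl$mask
    flat <- pl$pooled; dim(flat) <- c(b, (w %/% 2) * spec$conv2_filters)
  } else {
    flat <- a2; dim(flat) <- c(b, w * spec$conv2_filters)
    mask_odd <- NULL
  }
  ad1 <- flat %*% par$Wd1
  .ff_bias_relu(ad1, par$bd1)
  yhat <- as.numeric(ad1 %*% par$Wd2 + par$bd2)
  if (!keep_cache) return(yhat)
  list(yhat = yhat, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
       flat = flat, mask_odd = mask_odd, ad1 = ad1,
       b = b, w = w, f = f)
}

cnn_backward <- function(par, spec, cache, dy) {
  b <- cache$b; w <- cache$w; f <- cache$f; k <- spec$kernel_size
  g <- list()
  # output layer
  dy <- matrix(dy, ncol = 1)
  g$Wd2 <- crossprod(cache$ad1, dy)
  g$bd2 <- sum(dy)
  dad1 <- dy %*% t(par$Wd2)
  dzd1 <- dad1 * (cache$ad1 > 0)   # relu mask from post-activation
  g$Wd1 <- crossprod(cache$flat, dzd1)
  g$bd1 <- colSums(dzd1)
  dflat <- dzd1 %*% t(par$Wd1)
  # un-flatten / un-pool
  if (spec$pool) {
    dpool <- dflat; dim(dpool) <- c(b * (w %/% 2L), spec$conv2_filters)
    da2 <- .ff_unpool2(dpool, cache$mask_odd, b, w, spec$conv2_filters)
  } else {
    da2 <- dflat; dim(da2) <- c(b * w, spec$conv2_filters)
  }
  dz2 <- da2 * (cache$a2 > 0)
  g$W2 <- crossprod(cache$c2, dz2)
  g$b2 <- colSums(dz2)
  dc2 <- dz2 %*% t(par$W2)
  da1_arr <- col2im1d(dc2, b, w, spec$conv1_filters, k)
  da1 <- da1_arr; dim(da1) <- c(b * w, spec$conv1_filters)
  dz1 <- da1 * (cache$a1 > 0)
  g$W1 <- crossprod(cache$c1, dz1)
  g$b1 <- colSums(dz1)
  g
}

adam_step <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the 1-D CNN fatigue regressor
#'
#' Trains the multi-channel convolutional network on a scaled windowed
#' dataset with the Adam optimizer and mean absolute error loss.  All
#' randomness (weight initialization, minibatch shuffling) flows from
#' `seed`.  The per-epoch loss trace records the MAE over the full training
#' set after each epoch.
#'
#' @param train A `windowed_dataset` (scale it first with
#'   [fit_window_scaling()] / [apply_window_scaling()]).
#' @param spec A [cnn_spec()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return A `fatigue_cnn` object: weights, `spec`, `loss_trace` tibble
#'   (`epoch`, `train_mae`), input geometry and `seed`.
#' @export
train_cnn <- function(train, spec = cnn_spec(), seed = 1, verbose = FALSE) {
  stopifnot(inherits(train, "windowed_dataset"), inherits(spec, "cnn_spec"))
  d <- dim(train$X)[1]; w <- dim(train$X)[2]; f <- dim(train$X)[3]
  if (d == 0) abort("Empty training set.", class = "ff_train_error")
  if (spec$pool && w %% 2 != 0) {
    abort("Window width must be even when pooling.", class = "ff_train_error")
  }
  par <- cnn_init(spec, w, f, seed)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  step <- 0
  trace <- numeric(spec$epochs)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(d)
      ep_abs <- 0
      for (start in seq(1, d, by = spec$batch_size)) {
        bi <- ord[start:min(start + spec$batch_size - 1, d)]
        xb <- train$X[bi, , , drop = FALSE]
        yb <- train$y[bi]
        cache <- cnn_forward(par, spec, xb, keep_cache = TRUE)
        resid <- cache$yhat - yb
        loss <- mean(abs(resid))
        if (!is.finite(loss)) {
          abort(sprintf("Non-finite loss at epoch %d; reduce learning rate.",
                        ep),
                class = "ff_train_error")
        }
        ep_abs <- ep_abs + sum(abs(resid))
        grads <- cnn_backward(par, spec, cache, sign(resid) / length(bi))
        step <- step + 1
        upd <- adam_step(par, grads, state, spec$learning_rate, step)
        par <- upd$par
        state <- upd$state
      }
      # epoch loss: running mean over minibatches (each window once)
      trace[ep] <- ep_abs / d
      if (verbose) {
        message(sprintf("epoch %3d  train MAE %.4f", ep, trace[ep]))
      }
    }
  })
  final_mae <- mean(abs(cnn_predict_raw(par, spec, train$X) - train$y))
  structure(
    list(par = par, spec = spec,
         loss_trace = tibble::tibble(epoch = seq_len(spec$epochs),
                                     train_mae = trace),
         final_train_mae = final_mae,
         width = w, n_channels = f, channel_names = train$channel_names,
         seed = seed),
    class = "fatigue_cnn"
  )
}

cnn_predict_raw <- function(par, spec, X, chunk = 1024L) {
  d <- dim(X)[1]
  if (d == 0) return(numeric(0))
  out <- numeric(d)
  for (start in seq(1, d, by = chunk)) {
    ii <- start:min(start + chunk - 1, d)
    out[ii] <- cnn_forward(par, spec, X[ii, , , drop = FALSE])
  }
  out
}

#' Predict fatigue for a windowed dataset
#'
#' One prediction per window, returned in time order (by window start
#' time), which is the order rolling-average evaluation expects.
#'
#' @param object A `fatigue_cnn`.
#' @param newdata A `windowed_dataset` with matching `(W, F)`, or a bare
#'   `(D, W, F)` array.
#' @param ... Unused.
#' @return For a dataset: a tibble `activity`, `start_s`, `order`, `y`
#'   (window label), `.pred`, sorted by `start_s`.  For an array: a numeric
#'   vector in row order.
#' @export
predict.fatigue_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "windowed_dataset")) {
    X <- newdata$X
  } else {
    X <- newdata
  }
  if (length(dim(X)) != 3 || dim(X)[2] != object$width ||
      dim(X)[3] != object$n_channels) {
    abort(sprintf("Input shape (%s) does not match the model (W=%d, F=%d).",
                  paste(dim(X), collapse = ", "), object$width,
                  object$n_channels),
          class = "ff_predict_error")
  }
  preds <- cnn_predict_raw(object$par, object$spec, X)
  if (!inherits(newdata, "windowed_dataset")) return(preds)
  newdata$meta |>
    dplyr::mutate(y = newdata$y, .pred = preds) |>
    dplyr::arrange(.data$start_s)
}

#' @export
print.fatigue_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf(
    "<fatigue_cnn> conv %d/%d k=%d, dense %d, W=%d, F=%d (%d params)\n  final train MAE %.4f after %d epochs\n",
    x$spec$conv1_filters, x$spec$conv2_filters, x$spec$kernel_size,
    x$spec$dense_width, x$width, x$n_channels, n_par,
    tail(x$loss_trace$train_mae, 1), nrow(x$loss_trace)
  ))
  invisible(x)
}
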