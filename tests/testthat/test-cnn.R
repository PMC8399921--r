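make_toy <- function(d, w = 16, f = 2, seed = 1,
                     rule = function(X) rowMeans(X[, , 1])) {
  withr::with_seed(seed, {
    X <- array(runif(d * w * f), dim = c(d, w, f))
    structure(
      list(X = X, y = rule(X),
           meta = tibble::tibble(activity = "toy", start_s = seq_len(d),
                                 order = seq_len(d)),
           width = as.integer(w), channel_names = paste0("ch", seq_len(f)),
           scaled = TRUE, scaling = NULL),
      class = "windowed_dataset"
    )
  })
}

test_that("analytic gradients match finite differences", {
  spec <- cnn_spec(conv1_filters = 3, conv2_filters = 4, dense_width = 5,
                   kernel_size = 3)
  withr::with_seed(2, {
    X <- array(runif(6 * 8 * 2), dim = c(6, 8, 2))
    y <- runif(6)
  })
  par <- fieldfatigue:::cnn_init(spec, 8, 2, seed = 3)
  # jitter the zero-initialized biases: with b = 0 exactly, convolution
  # positions fed only by dead (all-zero) activations sit exactly on the
  # ReLU kink, where finite differences measure a subgradient instead
  withr::with_seed(4, {
    for (nm in c("b1", "b2", "bd1")) {
      par[[nm]] <- par[[nm]] + rnorm(length(par[[nm]]), 0, 0.05)
    }
  })
  loss <- function(p) mean((fieldfatigue:::cnn_forward(p, spec, X) - y)^2)
  cache <- fieldfatigue:::cnn_forward(par, spec, X, keep_cache = TRUE)
  grads <- fieldfatigue:::cnn_backward(par, spec, cache,
                                       2 * (cache$yhat - y) / 6)
  eps <- 1e-6
  for (nm in names(grads)) {
    n_check <- min(10, length(par[[nm]]))
    for (ii in seq_len(n_check)) {
      p2 <- par
      p2[[nm]][ii] <- par[[nm]][ii] + eps
      p3 <- par
      p3[[nm]][ii] <- par[[nm]][ii] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]])[ii], num, tolerance = 1e-3)
    }
  }
})

test_that("a constant label is learned to high precision", {
  ds <- make_toy(50, rule = function(X) rep(0.6, dim(X)[1]))
  m <- train_cnn(ds, cnn_spec(conv1_filters = 4, conv2_filters = 4,
                              dense_width = 8, epochs = 100,
                              batch_size = 50, learning_rate = 5e-3),
                 seed = 5)
  expect_lt(m$final_train_mae, 0.02)
})

test_that("training loss decreases on learnable structure", {
  ds <- make_toy(120, seed = 7)
  m <- train_cnn(ds, cnn_spec(conv1_filters = 8, conv2_filters = 8,
                              dense_width = 16, epochs = 40,
                              batch_size = 64), seed = 6)
  tr <- tidy(m)
  expect_lt(tail(tr$train_mae, 1), tr$train_mae[1])
  expect_equal(nrow(tr), 40)
  # glance reports the topology
  g <- glance(m)
  expect_equal(g$epochs, 40L)
  expect_equal(g$n_channels, 2L)
})

test_that("training is deterministic under a fixed seed", {
  ds <- make_toy(60, seed = 9)
  spec <- cnn_spec(conv1_filters = 4, conv2_filters = 4, dense_width = 8,
                   epochs = 5, batch_size = 32)
  m1 <- train_cnn(ds, spec, seed = 11)
  m2 <- train_cnn(ds, spec, seed = 11)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$loss_trace, m2$loss_trace)
})

test_that("predictions are consistent, ordered and shape-checked", {
  ds <- make_toy(40, seed = 13)
  spec <- cnn_spec(conv1_filters = 4, conv2_filters = 4, dense_width = 8,
                   epochs = 10, batch_size = 32)
  m <- train_cnn(ds, spec, seed = 12)
  pr <- predict(m, ds)
  # MAE over training windows equals the recorded final training MAE
  expect_equal(mean(abs(pr$.pred - pr$y)), m$final_train_mae,
               tolerance = 1e-10)
  # deterministic given fixed weights
  expect_identical(pr$.pred, predict(m, ds)$.pred)
  # time order even when metadata is scrambled
  shuffled <- fieldfatigue:::subset_windows(ds, sample(40))
  expect_true(all(diff(predict(m, shuffled)$start_s) > 0))
  # empty input -> empty output
  empty <- fieldfatigue:::subset_windows(ds, integer(0))
  expect_equal(nrow(predict(m, empty)), 0)
  # shape mismatch is an error
  bad <- array(0, dim = c(3, 8, 2))
  expect_error(predict(m, bad), class = "ff_predict_error")
})

test_that("shuffled labels cannot beat a constant predictor", {
  # permutation-null oracle: with labels shuffled there is no signal, so
  # test MAE sits at the uninformative-constant floor (the label median,
  # which MAE-trained models converge to)
  ds <- make_toy(150, seed = 15)
  parts <- split_train_test(ds, 0.33, seed = 16)
  gaps <- vapply(1:3, function(i) {
    tr <- parts$train
    tr$y <- withr::with_seed(20 + i, sample(tr$y))
    m <- train_cnn(tr, cnn_spec(conv1_filters = 4, conv2_filters = 4,
                                dense_width = 8, epochs = 15,
                                batch_size = 64), seed = 30 + i)
    pr <- predict(m, parts$test)
    mean(abs(pr$.pred - pr$y)) -
      baseline_mae(tr$y, parts$test$y, statistic = "median")
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 2 * max(sd(gaps), 0.01))
})
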