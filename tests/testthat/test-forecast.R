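test_that("windowing produces exactly length - n chronological pairs", {
  wd <- make_windows(1:10, 7)
  expect_equal(ncol(wd$inputs), 3L)
  expect_equal(wd$inputs[, 1], 1:7)
  expect_equal(wd$targets, 8:10)
  expect_error(make_windows(1:7, 7), "longer than")
  cw <- make_windows(rep(2.5, 12), 7)
  expect_true(all(cw$targets == 2.5))
  # no-leakage: truncating the series yields exactly the leading windows
  s <- sin(seq(0, 4, length.out = 25))
  full <- make_windows(s, 5)
  head_only <- make_windows(s[1:15], 5)
  expect_equal(head_only$inputs, full$inputs[, 1:10])
  expect_equal(head_only$targets, full$targets[1:10])
})

test_that("backpropagation gradients match finite differences", {
  set.seed(42)
  X <- matrix(rnorm(5 * 6), 5, 6)
  y <- rnorm(6)
  for (arch in c("rnn", "gru", "lstm")) {
    p <- metalrisk:::init_params(arch, 3, init = "random")
    fg <- metalrisk:::rnn_loss_grad(p, arch, X, y)
    th <- metalrisk:::flatten_params(p)
    g <- metalrisk:::flatten_params(fg$grads)
    idx <- sample(length(th), min(20, length(th)))  # spot-check subset
    num <- vapply(idx, function(i) {
      e <- 1e-6
      tp <- th; tp[i] <- tp[i] + e
      tm <- th; tm[i] <- tm[i] - e
      (metalrisk:::rnn_loss_grad(
         metalrisk:::unflatten_params(tp, p), arch, X, y)$loss -
       metalrisk:::rnn_loss_grad(
         metalrisk:::unflatten_params(tm, p), arch, X, y)$loss) / (2 * e)
    }, numeric(1))
    expect_equal(g[idx], num, tolerance = 1e-6)
  }
})

test_that("training is deterministic and converges on simple series", {
  s <- rep(0.5, 40)
  for (arch in c("rnn", "gru", "lstm")) {
    m1 <- recurrent_forecaster(s, arch, window_n = 7, hidden = 8,
                               epochs = 100, seed = 3)
    m2 <- recurrent_forecaster(s, arch, window_n = 7, hidden = 8,
                               epochs = 100, seed = 3)
    expect_identical(m1$params, m2$params)
    expect_lt(abs(predict_step(m1, rep(0.5, 7)) - 0.5), 0.05)
  }
  # linear ramp: one-step error far below a mean-only predictor's variance
  ramp <- seq(0, 1, length.out = 50)
  mr <- recurrent_forecaster(ramp, "gru", window_n = 7, hidden = 8,
                             epochs = 150, seed = 4)
  wd <- make_windows(ramp, 7)
  pred <- predict_step(mr, wd$inputs)
  expect_lt(mean((pred - wd$targets)^2), var(wd$targets) / 10)
})

test_that("the persistence-prior initialization starts near the identity", {
  for (arch in c("rnn", "gru", "lstm")) {
    set.seed(6)
    p <- metalrisk:::init_params(arch, 16, init = "persistence")
    m <- structure(list(params = p, architecture = arch, window_n = 7,
                        hidden = 16), class = "recurrent_forecaster")
    x <- seq(0.05, 0.95, by = 0.15)
    for (v in x) {
      w <- c(runif(6), v)
      expect_lt(abs(predict_step(m, w) - v), 0.06)
    }
  }
})

test_that("recursive forecasting matches a hand-rolled recursion", {
  # 0.5-contraction one-step model: exact geometric sequence
  halver <- structure(list(window_n = 3), class = "halver_model")
  registerS3method("predict_step", "halver_model",
                   function(model, window) {
                     X <- if (is.matrix(window)) window else
                       matrix(window, ncol = 1)
                     0.5 * X[nrow(X), ]
                   },
                   envir = asNamespace("metalrisk"))
  expect_identical(recursive_forecast(halver, c(0.3, 0.7, 1.0), 3),
                   c(0.5, 0.25, 0.125))
  expect_identical(recursive_forecast(halver, c(0, 0, 1.0), 8),
                   0.5^(1:8))
  expect_identical(recursive_forecast(halver, c(0, 0, 1), 0), numeric(0))
  expect_error(recursive_forecast(halver, c(1, 2), 3), "history length")
  # persistence is a fixpoint of the recursion
  pm <- persistence_forecaster(4)
  expect_equal(recursive_forecast(pm, c(0.1, 0.9, 0.4, 0.7), 5),
               rep(0.7, 5))
  # trained model: recursion agrees with manually iterating predict_step
  set.seed(10)
  s <- as.numeric(arima.sim(list(ar = 0.8), 60)) / 5 + 0.5
  m <- recurrent_forecaster(s, "rnn", window_n = 7, hidden = 8,
                            epochs = 50, seed = 2)
  fc <- recursive_forecast(m, s[54:60], 10)
  w <- s[54:60]
  hand <- numeric(10)
  for (i in 1:10) {
    hand[i] <- predict_step(m, w)
    w <- c(w[-1], hand[i])
  }
  expect_identical(fc, hand)
})

test_that("snapshots record the trajectory and are selectable", {
  m <- recurrent_forecaster(runif(30), "rnn", window_n = 5, hidden = 4,
                            epochs = 20, seed = 1, snapshot_every = 5)
  expect_equal(m$snapshot_epochs, c(0L, 5L, 10L, 15L, 20L))
  expect_length(m$snapshots, 5L)
  m0 <- select_snapshot(m, 1)
  expect_equal(m0$selected_epoch, 0L)
  expect_identical(m0$params, m$snapshots[[1]])
  # final snapshot equals the returned parameters
  expect_identical(m$snapshots[[5]], m$params)
})
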