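test_that("the simplex grid enumerates the stars-and-bars count", {
  g66 <- simplex_grid(3, 0.1)
  expect_equal(nrow(g66), choose(12, 2))       # 66
  g231 <- simplex_grid(3, 0.05)
  expect_equal(nrow(g231), choose(22, 2))      # 231
  expect_true(all(abs(rowSums(g231) - 1) < 1e-12))
  expect_true(all(g231 >= 0))
  expect_equal(nrow(unique(g231)), 231L)
  expect_error(simplex_grid(3, 0.3), "divide 1")
})

test_that("vote_combine is a pointwise convex combination", {
  f <- list(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_equal(vote_combine(f, c(0.5, 0.3, 0.2)), rep(1.7, 3))
  expect_equal(vote_combine(f, c(1, 0, 0)), f[[1]])
  same <- list(c(4, 5), c(4, 5), c(4, 5))
  expect_equal(vote_combine(same, c(0.2, 0.3, 0.5)), c(4, 5))
  expect_error(vote_combine(f, c(0.5, 0.5)), "one weight per")
  expect_error(vote_combine(f, c(0.7, 0.2, 0.2)), "sum to 1")
  expect_error(vote_combine(list(1:2, 1:3, 1:2), c(0.4, 0.3, 0.3)),
               "equal length")
  # order preservation: all sub-forecasts increase => combination increases
  lo <- list(c(1, 1), c(2, 1), c(0.5, 1))
  hi <- list(c(2, 1), c(3, 1), c(1.5, 1))
  w <- c(0.2, 0.5, 0.3)
  expect_gt(vote_combine(hi, w)[1], vote_combine(lo, w)[1])
})

test_that("error metrics match hand arithmetic and rmse >= mae", {
  expect_equal(rmse(1:3, 1:3), 0)
  expect_equal(mae(1:3, 1:3), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 1, 4)), 1)
  expect_equal(mae(c(1, 2, 3), c(2, 1, 4)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(0, 0), c(3, 4)), 3.53553, tolerance = 1e-5)
  expect_equal(mae(c(0, 0), c(3, 4)), 3.5)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(8); p <- rnorm(8)
    expect_gte(rmse(a, p), mae(a, p))
  }
})

test_that("prediction accuracy is the indicator mean", {
  expect_equal(prediction_accuracy(rep(1, 5)), 1)
  expect_equal(prediction_accuracy(rep(0, 5)), 0)
  expect_equal(prediction_accuracy(c(rep(1, 19), 0, 0)), 0.90476,
               tolerance = 1e-4)
  expect_error(prediction_accuracy(integer(0)), "no indicators")
})

test_that("level indicators compare classified forecast and actual", {
  mod <- reference_cluster_model()
  ctr <- reference_centers()
  expect_equal(level_indicator(rbind(ctr[2, ]), rbind(ctr[2, ]), mod), 1L)
  expect_equal(level_indicator(rbind(ctr[1, ]), rbind(ctr[4, ]), mod), 0L)
  # two different points both nearest the second center still agree
  p1 <- ctr[2, ] + c(0.01, 0, 0)
  p2 <- ctr[2, ] - c(0.01, 0, 0)
  d1 <- sqrt(colSums((t(ctr) - p1)^2))
  d2 <- sqrt(colSums((t(ctr) - p2)^2))
  expect_equal(which.min(d1), 2L)
  expect_equal(which.min(d2), 2L)
  expect_equal(level_indicator(rbind(p1), rbind(p2), mod), 1L)
})

test_that("weight optimization is grid-exhaustive with ordered tie-breaks", {
  mod <- reference_cluster_model()
  ctr <- reference_centers()
  actual <- ctr[c(1, 2, 3, 4, 2), ]
  # sub-model 1 reproduces the actuals exactly; the others are off
  sub <- list(actual,
              actual + 0.2,
              matrix(0.5, nrow(actual), 3))
  out <- optimize_weights(sub, actual, mod, grid_step = 0.1)
  expect_equal(out$n_candidates, 66L)
  expect_equal(out$pa, 1)
  expect_equal(out$pa_by_model[1], 1)
  # a vertex on the perfect model attains maximal accuracy
  expect_gte(out$pa, max(out$pa_by_model))
  # all-tie case: every candidate classifies identically, so the
  # mean-squared-error tie-break engages and prefers the closest model
  same <- list(actual + 0.01, actual + 0.02, actual + 0.02)
  out2 <- optimize_weights(same, actual, mod, grid_step = 0.5)
  expect_equal(unname(out2$weights), c(1, 0, 0))
  expect_error(optimize_weights(sub, actual[0, ], mod), "empty")
})

test_that("scoring reduces to sub-model rows under vertex weights", {
  mod <- reference_cluster_model()
  set.seed(17)
  actual <- matrix(runif(21 * 3), 21, 3,
                   dimnames = list(NULL, c("nipi", "tcr", "thq")))
  fc_a <- actual + rnorm(63, 0, 0.05)
  fc_b <- actual + rnorm(63, 0, 0.10)
  ens <- vote_combine(list(fc_a, fc_b), c(1, 0))  # vertex: equals fc_a
  sc <- score_forecasts(list(a = fc_a, b = fc_b, ensemble = ens),
                        actual, mod, horizons = c(7, 14, 21))
  err <- sc$errors
  for (h in c("7", "14", "21", "Avg")) {
    expect_equal(err[err$model == "ensemble" & err$horizon == h, c("rmse", "mae")],
                 err[err$model == "a" & err$horizon == h, c("rmse", "mae")],
                 ignore_attr = TRUE)
  }
  acc <- sc$accuracy
  expect_equal(acc$pa[acc$model == "ensemble"], acc$pa[acc$model == "a"])
  # a constant test series with persistence-style forecasts scores zero
  const <- matrix(0.4, 10, 3, dimnames = list(NULL, c("nipi", "tcr", "thq")))
  sc0 <- score_forecasts(list(p = const), const, mod, horizons = 7)
  expect_equal(sc0$errors$rmse[1], 0)
  expect_equal(sc0$accuracy$pa, 1)
  # compositional check: reported numbers equal direct metric calls
  expect_equal(err$rmse[err$model == "b" & err$horizon == "7" &
                          err$index == "nipi"],
               rmse(actual[1:7, 1], fc_b[1:7, 1]))
  expect_error(score_forecasts(list(a = fc_a), actual, mod, horizons = 22),
               "exceeds")
})
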