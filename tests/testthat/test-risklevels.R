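test_that("min-max normalization maps to [0,1] and inverts", {
  nm <- minmax_normalize(cbind(x = c(2, 4, 6)))
  expect_equal(as.vector(nm$points), c(0, 0.5, 1))
  ident <- minmax_normalize(cbind(x = c(0, 0.3, 1)))
  expect_equal(as.vector(ident$points), c(0, 0.3, 1))
  expect_error(minmax_normalize(cbind(x = c(1, 1, 1))), "constant")
  set.seed(8)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  nm2 <- minmax_normalize(m)
  expect_equal(invert_bounds(nm2$points, nm2$bounds), m)
  expect_equal(apply_bounds(m, nm2$bounds), nm2$points)
})

test_that("k-means++ seeding favors distant points and is reproducible", {
  # two coincident points plus one far point: the far point must be the
  # second seed with probability d^2 / sum d^2 -> 1 as separation grows
  pts <- rbind(c(0, 0), c(0, 0), c(100, 0))
  set.seed(1)
  far_second <- replicate(50, {
    ctr <- kmeanspp_seed(pts, 2)
    any(ctr[, 1] == 100) && any(ctr[, 1] == 0)
  })
  expect_true(all(far_second))
  expect_error(kmeanspp_seed(pts, 3), "distinct")
  set.seed(42); a <- kmeanspp_seed(matrix(runif(20), 10), 3)
  set.seed(42); b <- kmeanspp_seed(matrix(runif(20), 10), 3)
  expect_identical(a, b)
})

test_that("k-means fit matches the exhaustive optimum on tiny instances", {
  # two well-separated triplets
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
               c(5, 5), c(5.1, 5), c(5, 5.1))
  fit <- kmeans_fit(pts, 2, n_restarts = 10, seed = 1)
  expect_equal(fit$wcss, enum_wcss(pts, 2))
  expect_equal(length(unique(fit$labels[1:3])), 1L)
  expect_equal(length(unique(fit$labels[4:6])), 1L)
  # k = n: every point its own center, zero wcss
  fit_n <- kmeans_fit(pts, 6, n_restarts = 5, seed = 2)
  expect_equal(fit_n$wcss, 0)
  # wcss trace of the winning run is non-increasing
  set.seed(30)
  for (i in 1:10) {
    x <- matrix(runif(24), 12, 2)
    f <- kmeans_fit(x, 3, n_restarts = 5)
    expect_true(all(diff(f$trace) <= 1e-12))
  }
})

test_that("silhouette matches hand evaluation and the cluster package", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  sil <- silhouette_score(pts, lab)
  expect_equal(sil$avg, 0.990, tolerance = 1e-3)
  # hand values: a = 0.1; b = 10.05 (near pair), 9.95 (far pair)
  expect_equal(sil$s[1], (10.05 - 0.1) / 10.05)
  expect_equal(sil$s[3], (9.95 - 0.1) / 9.95)
  # cross-check against the cluster package on a random instance
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  l <- rep(1:2, each = 10)
  ref <- mean(cluster::silhouette(l, dist(x))[, "sil_width"])
  expect_equal(silhouette_score(x, l)$avg, ref)
  # perfectly mixed clusters (identical composition) score non-positive
  mixed <- matrix(rep(c(0, 1), 4), ncol = 1)
  expect_lte(silhouette_score(mixed, rep(1:2, each = 4))$avg, 0)
  # singleton-cluster members get s = 0 by convention
  s3 <- silhouette_score(matrix(c(0, 0.1, 5), ncol = 1), c(1L, 1L, 2L))
  expect_equal(s3$s[3], 0)
  expect_error(silhouette_score(pts, rep(1L, 4)), "2 clusters")
})

test_that("the cluster count maximizing average silhouette is selected", {
  scores <- c(`3` = 0.37741, `4` = 0.38230, `5` = 0.36543,
              `6` = 0.36067, `7` = 0.30792)
  expect_equal(select_k(scores)$k, 4L)
  # ties resolve to the smaller k
  expect_equal(select_k(c(`3` = 0.5, `5` = 0.5, `4` = 0.2))$k, 3L)
  # recovers the true count on well-separated synthetic groups
  set.seed(14)
  blob <- function(mx, my) cbind(rnorm(20, mx, 0.6), rnorm(20, my, 0.6))
  x <- rbind(blob(0, 0), blob(5, 5), blob(0, 10), blob(10, 0))
  expect_equal(select_k(x, 2:6, n_restarts = 5)$k, 4L)
})

test_that("centers are ordered into risk levels by distance to origin", {
  lv <- order_levels(reference_centers())
  expect_equal(lv$norm,
               c(0.21133483, 0.41548066, 0.72480507, 0.73673754),
               tolerance = 1e-6)
  expect_equal(as.character(lv$level),
               c("Low-Risk", "Medium-Risk", "Second-Highest Risk",
                 "High-Risk"))
  expect_true(all(diff(lv$norm) > 0))
  # ties on the norm break lexicographically on coordinates
  sph <- rbind(c(0, 1), c(1, 0))
  lv2 <- order_levels(sph)
  expect_equal(lv2$cluster, c(1L, 2L))   # (0,1) before (1,0)
  # generic names away from k = 4
  expect_equal(as.character(order_levels(rbind(c(0, 0), c(1, 1)))$level),
               c("Level 1", "Level 2"))
})

test_that("classification assigns the nearest center, ties to lower risk", {
  mod <- reference_cluster_model()
  # each fitted center classifies to its own level at distance 0
  pr <- predict(mod, mod$centers, normalized = TRUE)
  expect_equal(as.character(pr$level),
               as.character(mod$level_order$level[
                 match(1:4, mod$level_order$cluster)]))
  expect_equal(pr$distance, rep(0, 4), tolerance = 1e-6)
  # hand-verified nearest center for a low point
  p <- c(0.1, 0.1, 0.2)
  d <- sqrt(colSums((t(reference_centers()) - p)^2))
  expect_equal(which.min(d), 1L)
  expect_equal(as.character(predict(mod, rbind(p),
                                    normalized = TRUE)$level), "Low-Risk")
  # equidistant point between two centers goes to the lower-risk level
  two <- structure(list(k = 2, centers = rbind(c(0, 0), c(1, 0)),
                        bounds = rbind(min = c(0, 0), max = c(1, 1)),
                        level_order = order_levels(rbind(c(0, 0), c(1, 0)))),
                   class = "risk_clusters")
  eq <- predict(two, rbind(c(0.5, 0)), normalized = TRUE)
  expect_equal(as.character(eq$level), "Level 1")
})

test_that("level distributions count proportions that sum to one", {
  labs <- factor(c("L", "L", "M", "H"), levels = c("L", "M", "SH", "H"))
  d <- level_distribution(labs)
  expect_equal(unname(d), c(0.5, 0.25, 0, 0.25))
  expect_equal(sum(d), 1)
  expect_equal(unname(level_distribution(factor(rep("L", 3)))), 1)
  expect_error(level_distribution(factor(character(0))), "empty")
})

test_that("the fitted model classifies its own training days consistently", {
  comp <- toy_comprehensive(40)
  mod <- risk_clusters(comp, k = 3, seed = 5)
  pr <- predict(mod, comp)
  expect_equal(as.character(pr$level), as.character(mod$levels))
  # serialization round trip preserves classification behavior
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_clusters(mod, path)
  mod2 <- read_risk_clusters(path)
  expect_equal(as.character(predict(mod2, comp)$level),
               as.character(pr$level))
})
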