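# Data-driven risk-level classification.
#
# The comprehensive (NIPI, TCR, THQ) series is min-max normalized to
# [0,1]^3, clustered with K-means++ (Lloyd iterations from
# distance-squared-weighted seeds, best of several restarts), the number of
# clusters selected by the average silhouette coefficient, and the fitted
# centers ordered into risk levels by their Euclidean distance to the
# origin: a day far from the origin in index space carries more integrated
# risk.  New days (including forecasts) are classified by nearest center.

risk_level_names <- function(k) {
  if (k == 4L) c("Low-Risk", "Medium-Risk", "Second-Highest Risk",
                 "High-Risk")
  else paste("Level", seq_len(k))
}

#' Min-max normalization with stored bounds
#'
#' Maps each column of the comprehensive series to [0, 1] via
#' `(x - min) / (max - min)`, keeping the bounds so that forecasts can be
#' normalized identically and results inverse-transformed.
#'
#' @param x Numeric matrix or the comprehensive data frame (columns `nipi`,
#'   `tcr`, `thq`; a `date` column is carried through as rownames).
#' @return List with `points` (normalized matrix) and `bounds`
#'   (2 x p matrix of min / max per column).
#' @export
minmax_normalize <- function(x) {
  if (is.data.frame(x)) {
    rn <- if ("date" %in% names(x)) as.character(x$date) else rownames(x)
    x <- as.matrix(x[, intersect(c("nipi", "tcr", "thq"), names(x)),
                     drop = FALSE])
    rownames(x) <- rn
  }
  if (nrow(x) < 2L) stop("need at least 2 rows to normalize")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (any(hi <= lo))
    stop("constant column(s): ",
         paste(colnames(x)[hi <= lo], collapse = ", "))
  pts <- sweep(sweep(x, 2, lo), 2, hi - lo, "/")
  list(points = pts, bounds = rbind(min = lo, max = hi))
}

#' Apply / invert stored normalization bounds
#'
#' @param x Matrix of raw (or normalized, for the inverse) values.
#' @param bounds Bounds matrix from [minmax_normalize()].
#' @return Matrix on the normalized (or original) scale.
#' @export
apply_bounds <- function(x, bounds) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, bounds["min", ]), 2,
        bounds["max", ] - bounds["min", ], "/")
}

#' @rdname apply_bounds
#' @export
invert_bounds <- function(x, bounds) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, bounds["max", ] - bounds["min", ], "*"), 2,
        bounds["min", ], "+")
}

# Squared Euclidean distance from each row of x to each row of centers.
dist2_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

#' K-means++ seeding
#'
#' Chooses `k` initial centers from the sample rows: the first uniformly at
#' random, each subsequent one with probability proportional to the squared
#' distance to the nearest already-chosen center.
#'
#' @param points Numeric matrix, one row per sample.
#' @param k Number of centers.
#' @return `k x p` matrix of initial centers (rows of `points`).
#' @export
kmeanspp_seed <- function(points, k) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (k > n_distinct) stop("k exceeds the number of distinct points")
  idx <- integer(k)
  idx[1L] <- sample.int(nrow(points), 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(points, 2, points[idx[1L], ])^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      idx[j] <- sample.int(nrow(points), 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(points, 2, points[idx[j], ])^2))
    }
  }
  points[idx, , drop = FALSE]
}

# One Lloyd run from given centers; returns labels, centers, wcss,
# per-iteration wcss trace.  Empty clusters are re-seeded to the point
# farthest from its assigned center, keeping k fixed.
lloyd_run <- function(points, centers, max_iter = 100L, tol = 1e-10) {
  k <- nrow(centers)
  labels_prev <- rep(0L, nrow(points))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(points, centers)
    labels <- max.col(-d2, ties.method = "first")
    wcss <- sum(d2[cbind(seq_len(nrow(points)), labels)])
    trace <- c(trace, wcss)
    if (identical(labels, labels_prev)) break
    labels_prev <- labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        centers[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        far <- which.max(d2[cbind(seq_len(nrow(points)), labels)])
        centers[j, ] <- points[far, ]
        labels[far] <- j
      }
    }
  }
  d2 <- dist2_to_centers(points, centers)
  labels <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(nrow(points)), labels)])
  list(labels = labels, centers = centers, wcss = wcss,
       trace = c(trace, wcss))
}

#' Fit k-means with K-means++ seeding and restarts
#'
#' Runs Lloyd iterations from [kmeanspp_seed()] starts; keeps the solution
#' with the smallest within-cluster sum of squares over `n_restarts`
#' independent seedings.
#'
#' @param points Numeric matrix (rows = samples).
#' @param k Number of clusters (>= 1).
#' @param n_restarts Independent K-means++ seedings (default 10).
#' @param max_iter Maximum Lloyd iterations per run.
#' @param seed Optional integer seed for reproducible seeding.
#' @return List: `labels`, `centers`, `wcss`, `trace` (wcss per iteration of
#'   the winning run, non-increasing).
#' @export
kmeans_fit <- function(points, k, n_restarts = 10L, max_iter = 100L,
                       seed = NULL) {
  points <- as.matrix(points)
  if (k < 1L || nrow(points) < k) stop("need at least k points")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- lloyd_run(points, kmeanspp_seed(points, k), max_iter)
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  best
}

#' Silhouette coefficients
#'
#' Per-sample silhouette `s_j = (b_j - a_j) / max(a_j, b_j)` where `a_j` is
#' the mean distance to the other members of the sample's own cluster and
#' `b_j` the smallest mean distance to any other cluster.  Members of
#' singleton clusters get `s_j = 0` by convention.
#'
#' @param points Numeric matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return List: `s` per-sample scores, `avg` the average silhouette
#'   coefficient (in [-1, 1]).
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L) stop("silhouette needs at least 2 clusters")
  dm <- as.matrix(stats::dist(points))
  s <- vapply(seq_len(nrow(points)), function(j) {
    own <- labels == labels[j]
    n_own <- sum(own)
    if (n_own == 1L) return(0)
    a <- sum(dm[j, own]) / (n_own - 1L)
    b <- min(vapply(ulab[ulab != labels[j]], function(l)
      mean(dm[j, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  list(s = s, avg = mean(s))
}

#' Select the number of clusters by average silhouette
#'
#' @param x Either a numeric matrix of points (clusters are fitted for each
#'   candidate `k`) or a named numeric vector of precomputed average
#'   silhouette scores (names = k).
#' @param k_candidates Candidate cluster counts (default 3:7).
#' @param ... Passed to [kmeans_fit()] (e.g. `n_restarts`, `seed`).
#' @return List: `k` (argmax of average silhouette; ties go to the smaller
#'   k), `scores` named vector of average silhouettes.
#' @export
select_k <- function(x, k_candidates = 3:7, ...) {
  if (is.numeric(x) && !is.matrix(x) && !is.null(names(x))) {
    scores <- x
  } else {
    points <- as.matrix(x)
    scores <- vapply(k_candidates, function(k) {
      fit <- kmeans_fit(points, k, ...)
      silhouette_score(points, fit$labels)$avg
    }, numeric(1))
    names(scores) <- k_candidates
  }
  ks <- as.integer(names(scores))
  ord <- order(-scores, ks)      # max score, ties -> smaller k
  list(k = ks[ord[1L]], scores = scores)
}

#' Order cluster centers into risk levels
#'
#' Sorts centers by their Euclidean distance to the origin of the
#' normalized index space, ascending; a longer distance means a higher
#' integrated risk.  With four centers the levels are named Low-Risk,
#' Medium-Risk, Second-Highest Risk and High-Risk; otherwise generic
#' "Level i" names are used.  Ties in the norm are broken lexicographically
#' on the center coordinates.
#'
#' @param centers `k x p` matrix of cluster centers.
#' @return Data frame: `cluster` (original row index), `norm` (distance to
#'   origin), `level` (ordered factor, low to high risk).
#' @export
order_levels <- function(centers) {
  centers <- as.matrix(centers)
  norms <- sqrt(rowSums(centers^2))
  ord <- do.call(order, c(list(norms),
                          lapply(seq_len(ncol(centers)),
                                 function(j) centers[, j])))
  nm <- risk_level_names(nrow(centers))
  out <- data.frame(cluster = ord, norm = norms[ord],
                    level = factor(nm, levels = nm, ordered = TRUE))
  rownames(out) <- NULL
  out
}

#' Fit the risk-level cluster model
#'
#' End-to-end fit: min-max normalize the comprehensive series, select the
#' number of clusters by average silhouette (unless `k` is given), fit
#' K-means++ with restarts, and order the centers into risk levels by
#' distance to the origin.
#'
#' @param x Comprehensive series data frame (`date`, `nipi`, `tcr`, `thq`)
#'   or a numeric matrix of index values.
#' @param k Number of risk levels; `NULL` (default) selects it from
#'   `k_candidates` by silhouette.
#' @param k_candidates Candidate counts for selection (default 3:7).
#' @param n_restarts K-means++ restarts (default 10).
#' @param seed Integer seed governing all randomness of the fit.
#' @return Object of class `risk_clusters`: `k`, `centers` (normalized
#'   space), `bounds`, `level_order`, `silhouette_by_k`, `silhouette`,
#'   `labels`, `levels` (per training day), `wcss`, `seed`.
#' @export
risk_clusters <- function(x, k = NULL, k_candidates = 3:7,
                          n_restarts = 10L, seed = 1L) {
  norm <- minmax_normalize(x)
  pts <- norm$points
  if (!is.null(seed)) set.seed(seed)
  sil_by_k <- NULL
  if (is.null(k)) {
    sel <- select_k(pts, k_candidates, n_restarts = n_restarts)
    k <- sel$k
    sil_by_k <- sel$scores
  }
  fit <- kmeans_fit(pts, k, n_restarts = n_restarts)
  sil <- silhouette_score(pts, fit$labels)$avg
  lv <- order_levels(fit$centers)
  # per-day level labels
  level_of_cluster <- lv$level[match(seq_len(k), lv$cluster)]
  obj <- structure(list(
    k = k, centers = fit$centers, bounds = norm$bounds,
    level_order = lv, silhouette_by_k = sil_by_k, silhouette = sil,
    labels = fit$labels, levels = level_of_cluster[fit$labels],
    dates = rownames(pts), wcss = fit$wcss, seed = seed
  ), class = "risk_clusters")
  obj
}

#' @export
print.risk_clusters <- function(x, ...) {
  cat("Risk-level cluster model (K-means++), k =", x$k, "\n")
  if (!is.null(x$silhouette_by_k)) {
    cat("  silhouette by k:",
        paste(sprintf("%s: %.4f", names(x$silhouette_by_k),
                      x$silhouette_by_k), collapse = ", "), "\n")
  }
  cat(sprintf("  average silhouette at k = %d: %.4f\n", x$k, x$silhouette))
  cat("  centers (normalized), ordered by distance to origin:\n")
  tab <- cbind(round(x$centers[x$level_order$cluster, , drop = FALSE], 4),
               norm = round(x$level_order$norm, 4))
  rownames(tab) <- as.character(x$level_order$level)
  print(tab)
  invisible(x)
}

#' Classify days by nearest cluster center
#'
#' Assigns each point the risk level of its nearest fitted center
#' (Euclidean distance in the normalized index space).  Ties are broken
#' toward the lower-risk level.
#'
#' @param object Fitted [risk_clusters()] model.
#' @param newdata Comprehensive series data frame or matrix.  Use
#'   `normalized = TRUE` when the values are already on the normalized
#'   scale (e.g. forecasts produced on that scale).
#' @param normalized Whether `newdata` is already normalized.
#' @param ... Unused.
#' @return Data frame: `level` (ordered factor), `distance` to the
#'   assigned center, `cluster` index.
#' @export
predict.risk_clusters <- function(object, newdata, normalized = FALSE,
                                  ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, intersect(c("nipi", "tcr", "thq"),
                                             names(newdata)), drop = FALSE])
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$centers))
  pts <- if (normalized) newdata else apply_bounds(newdata, object$bounds)
  # centers in risk order: ties in distance then resolve to lower risk
  ord_centers <- object$centers[object$level_order$cluster, , drop = FALSE]
  d2 <- dist2_to_centers(pts, ord_centers)
  pick <- max.col(-d2, ties.method = "first")   # first = lowest risk level
  data.frame(
    level = object$level_order$level[pick],
    distance = sqrt(pmax(d2[cbind(seq_len(nrow(pts)), pick)], 0)),
    cluster = object$level_order$cluster[pick]
  )
}

#' Distribution of risk levels in a classified series
#'
#' @param levels Factor (or character) vector of level labels, or the data
#'   frame returned by [predict.risk_clusters()].
#' @param all_levels Optional complete level set to report zeros for.
#' @return Named numeric vector of proportions summing to 1.
#' @export
level_distribution <- function(levels, all_levels = NULL) {
  if (is.data.frame(levels)) levels <- levels$level
  if (length(levels) == 0L) stop("empty series")
  if (is.factor(levels)) {
    tab <- table(levels)
  } else {
    if (is.null(all_levels)) all_levels <- unique(levels)
    tab <- table(factor(levels, levels = all_levels))
  }
  prop <- as.numeric(tab) / length(levels)
  stats::setNames(prop, names(tab))
}

#' Serialize / restore a risk_clusters model as text
#'
#' @param model `risk_clusters` object.
#' @param path Destination file (JSON).
#' @return `path` invisibly; `read_risk_clusters()` returns the model.
#' @export
write_risk_clusters <- function(model, path) {
  stopifnot(inherits(model, "risk_clusters"))
  obj <- list(k = model$k, centers = model$centers,
              bounds = model$bounds,
              level_cluster = model$level_order$cluster,
              level_names = as.character(model$level_order$level),
              silhouette = model$silhouette, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_clusters
#' @export
read_risk_clusters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(unlist(obj$centers), nrow = obj$k)
  bounds <- matrix(unlist(obj$bounds), nrow = 2,
                   dimnames = list(c("min", "max"), NULL))
  nm <- obj$level_names
  lv <- data.frame(cluster = obj$level_cluster,
                   norm = sqrt(rowSums(
                     centers[obj$level_cluster, , drop = FALSE]^2)),
                   level = factor(nm, levels = nm, ordered = TRUE))
  structure(list(k = obj$k, centers = centers, bounds = bounds,
                 level_order = lv, silhouette = obj$silhouette,
                 seed = obj$seed),
            class = "risk_clusters")
}
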