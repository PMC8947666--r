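# Voting ensemble of sub-model forecasts.
#
# Sub-model forecasts are combined as a convex combination h_t = sum_i w_i
# zeta_i(X) with weights on the simplex (non-negative, summing to 1).  The
# weights are selected by exhaustive search over a rational simplex grid,
# maximizing the risk-level prediction accuracy PA -- the fraction of
# forecast days whose predicted level (nearest cluster center of the
# combined forecast) matches the actual level.  PA is piecewise constant in
# the weights, so a fine grid search is exact up to its resolution and
# exactly reproducible.

#' Enumerate simplex grid weights
#'
#' All weight vectors for `n_models` models with entries that are multiples
#' of `grid_step` and sum to 1; for 3 models there are
#' `choose(1/grid_step + 2, 2)` of them (66 at step 0.1, 231 at step 0.05).
#'
#' @param n_models Number of sub-models.
#' @param grid_step Grid resolution; `1/grid_step` must be an integer.
#' @return Matrix with one weight vector per row; rows sum to 1 exactly.
#' @export
simplex_grid <- function(n_models, grid_step = 0.05) {
  steps <- 1 / grid_step
  if (abs(steps - round(steps)) > 1e-9)
    stop("grid_step must divide 1")
  steps <- as.integer(round(steps))
  combos <- utils::combn(steps + n_models - 1L, n_models - 1L)
  # stars and bars: positions of bars among steps + n_models - 1 slots
  grid <- t(apply(combos, 2, function(bars) {
    diff(c(0L, bars, steps + n_models)) - 1L
  }))
  grid / steps
}

#' Convex combination of sub-model forecasts
#'
#' @param sub_forecasts List of equal-length numeric vectors (or matrices
#'   with one column per index type), one per sub-model.
#' @param weights Numeric weights, non-negative and summing to 1.
#' @return The pointwise weighted combination, same shape as each element.
#' @export
vote_combine <- function(sub_forecasts, weights) {
  if (length(sub_forecasts) != length(weights))
    stop("one weight per sub-model is required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  dims <- lapply(sub_forecasts, dim)
  lens <- vapply(sub_forecasts, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("sub-model forecasts must have equal length")
  out <- sub_forecasts[[1L]] * weights[1L]
  for (i in seq_along(sub_forecasts)[-1L])
    out <- out + sub_forecasts[[i]] * weights[i]
  out
}

#' Root mean square error and mean absolute error
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return A single number; `rmse(a, p) >= mae(a, p)` always.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    stop("actual and predicted must be non-empty and of equal length")
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rmse
#' @export
mae <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    stop("actual and predicted must be non-empty and of equal length")
  mean(abs(actual - predicted))
}

#' Risk-level agreement indicator
#'
#' 1 when the forecast index triple and the actual triple are classified to
#' the same risk level by the cluster model, else 0.
#'
#' @param forecast,actual Numeric index triples (or matrices, one day per
#'   row) on the normalized scale.
#' @param model Fitted [risk_clusters()] model.
#' @return Integer vector of 0/1 indicators.
#' @export
level_indicator <- function(forecast, actual, model) {
  lf <- predict(model, forecast, normalized = TRUE)$level
  la <- predict(model, actual, normalized = TRUE)$level
  as.integer(lf == la)
}

#' Level prediction accuracy
#'
#' @param indicators Vector of 0/1 level-agreement indicators.
#' @return Mean of the indicators, in [0, 1].
#' @export
prediction_accuracy <- function(indicators) {
  if (length(indicators) == 0L) stop("no indicators")
  mean(indicators)
}

#' Select voting weights by level-accuracy maximization
#'
#' Exhaustively searches the simplex grid for the weight vector whose
#' combined forecast classifies the most evaluation days to their actual
#' risk level.  Ties are broken by lower mean squared forecast error, then
#' by lexicographic weight order.
#'
#' @param sub_forecasts List (one per sub-model) of `tau x 3` matrices of
#'   normalized index forecasts (columns nipi, tcr, thq).
#' @param actuals `tau x 3` matrix of actual normalized index values.
#' @param cluster_model Fitted [risk_clusters()] model.
#' @param grid_step Simplex grid resolution (default 0.05).
#' @return List: `weights`, `pa` (accuracy attained), `n_candidates`, and
#'   `pa_by_model` (each sub-model's own accuracy).
#' @export
optimize_weights <- function(sub_forecasts, actuals, cluster_model,
                             grid_step = 0.05) {
  actuals <- as.matrix(actuals)
  if (nrow(actuals) == 0L) stop("empty evaluation window")
  sub_forecasts <- lapply(sub_forecasts, as.matrix)
  grid <- simplex_grid(length(sub_forecasts), grid_step)
  actual_levels <- predict(cluster_model, actuals,
                           normalized = TRUE)$level
  eval_w <- function(w) {
    comb <- vote_combine(sub_forecasts, w)
    lev <- predict(cluster_model, comb, normalized = TRUE)$level
    c(pa = mean(lev == actual_levels),
      mse = mean((comb - actuals)^2))
  }
  scores <- t(apply(grid, 1, eval_w))
  # best PA; ties -> lower MSE; remaining ties -> lexicographically
  # smallest weight vector (rows of simplex_grid are already in
  # lexicographic order)
  ord <- order(-scores[, "pa"], scores[, "mse"])
  best <- ord[1L]
  vert <- diag(length(sub_forecasts))
  pa_by_model <- apply(vert, 1, function(w) eval_w(w)[["pa"]])
  list(weights = grid[best, ], pa = unname(scores[best, "pa"]),
       n_candidates = nrow(grid), pa_by_model = pa_by_model)
}

#' Score forecasts against actuals at several horizons
#'
#' Builds the per-index RMSE/MAE and per-horizon level accuracy for a set
#' of forecasters over one test window.
#'
#' @param forecasts Named list (one per model) of `tau x 3` forecast
#'   matrices on the normalized scale.
#' @param actuals `tau x 3` matrix of actual normalized values.
#' @param cluster_model Fitted [risk_clusters()] model.
#' @param horizons Horizons (days) to report; each must be <= `nrow(actuals)`.
#' @return List: `errors` data frame (model, index, horizon, rmse, mae,
#'   plus per-model `Avg` horizon rows), `accuracy` data frame (model,
#'   horizon, pa).
#' @export
score_forecasts <- function(forecasts, actuals, cluster_model,
                            horizons = c(7, 14, 21)) {
  actuals <- as.matrix(actuals)
  if (max(horizons) > nrow(actuals))
    stop("horizon exceeds the test window")
  idx <- colnames(actuals)
  if (is.null(idx)) idx <- c("nipi", "tcr", "thq")
  err <- list(); acc <- list()
  for (mod in names(forecasts)) {
    fc <- as.matrix(forecasts[[mod]])
    for (h in horizons) {
      for (j in seq_along(idx)) {
        err[[length(err) + 1L]] <- data.frame(
          model = mod, index = idx[j], horizon = h,
          rmse = rmse(actuals[1:h, j], fc[1:h, j]),
          mae = mae(actuals[1:h, j], fc[1:h, j]),
          stringsAsFactors = FALSE)
      }
      acc[[length(acc) + 1L]] <- data.frame(
        model = mod, horizon = h,
        pa = prediction_accuracy(
          level_indicator(fc[1:h, , drop = FALSE],
                          actuals[1:h, , drop = FALSE], cluster_model)),
        stringsAsFactors = FALSE)
    }
  }
  errors <- do.call(rbind, err)
  # per-model, per-index average over horizons (reporting convention)
  avg <- stats::aggregate(cbind(rmse, mae) ~ model + index, errors, mean)
  avg$horizon <- "Avg"
  errors$horizon <- as.character(errors$horizon)
  list(errors = rbind(errors, avg[, names(errors)]),
       accuracy = do.call(rbind, acc))
}
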