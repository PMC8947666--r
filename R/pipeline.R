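# End-to-end early-warning pipeline: detection records -> daily indexes ->
# entropy-weight fusion -> risk-level clustering -> ensemble forecasting
# and evaluation on chronological dataset splits.

derive_seed <- function(seed, ...) {
  parts <- c(...)
  as.integer((as.numeric(seed) * 7919 + sum(parts * 101^(seq_along(parts))))
             %% 2147483647)
}

# Three chronological train/test splits over N days, each with a 21-day
# test window: Dataset1 and Dataset2 share the 80% training ratio with
# different test windows; Dataset2 and Dataset3 share the test window with
# a 70% vs 80% ratio.
default_splits <- function(n, test_len = 21L, offset = 60L) {
  t1 <- floor(0.8 * n)
  t2 <- floor(0.8 * (n - offset))
  len3 <- floor(0.7 * (n - offset))
  list(
    Dataset1 = list(train_start = 1L, train_end = t1,
                    test = (t1 + 1L):(t1 + test_len)),
    Dataset2 = list(train_start = 1L, train_end = t2,
                    test = (t2 + 1L):(t2 + test_len)),
    Dataset3 = list(train_start = t2 - len3 + 1L, train_end = t2,
                    test = (t2 + 1L):(t2 + test_len))
  )
}

#' Run the full early-warning pipeline
#'
#' Generates (or accepts) detection records, computes the daily per-metal
#' risk indexes, fuses them with entropy weights into the comprehensive
#' series, fits the risk-level cluster model, trains the recurrent
#' sub-models on three chronological dataset splits, selects voting weights
#' on the last 21 training days of each split, and scores all forecasters
#' (sub-models, voting ensemble, persistence baseline) on 21-day test
#' windows at 7/14/21-day horizons.
#'
#' @param records Detection-record data frame; `NULL` (default) simulates
#'   one with [simulate_detections()].
#' @param sim A [sim_config()] for the simulation when `records` is `NULL`.
#' @param seed Master integer seed; every random stage derives its own seed
#'   from it.
#' @param params,limits,lod_table,fc Exposure configuration (defaults as in
#'   the respective functions).
#' @param train_frac Fraction of days defining the primary training span
#'   used to fit the entropy weights (default 0.8).
#' @param window_n Forecast input window length (default 7).
#' @param hidden,epochs,lr Recurrent sub-model size and training length
#'   (pipeline-scale defaults 16 units / 120 epochs keep the full run in
#'   seconds; see the package vignette).
#' @param grid_step Voting-weight grid resolution (default 0.05).
#' @param horizons Forecast horizons to score (default 7, 14, 21 days).
#' @param k_candidates Cluster-count candidates (default 3:7).
#' @param opt_len Length of the weight-optimization window at the end of
#'   each training span (default 21 days).
#' @return List of class `metalrisk_run`: `index_series`, `weights`
#'   (entropy), `comprehensive`, `clusters` (risk_clusters model),
#'   `normalized` (matrix), `regimes` (truth labels when simulated),
#'   `datasets` (per-split forecasts, chosen voting weights and scores),
#'   `summary` (per-model average 7-day PA across splits).
#' @export
run_early_warning <- function(records = NULL, sim = sim_config(),
                              seed = 0L,
                              params = tox_params(),
                              limits = default_limits(),
                              lod_table = default_lods(),
                              fc = national_fc(),
                              train_frac = 0.8, window_n = 7L,
                              hidden = 16L, epochs = 120L, lr = 0.01,
                              grid_step = 0.05, horizons = c(7, 14, 21),
                              k_candidates = 3:7, opt_len = 21L) {
  regimes <- NULL
  if (is.null(records)) {
    gen <- simulate_detections(sim, seed = derive_seed(seed, 1))
    records <- gen$records
    regimes <- gen$regimes
  }
  records <- preprocess_records(records, lod_table = lod_table,
                                inorganic_as_ratio = params$inorganic_as_ratio)
  summaries <- summarize_daily(records, limits = limits)
  index_series <- assess_days(summaries, params = params, fc = fc)

  dates <- sort(unique(index_series$date))
  n <- length(dates)
  train_days <- dates[seq_len(floor(train_frac * n))]
  ew <- entropy_weights(index_series[index_series$date %in% train_days, ])
  comp <- fuse_indexes(index_series, ew)
  clusters <- risk_clusters(comp, k_candidates = k_candidates,
                            seed = derive_seed(seed, 2))
  Z <- apply_bounds(as.matrix(comp[, c("nipi", "tcr", "thq")]),
                    clusters$bounds)
  rownames(Z) <- as.character(comp$date)

  arches <- c("rnn", "gru", "lstm")
  splits <- default_splits(n)
  tau <- max(horizons)
  datasets <- list()
  for (di in seq_along(splits)) {
    sp <- splits[[di]]
    if (sp$train_start + window_n + opt_len > sp$train_end)
      stop("training span too short for the optimization window")
    # sub-model training on the split's training days minus the held-out
    # validation segments, one model per index, with parameter snapshots
    # along the trajectory
    snap_every <- max(1L, epochs %/% 12L)
    n_val <- min(3L, max(1L, (sp$train_end - sp$train_start + 1L -
                                window_n - 2L * opt_len) %/% opt_len))
    fit_end <- sp$train_end - n_val * opt_len
    models <- lapply(seq_along(arches), function(ai) {
      lapply(1:3, function(j) {
        recurrent_forecaster(
          Z[sp$train_start:fit_end, j], architecture = arches[ai],
          window_n = window_n, hidden = hidden, epochs = epochs, lr = lr,
          seed = derive_seed(seed, 3, di, ai, j),
          snapshot_every = snap_every)
      })
    })
    names(models) <- arches
    fc3 <- function(model_list, hist_rows, steps) {
      vapply(1:3, function(j)
        recursive_forecast(model_list[[j]], Z[hist_rows, j], steps),
        numeric(steps))
    }
    # validation by backtesting: the last n_val consecutive opt_len-day
    # segments of the training span, held out from sub-model fitting and
    # each forecast recursively from the window_n days preceding it.  Used
    # both to pick the training length per architecture (early stopping on
    # level accuracy) and to select the voting weights; a single 21-day
    # segment holds too few regime episodes for a stable choice.
    val_rows <- lapply(seq_len(n_val) - 1L, function(w)
      (sp$train_end - (w + 1L) * opt_len + 1L):(sp$train_end - w * opt_len))
    val_hist <- lapply(val_rows, function(rows)
      (rows[1L] - window_n):(rows[1L] - 1L))
    actual_val <- do.call(rbind, lapply(val_rows, function(rows)
      Z[rows, , drop = FALSE]))
    val_levels <- predict(clusters, actual_val, normalized = TRUE)$level
    val_fc <- function(model_list) {
      do.call(rbind, lapply(val_hist, function(h)
        fc3(model_list, h, opt_len)))
    }
    for (ai in seq_along(arches)) {
      n_snap <- length(models[[ai]][[1L]]$snapshots)
      pa_snap <- vapply(seq_len(n_snap), function(s) {
        ml <- lapply(models[[ai]], select_snapshot, which = s)
        mean(predict(clusters, val_fc(ml),
                     normalized = TRUE)$level == val_levels)
      }, numeric(1))
      # one-standard-error rule: earliest snapshot whose validated
      # accuracy is within one binomial SE of the best (conservative
      # model selection; longer training must earn its keep)
      best <- max(pa_snap)
      se <- sqrt(best * (1 - best) / length(val_levels))
      pick <- which(pa_snap >= best - se)[1L]
      models[[ai]] <- lapply(models[[ai]], select_snapshot, which = pick)
    }
    opt_fc <- lapply(models, val_fc)
    wsel <- optimize_weights(opt_fc, actual_val,
                             clusters, grid_step = grid_step)
    # test-window forecasts
    hist_test <- (sp$train_end - window_n + 1L):sp$train_end
    test_fc <- lapply(models, fc3, hist_rows = hist_test, steps = tau)
    test_fc$ensemble <- vote_combine(test_fc[arches], wsel$weights)
    pers <- persistence_forecaster(window_n)
    test_fc$persistence <- vapply(1:3, function(j)
      recursive_forecast(pers, Z[hist_test, j], tau), numeric(tau))
    test_fc <- lapply(test_fc, function(m) {
      colnames(m) <- c("nipi", "tcr", "thq")
      m
    })
    actual <- Z[sp$test, , drop = FALSE]
    scores <- score_forecasts(test_fc, actual, clusters,
                              horizons = horizons)
    datasets[[names(splits)[di]]] <- list(
      split = sp, voting = wsel, forecasts = test_fc, actual = actual,
      scores = scores)
  }

  acc <- do.call(rbind, lapply(names(datasets), function(nm) {
    a <- datasets[[nm]]$scores$accuracy
    a$dataset <- nm
    a
  }))
  pa_summary <- stats::aggregate(pa ~ model + horizon, acc, mean)
  structure(list(index_series = index_series, weights = ew,
                 comprehensive = comp, clusters = clusters,
                 normalized = Z, regimes = regimes, datasets = datasets,
                 accuracy = acc, summary = pa_summary, seed = seed),
            class = "metalrisk_run")
}

#' @export
print.metalrisk_run <- function(x, ...) {
  cat("Early-warning pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  %d assessed days; k = %d risk levels (silhouette %.4f)\n",
              nrow(x$comprehensive), x$clusters$k, x$clusters$silhouette))
  cat("  Risk-level distribution:\n")
  print(round(level_distribution(x$clusters$levels), 4))
  cat("  Mean level-prediction accuracy across datasets:\n")
  s <- x$summary[order(x$summary$horizon, x$summary$model), ]
  print(s, row.names = FALSE)
  invisible(x)
}
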