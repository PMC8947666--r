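# Entropy-weight fusion of the nine per-metal indexes into three
# comprehensive daily indexes.
#
# For an index matrix X (days x 9 columns, one column per metal x index
# type), the entropy-weight scheme is:
#   p_tj = x_tj / sum_t x_tj
#   e_j  = -(1 / ln n) * sum_t p_tj ln p_tj     (0 * ln 0 := 0)
#   w_j  = (1 - e_j) / sum_k (1 - e_k)
# More variable columns carry more information (lower entropy) and weigh
# more.  The comprehensive index of each type is the weighted sum of the
# three per-metal values of that type, by default using the three weights
# renormalized within the type (a convex combination).

index_types <- function() c("nipi", "tcr", "thq")

# days x 9 matrix with columns metal.type in fixed order
index_matrix <- function(index_df) {
  dates <- sort(unique(index_df$date))
  cols <- as.vector(outer(supported_metals(), index_types(),
                          function(m, t) paste(m, t, sep = ".")))
  mat <- matrix(NA_real_, nrow = length(dates), ncol = length(cols),
                dimnames = list(as.character(dates), cols))
  for (ty in index_types()) {
    for (m in supported_metals()) {
      sel <- index_df$metal == m
      mat[as.character(index_df$date[sel]), paste(m, ty, sep = ".")] <-
        index_df[[ty]][sel]
    }
  }
  if (anyNA(mat)) stop("index series has incomplete days; ",
                       "run assess_days with require_complete = TRUE")
  mat
}

#' Entropy weights for the nine per-metal indexes
#'
#' @param x Either the long index data frame from [assess_days()] or a
#'   non-negative numeric matrix (days x indicators).
#' @return An object of class `entropy_weights`: `weights` (sums to 1),
#'   `entropy` per column, and `sub_weights`, a list with the per-index-type
#'   weights renormalized to sum to 1 within each type (only when columns
#'   follow the metal x type layout).
#' @export
entropy_weights <- function(x) {
  mat <- if (is.data.frame(x) && "metal" %in% names(x)) index_matrix(x)
         else as.matrix(x)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 days to compute entropy weights")
  if (any(mat < 0)) stop("index values must be non-negative")
  tot <- colSums(mat)
  e <- vapply(seq_len(ncol(mat)), function(j) {
    if (tot[j] == 0) return(1)            # all-zero column: no information
    p <- mat[, j] / tot[j]
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(n)
  }, numeric(1))
  info <- 1 - e
  # columns constant across days have e_j = 1 (up to rounding); clamp
  info[info < 0] <- 0
  if (sum(info) <= 0)
    stop("all columns are constant; entropy weights are undefined")
  w <- info / sum(info)
  names(w) <- colnames(mat)
  sub <- NULL
  cols <- as.vector(outer(supported_metals(), index_types(),
                          function(m, t) paste(m, t, sep = ".")))
  if (!is.null(colnames(mat)) && setequal(colnames(mat), cols)) {
    sub <- lapply(index_types(), function(ty) {
      wt <- w[paste(supported_metals(), ty, sep = ".")]
      if (sum(wt) == 0) {
        # no information in this type: fall back to equal weights
        wt[] <- 1 / length(wt)
      } else wt <- wt / sum(wt)
      names(wt) <- supported_metals()
      wt
    })
    names(sub) <- index_types()
  }
  structure(list(weights = w, entropy = stats::setNames(e, colnames(mat)),
                 sub_weights = sub, n_days = n),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("Entropy weights over", length(x$weights), "indicators,",
      x$n_days, "days\n")
  print(round(x$weights, 4))
  if (!is.null(x$sub_weights)) {
    cat("Renormalized per-index-type sub-weights:\n")
    for (ty in names(x$sub_weights))
      cat(" ", ty, ":", paste(sprintf("%s %.4f",
          names(x$sub_weights[[ty]]), x$sub_weights[[ty]]),
          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fuse per-metal indexes into comprehensive daily indexes
#'
#' Computes the comprehensive NIPI, TCR and THQ for every day as the
#' weighted sum of the three per-metal values of each index type.
#'
#' @param index_df Long index data frame from [assess_days()].
#' @param weights An `entropy_weights` object fitted with
#'   [entropy_weights()] (possibly on a training subset of days).
#' @param mode `"renormalized"` (default): each comprehensive index is a
#'   convex combination using the per-type sub-weights; `"global"`: the raw
#'   nine-way weights are used without renormalization (sensitivity
#'   checks).
#' @return Data frame: `date`, `nipi`, `tcr`, `thq` (the comprehensive
#'   series).
#' @export
fuse_indexes <- function(index_df, weights,
                         mode = c("renormalized", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "entropy_weights"))
  mat <- index_matrix(index_df)
  out <- data.frame(date = as.Date(rownames(mat)))
  for (ty in index_types()) {
    cols <- paste(supported_metals(), ty, sep = ".")
    wt <- if (mode == "renormalized") {
      if (is.null(weights$sub_weights))
        stop("weights lack per-type sub-weights; use mode = 'global'")
      stats::setNames(weights$sub_weights[[ty]][supported_metals()], cols)
    } else weights$weights[cols]
    out[[ty]] <- as.vector(mat[, cols, drop = FALSE] %*% wt)
  }
  rownames(out) <- NULL
  out
}

#' Write / read entropy weights as key-value text
#'
#' @param weights `entropy_weights` object.
#' @param path Destination file.
#' @return `path`, invisibly (`write_entropy_weights`); the restored object
#'   (`read_entropy_weights`).
#' @export
write_entropy_weights <- function(weights, path) {
  stopifnot(inherits(weights, "entropy_weights"))
  obj <- list(weights = as.list(weights$weights),
              entropy = as.list(weights$entropy),
              sub_weights = lapply(weights$sub_weights, as.list),
              n_days = weights$n_days)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_entropy_weights
#' @export
read_entropy_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(obj$weights),
                 entropy = unlist(obj$entropy),
                 sub_weights = lapply(obj$sub_weights, unlist),
                 n_days = obj$n_days),
            class = "entropy_weights")
}
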