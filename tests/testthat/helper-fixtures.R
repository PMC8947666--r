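# Shared fixtures, built in code.

# Minimal detection-record data frame in the package's canonical layout.
make_records <- function(metal, value, date = as.Date("2020-06-01"),
                         censored = FALSE, lod = NA_real_,
                         raw = as.character(value)) {
  n <- max(length(metal), length(value), length(date))
  data.frame(
    metal = rep_len(metal, n), date = rep_len(date, n),
    raw_result = rep_len(raw, n),
    value = rep_len(value, n), censored = rep_len(censored, n),
    lod = rep_len(lod, n),
    province = "Henan", food_category = "Grain processing products",
    stringsAsFactors = FALSE
  )
}

mark_preprocessed <- function(records) {
  attr(records, "preprocessed") <- TRUE
  records
}

# Four normalized cluster centers of a published-style reference fit, used
# as a fixed geometry for classification tests.
reference_centers <- function() {
  rbind(c(0.0841556, 0.0898703, 0.1717660),
        c(0.2272796, 0.1375510, 0.3194492),
        c(0.1693235, 0.6068999, 0.3582518),
        c(0.3463198, 0.1970221, 0.6196991))
}

# risk_clusters object built directly from fixed centers (normalized
# space; identity bounds).
reference_cluster_model <- function(centers = reference_centers()) {
  lv <- order_levels(centers)
  structure(list(k = nrow(centers), centers = centers,
                 bounds = rbind(min = rep(0, ncol(centers)),
                                max = rep(1, ncol(centers))),
                 level_order = lv, silhouette = NA_real_, seed = NA),
            class = "risk_clusters")
}

# Exhaustive-enumeration optimum of the within-cluster sum of squares over
# all labelings with at most k clusters (independent oracle for the
# k-means fit on tiny instances).
enum_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  L <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  tot <- 0
  for (j in seq_len(k)) {
    M <- (L == j) * 1
    cnt <- rowSums(M)
    for (d in seq_len(ncol(x))) {
      sx <- as.vector(M %*% x[, d])
      sx2 <- as.vector(M %*% x[, d]^2)
      tot <- tot + sx2 - ifelse(cnt > 0, sx^2 / pmax(cnt, 1), 0)
    }
  }
  min(tot)
}

# A tiny comprehensive series with visible structure.
toy_comprehensive <- function(n = 30, seed = 7) {
  set.seed(seed)
  data.frame(date = as.Date("2020-03-01") + seq_len(n) - 1,
             nipi = runif(n, 0.2, 1.5),
             tcr = runif(n, 0.001, 0.01),
             thq = runif(n, 0.1, 2))
}
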