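# Reading and preprocessing of heavy-metal detection records.
#
# A detection-record table has one row per laboratory measurement: the
# metal, the inspection date, the measured concentration (or a
# "not detected" marker), and sample metadata.  Records flow through
# preprocess_records() (censoring substitution, symbol stripping, inorganic
# arsenic conversion) before daily aggregation in summarize_daily().

#' Default column dialect for detection tables
#'
#' Maps the package's canonical field names to the column headers of a raw
#' surveillance export.  Override individual entries for files with other
#' headers.
#'
#' @param ... Named overrides, e.g. `result = "Value"`.
#' @return Named character vector: canonical field -> column name.
#' @export
detection_dialect <- function(...) {
  d <- c(metal = "Heavy Metal Elements",
         date = "Date of Inspection",
         result = "Inspection Result",
         province = "Province",
         food_category = "Food Category",
         lod = "Limit of Detection")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop("unknown dialect fields: ",
                          paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

# Recognize a metal name in free text; NA when unrecognizable.
parse_metal <- function(x) {
  x <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[grepl("chromium|\\bcr\\b|\\(cr\\)", x)] <- "chromium"
  out[grepl("cadmium|\\bcd\\b|\\(cd\\)", x)] <- "cadmium"
  out[grepl("arsenic|\\bas\\b|\\(as\\)", x)] <- "arsenic"
  out
}

# Dates arrive either ISO (2020-06-23) or US-style (6/23/2020).
parse_detection_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  us <- is.na(d)
  if (any(us)) d[us] <- as.Date(x[us], format = "%m/%d/%Y")
  d
}

is_censored_result <- function(x) {
  grepl("^\\s*(not\\s*detected|nd|n\\.d\\.|<\\s*lod|-)\\s*$",
        tolower(x))
}

#' Read a detection-record table
#'
#' Reads a delimited text file of heavy-metal detection records and returns
#' a standardized record data frame.  Rows whose metal or date cannot be
#' parsed are dropped; their count is reported via a message and an
#' attribute.
#'
#' @param path Path to a delimited text file with one header row.
#' @param dialect Column mapping from [detection_dialect()].
#' @param sep Field separator (default comma).
#' @return Data frame of detection records with columns `metal`, `date`,
#'   `raw_result`, `value`, `censored`, `lod`, `province`, `food_category`;
#'   attribute `n_rejected` counts dropped rows.
#' @export
read_detection_table <- function(path, dialect = detection_dialect(),
                                 sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  need <- c("metal", "date", "result")
  miss <- need[!dialect[need] %in% names(raw)]
  if (length(miss))
    stop("missing mandatory column(s): ",
         paste(dialect[miss], collapse = ", "))
  get_col <- function(field, default = NA) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(default, nrow(raw))
  }
  metal <- parse_metal(as.character(get_col("metal")))
  date <- parse_detection_date(as.character(get_col("date")))
  result <- trimws(as.character(get_col("result")))
  censored <- is_censored_result(result)
  value <- suppressWarnings(as.numeric(sub("^\\s*<\\s*", "", result)))
  value[censored] <- NA_real_
  lod <- suppressWarnings(as.numeric(get_col("lod")))

  ok <- !is.na(metal) & !is.na(date) & (censored | !is.na(value))
  n_rejected <- sum(!ok)
  rec <- data.frame(
    metal = metal[ok], date = date[ok], raw_result = result[ok],
    value = value[ok], censored = censored[ok], lod = lod[ok],
    province = as.character(get_col("province"))[ok],
    food_category = as.character(get_col("food_category"))[ok],
    stringsAsFactors = FALSE
  )
  if (nrow(rec) == 0L) stop("zero parseable rows in ", path)
  if (n_rejected > 0)
    message(n_rejected, " row(s) rejected (unparseable metal, date or result)")
  attr(rec, "n_rejected") <- n_rejected
  rec
}

#' Preprocess detection records
#'
#' Applies the three standard preprocessing rules of the exposure workflow,
#' in this order:
#' \enumerate{
#'   \item censored ("not detected") results are replaced by half the limit
#'     of detection (record LOD first, then `lod_table` by metal);
#'   \item results recorded as `"<x"` keep the numeric value `x` (done at
#'     read time; such records are treated as uncensored);
#'   \item total-arsenic values are converted to inorganic arsenic by
#'     multiplying with `inorganic_as_ratio`.
#' }
#' The function is idempotent: records already carrying the `preprocessed`
#' attribute are returned unchanged, so the arsenic ratio is applied exactly
#' once.
#'
#' @param records Detection-record data frame from [read_detection_table()]
#'   or [simulate_detections()].
#' @param lod_table Named fallback LODs per metal, mg/kg.
#' @param inorganic_as_ratio Inorganic fraction for arsenic (default 0.70).
#' @return Records with all values positive and `censored` cleared;
#'   attribute `preprocessed = TRUE`.
#' @export
preprocess_records <- function(records, lod_table = default_lods(),
                               inorganic_as_ratio = 0.70) {
  if (isTRUE(attr(records, "preprocessed"))) return(records)
  stopifnot(is.data.frame(records))
  cen <- which(records$censored)
  if (length(cen)) {
    lod <- records$lod[cen]
    fill <- is.na(lod)
    if (any(fill)) lod[fill] <- lod_table[records$metal[cen][fill]]
    if (anyNA(lod) || any(lod <= 0))
      stop("censored record(s) with no resolvable LOD")
    records$value[cen] <- lod / 2
    records$lod[cen] <- lod
    records$censored[cen] <- FALSE
  }
  ars <- records$metal == "arsenic"
  records$value[ars] <- records$value[ars] * inorganic_as_ratio
  if (any(records$value <= 0, na.rm = TRUE) || anyNA(records$value))
    stop("preprocessing produced non-positive or missing values")
  attr(records, "preprocessed") <- TRUE
  records
}

#' Aggregate records to per-day, per-metal summaries
#'
#' Forms, for each (date, metal) group, the pollution indexes P = X / S and
#' their maximum and mean, plus the 50th and 95th concentration quantiles
#' that feed the exposure indexes.
#'
#' @param records Preprocessed detection records.
#' @param limits Named national limit standards S per metal, mg/kg.
#' @param quantile_type Quantile interpolation scheme passed to
#'   [stats::quantile()]; default 7, linear interpolation between order
#'   statistics.
#' @return Data frame with one row per date x metal: `date`, `metal`,
#'   `n_samples`, `p_max`, `p_avg`, `x_q50`, `x_q95`.
#' @export
summarize_daily <- function(records, limits = default_limits(),
                            quantile_type = 7) {
  if (!isTRUE(attr(records, "preprocessed")))
    stop("records must be preprocessed first (see preprocess_records)")
  present <- unique(records$metal)
  miss <- setdiff(present, names(limits))
  if (length(miss))
    stop("missing national limit for: ", paste(miss, collapse = ", "))
  if (any(limits[present] <= 0)) stop("limits must be positive")

  key <- interaction(records$date, records$metal, drop = TRUE)
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    x <- records$value[idx]
    metal <- records$metal[idx[1L]]
    p <- x / limits[[metal]]
    q <- stats::quantile(x, c(0.5, 0.95), type = quantile_type,
                         names = FALSE)
    data.frame(date = records$date[idx[1L]], metal = metal,
               n_samples = length(x), p_max = max(p), p_avg = mean(p),
               x_q50 = q[1L], x_q95 = q[2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$date, match(out$metal, supported_metals())), ]
  rownames(out) <- NULL
  out
}
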