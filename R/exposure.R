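# Daily dietary risk-assessment indexes.
#
# Three indexes per metal per day:
#   NIPI  = sqrt((Pmax^2 + Pavg^2) / 2)          peak-weighted pollution
#   TCR   = EF*ED*CSF*EDI50 / ATC                lifetime cancer risk
#   THQ   = EF*ED*EDI95 / (ATC*RfD)              non-carcinogenic quotient
# with EDIq = FC * Xq / W the estimated daily intake at concentration
# quantile Xq.  Under the default scenario EF*ED/ATC = 1, so TCR reduces to
# CSF*EDI50 and THQ to EDI95/RfD.  All three indexes are homogeneous of
# degree 1 in the concentration scale.

#' Nemerow integrated pollution index
#'
#' Quadratic mean of the maximum and average pollution index of a metal on
#' one day, emphasizing peak contamination over the day's mean.
#'
#' @param p_max Maximum pollution index over the day's samples (>= p_avg).
#' @param p_avg Mean pollution index.
#' @return Dimensionless NIPI, between `p_avg` and `p_max`.
#' @export
nipi <- function(p_max, p_avg) {
  if (any(p_max < 0) || any(p_avg < 0)) stop("pollution indexes must be >= 0")
  if (any(p_max < p_avg)) stop("p_max must be >= p_avg")
  sqrt((p_max^2 + p_avg^2) / 2)
}

#' Estimated daily intake
#'
#' @param fc Per-capita daily consumption, kg/day.
#' @param x Concentration, mg/kg (a daily quantile).
#' @param body_mass Body mass, kg.
#' @return Intake in mg/(kg body weight * day).
#' @export
edi <- function(fc, x, body_mass = 60) {
  if (any(body_mass <= 0)) stop("body mass must be positive")
  if (any(fc <= 0)) stop("consumption must be positive")
  if (any(x < 0)) stop("concentration must be >= 0")
  fc * x / body_mass
}

#' Target cancer risk for one daily summary
#'
#' Lifetime incremental cancer risk from the day's median concentration:
#' `EF*ED*CSF*EDI50/ATC`.
#'
#' @param summary One row of [summarize_daily()] output.
#' @param params [tox_params()] object.
#' @param fc National consumption, kg/day.
#' @return Dimensionless TCR.
#' @export
tcr_index <- function(summary, params = tox_params(), fc = national_fc()) {
  csf <- params$csf[[summary$metal]]
  if (is.null(csf) || is.na(csf)) stop("no CSF for metal ", summary$metal)
  (params$ef * params$ed * csf *
     edi(fc, summary$x_q50, params$body_mass)) / params$atc
}

#' Target hazard quotient for one daily summary
#'
#' Non-carcinogenic risk from the day's 95th-percentile concentration:
#' `EF*ED*EDI95/(ATC*RfD)`.  Values above 1 flag potential non-cancer risk.
#'
#' @inheritParams tcr_index
#' @return Dimensionless THQ.
#' @export
thq_index <- function(summary, params = tox_params(), fc = national_fc()) {
  rfd <- params$rfd[[summary$metal]]
  if (is.null(rfd) || is.na(rfd) || rfd <= 0)
    stop("missing or zero RfD for metal ", summary$metal)
  (params$ef * params$ed * edi(fc, summary$x_q95, params$body_mass)) /
    (params$atc * rfd)
}

#' Compute the per-metal index series for all days
#'
#' Applies NIPI, TCR and THQ to every daily summary.  Days missing any of
#' the three metals are dropped (the downstream fusion needs all nine
#' indexes for a day).
#'
#' @param summaries Output of [summarize_daily()].
#' @param params [tox_params()] object.
#' @param fc National consumption, kg/day.
#' @param require_complete Drop days lacking any metal (default TRUE).
#' @return Data frame: `date`, `metal`, `nipi`, `tcr`, `thq`; attribute
#'   `n_dropped_days` counts incomplete days removed.
#' @export
assess_days <- function(summaries, params = tox_params(),
                        fc = national_fc(), require_complete = TRUE) {
  stopifnot(nrow(summaries) > 0)
  out <- data.frame(
    date = summaries$date, metal = summaries$metal,
    nipi = nipi(summaries$p_max, summaries$p_avg),
    tcr = vapply(seq_len(nrow(summaries)), function(i)
      tcr_index(summaries[i, ], params, fc), numeric(1)),
    thq = vapply(seq_len(nrow(summaries)), function(i)
      thq_index(summaries[i, ], params, fc), numeric(1)),
    stringsAsFactors = FALSE
  )
  n_dropped <- 0L
  if (require_complete) {
    cnt <- table(out$date)
    full <- names(cnt)[cnt == length(supported_metals())]
    n_dropped <- sum(cnt != length(supported_metals()))
    out <- out[as.character(out$date) %in% full, ]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped_days") <- n_dropped
  out
}

#' Assess one day from its per-metal summaries
#'
#' Convenience wrapper returning the three indexes for each metal of a
#' single date.
#'
#' @param day_summaries Rows of [summarize_daily()] output sharing one date,
#'   one row per supported metal.
#' @inheritParams assess_days
#' @return Data frame with one row per metal: `metal`, `nipi`, `tcr`, `thq`.
#' @export
assess_day <- function(day_summaries, params = tox_params(),
                       fc = national_fc()) {
  if (length(unique(day_summaries$date)) != 1L)
    stop("day_summaries must cover a single date")
  if (!setequal(day_summaries$metal, supported_metals()))
    stop("summaries for all three metals are required")
  res <- assess_days(day_summaries, params, fc, require_complete = TRUE)
  res[, c("metal", "nipi", "tcr", "thq")]
}
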