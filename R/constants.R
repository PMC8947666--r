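#' Supported heavy metals
#'
#' The package assesses chromium, cadmium and arsenic in grain processing
#' products.  The set is closed: every ingest, exposure and fusion step
#' expects exactly these three elements.
#'
#' @return Character vector of the three metal names.
#' @export
supported_metals <- function() c("chromium", "cadmium", "arsenic")

#' Default national limit standards (mg/kg)
#'
#' Regulatory maximum concentrations S for each metal in grain processing
#' products, used to form pollution indexes P = X / S.  Defaults follow the
#' Chinese national food-contaminant standard (GB 2762) values for rice and
#' grain products: chromium 1.0, cadmium 0.2, inorganic arsenic 0.2 mg/kg.
#' Override when assessing other food classes.
#'
#' @return Named numeric vector, mg/kg.
#' @export
default_limits <- function() {
  c(chromium = 1.0, cadmium = 0.2, arsenic = 0.2)
}

#' Default limits of detection (mg/kg)
#'
#' Fallback per-metal assay detection limits used to substitute censored
#' ("not detected") results by LOD/2 when a record carries no LOD of its
#' own.
#'
#' @return Named numeric vector, mg/kg.
#' @export
default_lods <- function() {
  c(chromium = 0.05, cadmium = 0.02, arsenic = 0.04)
}

#' Toxicology parameters for dietary risk indexes
#'
#' Bundles the constants of the exposure model: per-metal oral reference
#' doses RfD (mg/(kg*d)), cancer slope factors CSF ((kg*d)/mg), and the
#' shared exposure-scenario constants.  Under the defaults the prefactor
#' EF*ED/ATC equals exactly 1, so TCR = CSF * EDI50 and THQ = EDI95 / RfD.
#'
#' @param rfd Named numeric, oral reference dose per metal, mg/(kg*d).
#'   Defaults: trivalent chromium 0.003, cadmium 0.001, arsenic 0.0003.
#' @param csf Named numeric, cancer slope factor per metal, (kg*d)/mg.
#'   Defaults: chromium 0.5, cadmium 6.3, arsenic 1.5.
#' @param ef Exposure frequency, days/year (default 365).
#' @param ed Exposure duration, years (default 70).
#' @param atc Averaging time, days (default 365 * ed).
#' @param body_mass Average adult body mass, kg (default 60).
#' @param inorganic_as_ratio Fraction of total arsenic counted as inorganic
#'   (default 0.70).
#' @return An object of class `tox_params`.
#' @export
tox_params <- function(rfd = c(chromium = 0.003, cadmium = 0.001,
                               arsenic = 0.0003),
                       csf = c(chromium = 0.5, cadmium = 6.3,
                               arsenic = 1.5),
                       ef = 365, ed = 70, atc = 365 * ed,
                       body_mass = 60, inorganic_as_ratio = 0.70) {
  stopifnot(all(rfd > 0), all(csf > 0), ef > 0, ed > 0, atc > 0,
            body_mass > 0, inorganic_as_ratio > 0, inorganic_as_ratio <= 1)
  if (!all(supported_metals() %in% names(rfd)))
    stop("rfd must be named for all supported metals")
  if (!all(supported_metals() %in% names(csf)))
    stop("csf must be named for all supported metals")
  structure(list(rfd = rfd, csf = csf, ef = ef, ed = ed, atc = atc,
                 body_mass = body_mass,
                 inorganic_as_ratio = inorganic_as_ratio),
            class = "tox_params")
}

#' @export
print.tox_params <- function(x, ...) {
  cat("Toxicology parameters\n")
  cat("  RfD mg/(kg d):", paste(names(x$rfd), signif(x$rfd, 3),
                                collapse = ", "), "\n")
  cat("  CSF (kg d)/mg:", paste(names(x$csf), signif(x$csf, 3),
                                collapse = ", "), "\n")
  cat(sprintf("  EF %g d/yr, ED %g yr, ATC %g d, body mass %g kg\n",
              x$ef, x$ed, x$atc, x$body_mass))
  cat(sprintf("  inorganic arsenic ratio %.2f\n", x$inorganic_as_ratio))
  invisible(x)
}

#' Provincial consumption of grain processing products
#'
#' Per-capita daily consumption (g/day) of grain processing products for 20
#' Chinese provinces, from the Fifth Chinese Total Diet Study survey
#' figures.
#'
#' @return Data frame with columns `province` and `fc_g_day`.
#' @export
consumption_table <- function() {
  data.frame(
    province = c("Heilongjiang", "Jilin", "Liaoning", "Beijing", "Hebei",
                 "Henan", "Ningxia", "Shaanxi", "Inner Mongolia", "Qinghai",
                 "Fujian", "Zhejiang", "Jiangsu", "Shanghai", "Jiangxi",
                 "Hubei", "Sichuan", "Hunan", "Guangxi", "Guangdong"),
    fc_g_day = c(673.70, 1201.02, 1131.27, 825.20, 935.58,
                 1517.90, 1002.35, 783.86, 1038.39, 1681.60,
                 920.55, 1126.50, 620.64, 566.96, 641.55,
                 916.16, 806.08, 905.68, 765.55, 431.90),
    stringsAsFactors = FALSE
  )
}

#' National per-capita consumption (kg/day)
#'
#' The exposure equations use a single national consumption figure FC while
#' the survey reports provincial values; the default policy is the
#' unweighted arithmetic mean of the provincial values, converted to kg/day.
#'
#' @param table Consumption table as from [consumption_table()].
#' @param policy `"mean"` (default) or `"median"` across provinces.
#' @return National FC in kg/day.
#' @export
national_fc <- function(table = consumption_table(),
                        policy = c("mean", "median")) {
  policy <- match.arg(policy)
  g <- switch(policy, mean = mean(table$fc_g_day),
              median = stats::median(table$fc_g_day))
  g / 1000
}
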