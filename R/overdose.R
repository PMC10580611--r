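#' Daily overdose probability for an exposure
#'
#' Prescription-opioid exposure carries a piecewise-constant hazard over MME
#' bands (< 20, 20-49, 50-99, >= 100 MME/day) with hazard ratios
#' (1, 1.44, 3.73, 8.87) scaled by the calibrated base daily hazard;
#' heroin/fentanyl multiplies the dose-band value by 1.7.  Agents on
#' medication for opioid use disorder carry their modality's person-year
#' rate instead of a dose-based hazard, and a diverted-buprenorphine day
#' carries the prescribed-buprenorphine rate (2.08 per 100 person-years;
#' 4.16 under sensitivity 1).  Zero consumption with no exposure is risk-free.
#'
#' @param opioid_type One of `"none"`, `"prescribed_po"`, `"illicit_po"`,
#'   `"heroin_fentanyl"`, `"moud"`, `"diverted_bupe"` (vectorized).
#' @param mme Non-negative consumed MME/day (ignored for moud/diverted_bupe).
#' @param params An [abm_params()] object.
#' @param moud_rate Person-year rate for `"moud"` entries (from
#'   [moud_overdose_rate()]); recycled.
#' @return Daily overdose probability, same length as `opioid_type`.
#' @examples
#' daily_overdose_prob("heroin_fentanyl", 60) /
#'   daily_overdose_prob("illicit_po", 60) # exactly 1.7
#' @export
daily_overdose_prob <- function(opioid_type, mme = 0,
                                params = abm_params(), moud_rate = 0) {
  if (any(mme < 0)) stop("mme must be non-negative", call. = FALSE)
  ov <- params$overdose
  k <- max(length(opioid_type), length(mme))
  opioid_type <- rep_len(opioid_type, k)
  mme <- rep_len(mme, k)
  moud_rate <- rep_len(moud_rate, k)
  band <- findInterval(mme, ov$mme_band_edges) + 1L
  p <- ov$base_daily_hazard * ov$band_hazard_ratios[band]
  p[opioid_type == "heroin_fentanyl"] <-
    p[opioid_type == "heroin_fentanyl"] * ov$heroin_od_multiplier
  p[opioid_type == "none" | mme == 0] <- 0
  i <- opioid_type == "moud"
  p[i] <- rate_to_daily_prob(moud_rate[i])
  i <- opioid_type == "diverted_bupe"
  p[i] <- rate_to_daily_prob(ov$od_rate_diverted_bupe)
  pmin(1, p)
}

#' Resolve overdose events to fatal or non-fatal
#'
#' For each overdose, naloxone is available with probability 27.6%; if
#' available, it reverses the overdose with probability 87.5% and a reversed
#' overdose is never fatal.  A non-reversed overdose is fatal with
#' probability 0.17, multiplied by 1.5 for heroin/fentanyl (capped at 1).
#' Setting `fatal_model = "marginal"` applies 0.17 to all events regardless
#' of naloxone (alternative composition flag).
#'
#' @param opioid_type Character vector, one entry per overdose event.
#' @param params An [abm_params()] object.
#' @return A tibble with one row per event: `opioid_type`,
#'   `naloxone_available`, `reversed`, `fatal`.  `reversed` implies
#'   `naloxone_available` and not `fatal`.
#' @export
resolve_overdoses <- function(opioid_type, params = abm_params()) {
  ov <- params$overdose
  k <- length(opioid_type)
  naloxone <- stats::runif(k) < ov$p_naloxone_available
  reversed <- naloxone & stats::runif(k) < ov$p_reversal_given_naloxone
  p_fatal <- pmin(1, ov$p_fatal_given_od *
                    ifelse(opioid_type == "heroin_fentanyl",
                           ov$heroin_fatal_multiplier, 1))
  if (identical(ov$fatal_model, "marginal")) {
    # 0.17 read as the marginal fatality: rescale so reversal doesn't dilute it
    p_fatal <- pmin(1, p_fatal / (1 - ov$p_naloxone_available *
                                    ov$p_reversal_given_naloxone))
  }
  fatal <- !reversed & stats::runif(k) < p_fatal
  tibble::tibble(opioid_type = opioid_type, naloxone_available = naloxone,
                 reversed = reversed, fatal = fatal)
}
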