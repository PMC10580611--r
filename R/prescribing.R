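# Draw prescription doses from a truncated normal with the 90 MME/day cap
# applied to cap-compliant prescriptions.
draw_rx_dose <- function(k, mean, sd, pr) {
  dose <- pmax(pr$dose_min, stats::rnorm(k, mean, sd))
  capped <- stats::runif(k) < pr$p_dose_cap_compliant
  over <- capped & dose >= pr$dose_cap_mme
  dose[over] <- pr$dose_cap_mme - 1e-6
  list(dose = dose, capped = capped)
}

#' Issue an opioid prescription for a pain presentation
#'
#' An agent presenting with the given pain type receives a prescription with
#' the published probability (22% acute, 30% chronic).  The daily dose is
#' drawn from the type's normal distribution (acute 30 MME sd 10; chronic
#' 50 MME sd 10), truncated at 1 MME; with probability 92.7% the prescribing
#' physician complies with the < 90 MME/day cap and the dose is clamped below
#' it.  Length is drawn uniformly from the type's day range (acute 3-7,
#' chronic 7-28).
#'
#' @param pain_type `"acute"` or `"chronic"`.
#' @param params An [abm_params()] object.
#' @param n Number of independent presentations to simulate.
#' @return A tibble with one row per presentation: `received`, `daily_dose`
#'   (NA when not received), `days`, `cap_compliant`.
#' @export
issue_prescription <- function(pain_type, params = abm_params(), n = 1) {
  if (!pain_type %in% c("acute", "chronic")) {
    stop("pain_type must be 'acute' or 'chronic'", call. = FALSE)
  }
  pr <- params$prescribing
  p_rx <- if (pain_type == "acute") pr$p_rx_given_acute else pr$p_rx_given_chronic
  mean <- if (pain_type == "acute") pr$acute_dose_mean else pr$chronic_dose_mean
  sd <- if (pain_type == "acute") pr$acute_dose_sd else pr$chronic_dose_sd
  len <- if (pain_type == "acute") pr$acute_len_days else pr$chronic_len_days
  received <- stats::runif(n) < p_rx
  d <- draw_rx_dose(n, mean, sd, pr)
  days <- sample(seq(len[1], len[2]), n, replace = TRUE)
  tibble::tibble(
    received = received,
    daily_dose = ifelse(received, d$dose, NA_real_),
    days = ifelse(received, days, NA_integer_),
    cap_compliant = ifelse(received, d$capped, NA)
  )
}

#' Physician decision on a refill request
#'
#' At prescription expiry a patient reporting continued pain requests a
#' refill.  The decision uses the per-physician refill probability (drawn
#' once per physician from mean 25% sd 10% for acute pain, mean 90% sd 10%
#' for chronic pain, truncated to `[0, 1]`).  Physicians complying with
#' prescription-monitoring rules (77.5%) deny patients holding overlapping
#' prescriptions.  When the granted refill escalates (patient's desire
#' exceeds the current dose), the dose increases by the mean 25%.
#'
#' @param rx A list or one-row tibble with `daily_dose` and `pain_type`
#'   (`"acute"`/`"chronic"`) describing the expiring prescription.
#' @param still_in_pain Does the patient report continued pain?
#' @param physician List with `refill_acute`, `refill_chronic`, `pdmp`
#'   (logical); defaults to a physician at the published means.
#' @param params An [abm_params()] object.
#' @param wants_escalation Does the patient report inadequate relief at the
#'   current dose?
#' @param has_overlapping_rx Does the patient hold another active opioid
#'   prescription?
#' @return A list with `decision` (`"refill"`, `"refill_with_escalation"`,
#'   `"deny"`) and `daily_dose` (the post-decision dose, NA on denial).
#' @export
refill_decision <- function(rx, still_in_pain = TRUE,
                            physician = list(refill_acute = 0.25,
                                             refill_chronic = 0.90,
                                             pdmp = TRUE),
                            params = abm_params(),
                            wants_escalation = FALSE,
                            has_overlapping_rx = FALSE) {
  if (!isTRUE(still_in_pain)) {
    return(list(decision = "deny", daily_dose = NA_real_))
  }
  if (isTRUE(has_overlapping_rx) && isTRUE(physician$pdmp)) {
    return(list(decision = "deny", daily_dose = NA_real_))
  }
  p <- if (identical(rx$pain_type, "acute")) physician$refill_acute
       else physician$refill_chronic
  if (stats::runif(1) >= p) {
    return(list(decision = "deny", daily_dose = NA_real_))
  }
  if (isTRUE(wants_escalation)) {
    list(decision = "refill_with_escalation",
         daily_dose = rx$daily_dose * (1 + params$prescribing$dose_escalation_pct))
  } else {
    list(decision = "refill", daily_dose = rx$daily_dose)
  }
}

#' Daily probability of acute pain onset
#'
#' Converts the 15%/12-month acute-pain probability to a daily hazard via
#' [annual_to_daily_prob()].
#'
#' @param params An [abm_params()] object.
#' @return Daily onset probability.
#' @export
acute_pain_daily_prob <- function(params = abm_params()) {
  annual_to_daily_prob(params$prescribing$p_acute_pain_12mo)
}
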