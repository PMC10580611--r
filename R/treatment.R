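#' Assign treatment modality
#'
#' Categorical draw over medications for opioid use disorder at treatment
#' entry: 59% methadone, 38% buprenorphine-naloxone, 3% naltrexone.
#'
#' @param n Number of entrants.
#' @param modality_probs Named probabilities summing to 1 (within 1e-9).
#' @return Integer vector of modality codes (1 methadone, 2 buprenorphine,
#'   3 naltrexone); use `MOD_LEVELS` labels via [abm_params()] docs.
#' @export
assign_moud <- function(n, modality_probs = abm_params()$treatment$modality_probs) {
  if (abs(sum(modality_probs) - 1) > 1e-9) {
    stop("modality probabilities must sum to 1", call. = FALSE)
  }
  sample.int(length(modality_probs), n, replace = TRUE, prob = modality_probs)
}

milestones_for <- function(modality, tr) {
  switch(modality,
         methadone = tr$cess_methadone,
         buprenorphine = tr$cess_buprenorphine,
         naltrexone = tr$cess_naltrexone,
         stop("unknown modality: ", modality, call. = FALSE))
}

# Piecewise-constant daily hazards reproducing milestone cumulative cessation
# probabilities under exponential survival.  For milestones (d1, p1), (d2, p2)
# the hazards are h1 = -log(1 - p1) / d1 on days 1..d1 and
# h2 = -log((1 - p2) / (1 - p1)) / (d2 - d1) thereafter.
milestone_hazards <- function(milestones) {
  d <- as.numeric(names(milestones))
  p <- as.numeric(milestones)
  if (is.unsorted(d) || is.unsorted(p)) {
    stop("cessation milestones must be ordered and non-decreasing", call. = FALSE)
  }
  logS <- log(1 - p)
  h <- -diff(c(0, logS)) / diff(c(0, d))
  list(breaks = d, hazard = h)
}

#' Daily treatment-cessation hazard
#'
#' Piecewise-constant daily hazard whose exponential survival reproduces the
#' published milestone cumulative cessation probabilities: buprenorphine 0.31
#' by one month and 0.735 by one year; naltrexone 0.52 and 0.95; methadone
#' 0.55 by one year.  The final piece continues beyond the last milestone.
#'
#' @param modality `"methadone"`, `"buprenorphine"` or `"naltrexone"`.
#' @param days_in_treatment Non-negative day(s) since treatment entry.
#' @param params An [abm_params()] object.
#' @return Daily cessation probability (vectorized over `days_in_treatment`).
#' @examples
#' cessation_hazard("buprenorphine", c(10, 200))
#' @export
cessation_hazard <- function(modality, days_in_treatment,
                             params = abm_params()) {
  if (any(days_in_treatment < 0)) {
    stop("days_in_treatment must be >= 0", call. = FALSE)
  }
  hz <- milestone_hazards(milestones_for(modality, params$treatment))
  piece <- findInterval(days_in_treatment, hz$breaks, left.open = TRUE) + 1L
  piece <- pmin(piece, length(hz$hazard))
  1 - exp(-hz$hazard[piece])
}

#' Cumulative cessation probability under the piecewise hazard
#'
#' Closed-form survival complement used to verify that the daily hazards
#' reproduce the milestone probabilities exactly.
#'
#' @inheritParams cessation_hazard
#' @param day Day(s) since treatment entry.
#' @return Probability of having ceased treatment by `day`.
#' @export
cumulative_cessation_prob <- function(modality, day, params = abm_params()) {
  hz <- milestone_hazards(milestones_for(modality, params$treatment))
  edges <- c(0, hz$breaks)
  haz <- c(hz$hazard, hz$hazard[length(hz$hazard)])  # final piece continues
  vapply(day, function(d) {
    exposure <- pmax(0, pmin(d, c(edges[-1], Inf)) - edges)
    1 - exp(-sum(haz * exposure))
  }, numeric(1))
}

#' Overdose rate while on medication for opioid use disorder
#'
#' Methadone 2 and buprenorphine 2.08 per 100 person-years throughout the
#' episode; injectable naltrexone 3.85 per 100 person-years while the
#' injection is recent (under one month old), after which the injection has
#' lapsed for risk purposes and -- because agents in treatment consume no
#' illicit opioids -- the rate is 0.
#'
#' @param modality `"methadone"`, `"buprenorphine"` or `"naltrexone"`.
#' @param days_in_treatment Day(s) since treatment entry.
#' @param params An [abm_params()] object.
#' @return Rate per 100 person-years (vectorized over `days_in_treatment`).
#' @export
moud_overdose_rate <- function(modality, days_in_treatment,
                               params = abm_params()) {
  tr <- params$treatment
  switch(modality,
         methadone = rep(tr$od_rate_methadone, length(days_in_treatment)),
         buprenorphine = rep(tr$od_rate_buprenorphine, length(days_in_treatment)),
         naltrexone = ifelse(days_in_treatment < tr$naltrexone_recent_days,
                             tr$od_rate_naltrexone_recent, 0),
         stop("unknown modality: ", modality, call. = FALSE))
}

#' Daily probability of seeking treatment
#'
#' A quarter of agents misusing prescription opioids or using
#' heroin/fentanyl seek treatment at least once per year; converted to a
#' daily probability via [annual_to_daily_prob()].
#'
#' @param params An [abm_params()] object.
#' @return Daily seeking probability.
#' @export
seek_treatment_daily_prob <- function(params = abm_params()) {
  annual_to_daily_prob(params$treatment$p_seek_annual)
}
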