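#' Convert a person-year event rate to a daily probability
#'
#' Epidemiological rates quoted per 100 person-years (for example, overdose
#' rates while on medication for opioid use disorder) are applied at the
#' simulator's daily time step through the exponential-hazard transform
#' \eqn{p = 1 - \exp(-r / 36{,}500)}.  For the small rates typical of these
#' parameters the result is close to \eqn{r / 36{,}500}.
#'
#' @param rate_per_100py Non-negative event rate per 100 person-years.
#' @return Daily event probability, same length as `rate_per_100py`.
#' @examples
#' rate_to_daily_prob(2.08) # daily overdose probability on buprenorphine
#' @export
rate_to_daily_prob <- function(rate_per_100py) {
  if (any(!is.finite(rate_per_100py)) || any(rate_per_100py < 0)) {
    stop("`rate_per_100py` must be finite and non-negative", call. = FALSE)
  }
  1 - exp(-rate_per_100py / 36500)
}

#' Convert an annual probability to a daily probability
#'
#' Several model parameters are quoted as probabilities over 12 months (acute
#' pain onset, treatment seeking).  The daily probability that composes back
#' to the annual figure over 365 independent daily draws is
#' \eqn{p_d = 1 - (1 - p_a)^{1/365}}.
#'
#' @param annual_prob Probability in `[0, 1)` over a 365-day year.
#' @return Daily probability, same length as `annual_prob`.
#' @examples
#' annual_to_daily_prob(0.15) # daily hazard of acute pain onset
#' @export
annual_to_daily_prob <- function(annual_prob) {
  if (any(!is.finite(annual_prob)) || any(annual_prob < 0) || any(annual_prob >= 1)) {
    stop("`annual_prob` must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - annual_prob)^(1 / 365)
}
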