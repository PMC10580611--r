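# Agent use-state codes used throughout the daily-step machinery.
USE_LEVELS <- c("opioid_naive", "prescribed_po", "misuse_po", "dependent_po",
                "heroin_fentanyl", "in_treatment", "post_treatment", "dead")
U_NAIVE <- 1L; U_RX <- 2L; U_MISUSE <- 3L; U_DEP <- 4L; U_HEROIN <- 5L
U_TREAT <- 6L; U_POST <- 7L; U_DEAD <- 8L
MOD_LEVELS <- c("methadone", "buprenorphine", "naltrexone")

use_state_label <- function(code) USE_LEVELS[code]

#' Initialize a synthetic agent population
#'
#' Creates `n_agents` simulated people with chronic pain assigned by
#' prevalence, per-agent underlying analgesic need, per-physician refill and
#' monitoring behaviour, lifetime misuse/dependence propensities, an initial
#' out-of-treatment pool of agents with opioid use disorder (OUD), an initial
#' in-treatment census scaled from the statewide count, and initial chronic
#' pain prescriptions.  Opioid-naive agents start with internal state
#' (desire, tolerance, satiation) = (0, 0, 0).
#'
#' @param params An [abm_params()] object.
#' @param n_agents Number of agents (>= 1).
#' @param seed Optional integer seed; when given the population is
#'   bit-reproducible.
#' @return A tibble with one row per agent.
#' @examples
#' pop <- init_population(n_agents = 500, seed = 1)
#' table(pop$use_state)
#' @export
init_population <- function(params = abm_params(), n_agents = 10000,
                            seed = NULL) {
  validate_params(params)
  if (!is.numeric(n_agents) || n_agents < 1) {
    stop("n_agents must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_agents)
  if (!is.null(seed)) set.seed(seed)
  po <- params$population; pr <- params$prescribing; int <- params$internal

  pop <- new.env(parent = emptyenv())
  pop$agent_id <- seq_len(n)
  pop$alive <- rep(TRUE, n)
  pop$use <- rep(U_NAIVE, n)
  pop$pain <- ifelse(stats::runif(n) < po$chronic_pain_prevalence, 2L, 0L)
  pop$pain_days <- rep(0L, n)
  pop$acute_need <- ifelse(stats::runif(n) < pr$acute_need_split,
                           pr$acute_need_mme[1], pr$acute_need_mme[2])
  pop$chronic_need <- pmax(pr$dose_min,
                           stats::rnorm(n, pr$chronic_need_mean, pr$chronic_need_sd))
  pop$desire <- numeric(n)
  pop$tolerance <- numeric(n)
  pop$satiation <- numeric(n)
  pop$ever_exposed <- rep(FALSE, n)
  pop$rx_active <- rep(FALSE, n)
  pop$rx_dose <- numeric(n)
  pop$rx_days <- rep(0L, n)
  pop$rx_type <- rep(0L, n)          # 1 acute, 2 chronic
  pop$rx_capped <- rep(FALSE, n)
  pop$courses <- rep(0L, n)
  pop$phys_refill_acute <- pmin(1, pmax(0,
    stats::rnorm(n, pr$refill_acute_mean, pr$refill_acute_sd)))
  pop$phys_refill_chronic <- pmin(1, pmax(0,
    stats::rnorm(n, pr$refill_chronic_mean, pr$refill_chronic_sd)))
  pop$phys_pdmp <- stats::runif(n) < pr$p_pdmp_compliant
  pop$mis_prop <- stats::runif(n, pr$misuse_range[1], pr$misuse_range[2])
  pop$dep_prop <- pmin(stats::runif(n, pr$dependence_range[1],
                                    pr$dependence_range[2]), pop$mis_prop)
  pop$treat_mod <- rep(0L, n)
  pop$treat_days <- rep(0L, n)
  pop$prev_use <- rep(0L, n)
  pop$ever_bupe <- rep(FALSE, n)
  pop$ever_div_use <- rep(FALSE, n)
  pop$is_diverter <- rep(FALSE, n)
  pop$is_diverted_user <- rep(FALSE, n)
  pop$stock <- rep(0L, n)
  pop$unmet_days <- rep(0L, n)
  pop$od_count <- rep(0L, n)

  # Out-of-treatment OUD pool
  oud <- which(stats::runif(n) < po$initial_oud_prevalence)
  if (length(oud)) {
    mix <- po$oud_mix / sum(po$oud_mix)
    states <- c(U_MISUSE, U_DEP, U_HEROIN)[
      sample.int(3, length(oud), replace = TRUE, prob = mix)]
    pop$use[oud] <- states
    tol0 <- c(70, 100, 120)[match(states, c(U_MISUSE, U_DEP, U_HEROIN))]
    pop$tolerance[oud] <- pmax(10, stats::rnorm(length(oud), tol0, 20))
    pop$ever_exposed[oud] <- TRUE
  }

  # Initial in-treatment census (statewide count scaled to the agent sample)
  n_treat <- min(round(po$treatment_census / po$reference_population * n), n)
  if (n_treat >= 1) {
    cand <- which(pop$use == U_NAIVE)
    idx <- sample(cand, min(n_treat, length(cand)))
    mix <- po$oud_mix / sum(po$oud_mix)
    pop$prev_use[idx] <- c(U_MISUSE, U_DEP, U_HEROIN)[
      sample.int(3, length(idx), replace = TRUE, prob = mix)]
    pop$use[idx] <- U_TREAT
    pop$treat_mod[idx] <- assign_moud(length(idx), params$treatment$modality_probs)
    pop$treat_days[idx] <- as.integer(stats::runif(length(idx), 0, 180))
    pop$tolerance[idx] <- pmax(10, stats::rnorm(length(idx), 90, 25))
    pop$ever_exposed[idx] <- TRUE
    pop$ever_bupe[idx] <- pop$ever_bupe[idx] | pop$treat_mod[idx] == 2L
  }

  # Initial chronic-pain prescriptions among untreated, non-OUD agents
  cand <- which(pop$pain == 2L & pop$use == U_NAIVE)
  rx <- cand[stats::runif(length(cand)) < pr$p_rx_given_chronic]
  if (length(rx)) {
    dose <- draw_rx_dose(length(rx), pr$chronic_dose_mean, pr$chronic_dose_sd, pr)
    pop$use[rx] <- U_RX
    pop$rx_active[rx] <- TRUE
    pop$rx_dose[rx] <- dose$dose
    pop$rx_capped[rx] <- dose$capped
    pop$rx_days[rx] <- sample.int(pr$chronic_len_days[2], length(rx), replace = TRUE)
    pop$rx_type[rx] <- 2L
    pop$courses[rx] <- 1L
    pop$tolerance[rx] <- dose$dose
    pop$ever_exposed[rx] <- TRUE
  }

  # Desire for exposed agents tracks need and tolerance
  exposed <- which(pop$ever_exposed)
  pop$desire[exposed] <- pmin(int$desire_cap, pmax(
    agent_need(pop, exposed),
    desire_beta(pop$use[exposed], int) * pop$tolerance[exposed]))
  pop_as_tibble(pop)
}

# Pain-driven MME need currently active for the given agents.
agent_need <- function(pop, idx) {
  need <- numeric(length(idx))
  need[pop$pain[idx] == 1L] <- pop$acute_need[idx][pop$pain[idx] == 1L]
  need[pop$pain[idx] == 2L] <- pop$chronic_need[idx][pop$pain[idx] == 2L]
  need
}

desire_beta <- function(use, int) {
  b <- rep(1, length(use))
  b[use == U_MISUSE] <- int$beta_misuse
  b[use %in% c(U_DEP, U_HEROIN)] <- int$beta_dependent
  b
}

pop_as_tibble <- function(pop) {
  tibble::tibble(
    agent_id = pop$agent_id,
    alive = pop$alive,
    use_state = use_state_label(pop$use),
    pain = c("none", "acute", "chronic")[pop$pain + 1L],
    desire = pop$desire,
    tolerance = pop$tolerance,
    satiation = pop$satiation,
    ever_exposed = pop$ever_exposed,
    acute_need = pop$acute_need,
    chronic_need = pop$chronic_need,
    rx_active = pop$rx_active,
    rx_dose = pop$rx_dose,
    rx_days = pop$rx_days,
    rx_type = pop$rx_type,
    phys_refill_acute = pop$phys_refill_acute,
    phys_refill_chronic = pop$phys_refill_chronic,
    phys_pdmp = pop$phys_pdmp,
    mis_prop = pop$mis_prop,
    dep_prop = pop$dep_prop,
    treat_modality = c(NA_character_, MOD_LEVELS)[pop$treat_mod + 1L],
    treat_days = pop$treat_days,
    has_bupe_rx = pop$use == U_TREAT & pop$treat_mod == 2L,
    ever_bupe = pop$ever_bupe,
    ever_used_diverted_bupe = pop$ever_div_use,
    is_diverter = pop$is_diverter,
    is_diverted_user = pop$is_diverted_user,
    stock = pop$stock,
    overdose_count = pop$od_count
  )
}

# Rebuild the internal vector state from an init_population() tibble.
pop_from_tibble <- function(tb) {
  pop <- new.env(parent = emptyenv())
  pop$agent_id <- tb$agent_id
  pop$alive <- tb$alive
  pop$use <- match(tb$use_state, USE_LEVELS)
  pop$pain <- match(tb$pain, c("none", "acute", "chronic")) - 1L
  pop$pain_days <- rep(0L, nrow(tb))
  pop$desire <- tb$desire
  pop$tolerance <- tb$tolerance
  pop$satiation <- tb$satiation
  pop$ever_exposed <- tb$ever_exposed
  pop$acute_need <- tb$acute_need
  pop$chronic_need <- tb$chronic_need
  pop$rx_active <- tb$rx_active
  pop$rx_dose <- tb$rx_dose
  pop$rx_days <- as.integer(tb$rx_days)
  pop$rx_type <- as.integer(tb$rx_type)
  pop$rx_capped <- rep(FALSE, nrow(tb))
  pop$courses <- rep(1L, nrow(tb)) * as.integer(tb$rx_active)
  pop$phys_refill_acute <- tb$phys_refill_acute
  pop$phys_refill_chronic <- tb$phys_refill_chronic
  pop$phys_pdmp <- tb$phys_pdmp
  pop$mis_prop <- tb$mis_prop
  pop$dep_prop <- tb$dep_prop
  pop$treat_mod <- ifelse(is.na(tb$treat_modality), 0L,
                          match(tb$treat_modality, MOD_LEVELS))
  pop$treat_days <- as.integer(tb$treat_days)
  pop$prev_use <- rep(0L, nrow(tb))
  treated <- which(pop$use == U_TREAT)
  pop$prev_use[treated] <- U_MISUSE
  pop$ever_bupe <- tb$ever_bupe
  pop$ever_div_use <- tb$ever_used_diverted_bupe
  pop$is_diverter <- tb$is_diverter
  pop$is_diverted_user <- tb$is_diverted_user
  pop$stock <- as.integer(tb$stock)
  pop$unmet_days <- rep(0L, nrow(tb))
  pop$od_count <- as.integer(tb$overdose_count)
  pop
}

#' Update the internal desire/tolerance/satiation state after consumption
#'
#' Tolerance follows exponential smoothing toward the consumed dose,
#' `tol' = (1 - a) * tol + a * consumed`, with a fast rate `alpha` when the
#' dose is at or above current tolerance (tolerance builds with use) and a
#' slow rate `alpha_decay` otherwise (tolerance wanes in abstinence);
#' satiation is the bounded
#' ratio `min(1, consumed / max(desire, epsilon))`; desire is the larger of
#' the pain-driven need and `beta * tol'` (plus any recreational increment),
#' capped at `desire_cap`.  Repeated consumption of a constant dose drives
#' tolerance to that dose as a fixed point.
#'
#' @param state A list or tibble with numeric `desire`, `tolerance`,
#'   `satiation` (recycled to a common length).
#' @param consumed_mme Non-negative MME consumed today.
#' @param dynamics Internal-dynamics parameters (`abm_params()$internal`).
#' @param need Pain-driven MME need (desire floor), default 0.
#' @param beta Desire multiplier on tolerance, default 1.
#' @return A tibble with updated `desire`, `tolerance`, `satiation`.
#' @examples
#' update_internal_state(list(desire = 50, tolerance = 40, satiation = 0), 50)
#' @export
update_internal_state <- function(state, consumed_mme,
                                  dynamics = abm_params()$internal,
                                  need = 0, beta = 1) {
  if (any(!is.finite(consumed_mme)) || any(consumed_mme < 0)) {
    stop("consumed_mme must be non-negative", call. = FALSE)
  }
  a <- ifelse(consumed_mme >= state$tolerance, dynamics$alpha,
              dynamics$alpha_decay)
  tol <- (1 - a) * state$tolerance + a * consumed_mme
  sat <- pmin(1, consumed_mme / pmax(state$desire, dynamics$epsilon))
  des <- pmin(dynamics$desire_cap,
              pmax(need, beta * tol) + dynamics$recreational_increment)
  # never-exposed agents with no need remain at the (0,0,0) fixed point
  des[state$tolerance == 0 & consumed_mme == 0 & need == 0] <- 0
  tibble::tibble(desire = des, tolerance = tol, satiation = sat)
}

#' Daily opioid consumption sought by each agent
#'
#' Maps each agent's use state, prescription and desire onto the MME
#' consumed today and the opioid type that governs overdose hazard.
#' Prescribed patients take their prescribed daily dose; misusing and
#' dependent agents consume up to their desire from prescription plus an
#' illicit pill market capped at `illicit_po_max_mme`; heroin/fentanyl users
#' consume their desire.  Days on which an agent uses diverted buprenorphine
#' are resolved by the engine and contribute zero MME of other opioids.
#'
#' @param pop Population tibble from [init_population()].
#' @param params An [abm_params()] object.
#' @return Tibble with `agent_id`, `consumed_mme`, `opioid_type`
#'   (one of `"none"`, `"prescribed_po"`, `"illicit_po"`,
#'   `"heroin_fentanyl"`, `"moud"`).
#' @export
daily_consumption <- function(pop, params = abm_params()) {
  if (any(!pop$alive)) stop("dead agents cannot consume", call. = FALSE)
  use <- match(pop$use_state, USE_LEVELS)
  rx_supply <- ifelse(pop$rx_active, pop$rx_dose, 0)
  consumed <- numeric(nrow(pop))
  type <- rep("none", nrow(pop))
  i <- use == U_RX & pop$rx_active
  consumed[i] <- rx_supply[i]; type[i] <- "prescribed_po"
  i <- use %in% c(U_MISUSE, U_DEP)
  supply <- rx_supply[i] + params$prescribing$illicit_po_max_mme
  consumed[i] <- pmin(pop$desire[i], supply)
  type[i] <- ifelse(consumed[i] > rx_supply[i] | !pop$rx_active[i],
                    "illicit_po", "prescribed_po")
  i <- use == U_HEROIN
  consumed[i] <- pop$desire[i]; type[i] <- "heroin_fentanyl"
  type[use == U_TREAT] <- "moud"
  tibble::tibble(agent_id = pop$agent_id, consumed_mme = consumed,
                 opioid_type = type)
}
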