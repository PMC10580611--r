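#' Default model parameters
#'
#' Builds the full nested parameter set for the simulator.  Defaults are the
#' published point estimates for a North Carolina-scale population (pain and
#' prescribing behaviour, treatment modality mix and retention, buprenorphine
#' diversion mechanics, overdose and naloxone probabilities); where the
#' literature gives only qualitative guidance (internal-state dynamics,
#' network growth) the defaults are the package's documented modelling
#' choices (see the methods vignette).
#'
#' The two calibrated constants are `overdose$base_daily_hazard` (the daily
#' overdose probability of a prescription-opioid user in the reference
#' < 20 MME band) and `population$initial_oud_prevalence` (the initial
#' fraction of agents with out-of-treatment opioid use disorder).  They were
#' fixed once by a grid search anchoring the status-quo scenario to the
#' reference cumulative overdose totals and are not scenario knobs.
#'
#' @param ... Named blocks of overrides, e.g.
#'   `abm_params(overdose = list(base_daily_hazard = 1e-4))`.  Unknown block
#'   or field names are an error.
#' @return A nested list of class `"abm_params"`.
#' @examples
#' p <- abm_params()
#' p$treatment$modality_probs
#' @export
abm_params <- function(...) {
  defaults <- list(
    population = list(
      chronic_pain_prevalence = 1671000 / 10500000,
      reference_population = 10500000, # North Carolina residents
      treatment_census = 24227,        # statewide count, scaled to n_agents at init
      initial_oud_prevalence = 0.0010, # calibrated (out-of-treatment OUD fraction)
      oud_mix = c(misuse = 0.50, dependent = 0.40, heroin = 0.10),
      scale_factor = 1050              # reporting scale for 10,000 agents
    ),
    internal = list(
      alpha = 0.05,            # tolerance smoothing rate while using (per day)
      alpha_decay = 0.01,      # tolerance waning rate in abstinence (per day)
      beta_misuse = 1.10,      # desire multiplier on tolerance while misusing
      beta_dependent = 1.20,   # ... while dependent or using heroin/fentanyl
      epsilon = 1,             # MME floor in the satiation denominator
      desire_cap = 200,        # MME/day ceiling on desire
      recreational_increment = 0,
      naive_revert_tol = 1,    # tolerance below which a lapsed patient re-naives
      treatment_tolerance_decay = 0
    ),
    prescribing = list(
      p_acute_pain_12mo = 0.15,
      acute_pain_days = c(7, 14),
      p_rx_given_acute = 0.22,
      p_rx_given_chronic = 0.30,
      acute_dose_mean = 30, acute_dose_sd = 10,
      chronic_dose_mean = 50, chronic_dose_sd = 10,
      dose_min = 1,
      acute_len_days = c(3, 7),
      chronic_len_days = c(7, 28),
      refill_acute_mean = 0.25, refill_acute_sd = 0.10,
      refill_chronic_mean = 0.90, refill_chronic_sd = 0.10,
      dose_escalation_pct = 0.25,
      p_dose_cap_compliant = 0.927, dose_cap_mme = 90,
      p_pdmp_compliant = 0.775,
      acute_need_mme = c(6, 30), acute_need_split = 0.70,
      chronic_need_mean = 52, chronic_need_sd = 10,
      chronic_represent_annual = 0.25,
      misuse_range = c(0.08, 0.16),
      dependence_range = c(0.02, 0.14),
      misuse_courses_scale = 40,       # lifetime propensity spread over ~40 courses
      dependence_horizon_days = 365,
      illicit_po_max_mme = 60,         # daily illicit pill-market ceiling
      heroin_escalation_unmet_days = 7,
      p_heroin_escalation_daily = 0.0003
    ),
    treatment = list(
      p_seek_annual = 0.25,
      modality_probs = c(methadone = 0.59, buprenorphine = 0.38, naltrexone = 0.03),
      od_rate_methadone = 2,
      od_rate_buprenorphine = 2.08,
      od_rate_naltrexone_recent = 3.85,
      naltrexone_recent_days = 30,
      cess_methadone = c("365" = 0.55),
      cess_buprenorphine = c("30" = 0.31, "365" = 0.735),
      cess_naltrexone = c("30" = 0.52, "365" = 0.95),
      annual_entrants = 5167,          # consistency metric only, not a flow control
      capacity_refill = TRUE,
      refill_delay_days = 14
    ),
    diversion = list(
      p_divert_given_rx = 0.50,
      p_use_diverted_given_oud = 0.10,
      p_daily_use_diverted = 0.15,
      p_source_friend = 0.80,
      doses_per_week = c(1, 2),
      share_targets = c(1, 2),
      friend_doses = 1,
      dealer_max_doses = 3,
      dealer_fraction = 0.20,          # share of diverted doses routed to the dealer pool
      naive_leak_fraction = 0,
      p_naive_misuse = 0.01,
      p_naive_fatal_od = 0.003
    ),
    network = list(
      assortativity = 0.45,
      init_degree = 3,
      weekly_tie_prob = 0.009,
      degree_cap = 10,
      maintain_min_degree = 3
    ),
    overdose = list(
      mme_band_edges = c(20, 50, 100),
      band_hazard_ratios = c(1, 1.44, 3.73, 8.87),
      base_daily_hazard = 4.47e-05,    # calibrated
      heroin_od_multiplier = 1.7,
      p_fatal_given_od = 0.17,
      heroin_fatal_multiplier = 1.5,
      p_naloxone_available = 0.276,
      p_reversal_given_naloxone = 0.875,
      od_rate_diverted_bupe = 2.08,
      fatal_model = "sequential"       # 0.17 applies to non-reversed events
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown parameter block(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (blk in names(overrides)) {
      ov <- overrides[[blk]]
      badf <- setdiff(names(ov), names(defaults[[blk]]))
      if (length(badf)) {
        stop("unknown field(s) in block '", blk, "': ",
             paste(badf, collapse = ", "), call. = FALSE)
      }
      defaults[[blk]][names(ov)] <- ov
    }
  }
  structure(defaults, class = "abm_params")
}

#' Update parameters by dotted path
#'
#' @param params An `abm_params` object.
#' @param ... Named values with dotted paths, e.g.
#'   `params_update(p, "overdose.base_daily_hazard" = 1e-4)`.
#' @return The updated `abm_params` object.
#' @export
params_update <- function(params, ...) {
  stopifnot(inherits(params, "abm_params"))
  ov <- list(...)
  for (path in names(ov)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
        !parts[2] %in% names(params[[parts[1]]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    params[[parts[1]]][[parts[2]]] <- ov[[path]]
  }
  validate_params(params)
  params
}

prob_fields <- list(
  population = c("chronic_pain_prevalence", "initial_oud_prevalence"),
  prescribing = c("p_acute_pain_12mo", "p_rx_given_acute", "p_rx_given_chronic",
                  "refill_acute_mean", "refill_chronic_mean", "p_dose_cap_compliant",
                  "p_pdmp_compliant", "acute_need_split", "p_heroin_escalation_daily"),
  treatment = c("p_seek_annual"),
  diversion = c("p_divert_given_rx", "p_use_diverted_given_oud", "p_daily_use_diverted",
                "p_source_friend", "dealer_fraction", "naive_leak_fraction",
                "p_naive_misuse", "p_naive_fatal_od"),
  network = c("assortativity"),
  overdose = c("p_fatal_given_od", "p_naloxone_available", "p_reversal_given_naloxone")
)

#' Validate a parameter set
#'
#' Checks probabilities lie in `[0, 1]`, rates and doses are positive, band
#' edges are strictly increasing, modality probabilities sum to one, and
#' cessation milestones are non-decreasing with horizon.
#'
#' @param params An `abm_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "abm_params"))
  for (blk in names(prob_fields)) {
    for (f in prob_fields[[blk]]) {
      v <- params[[blk]][[f]]
      if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
        stop("parameter ", blk, "$", f, " must be a probability in [0, 1]",
             call. = FALSE)
      }
    }
  }
  ov <- params$overdose
  if (any(diff(ov$mme_band_edges) <= 0)) {
    stop("mme_band_edges must be strictly increasing", call. = FALSE)
  }
  if (length(ov$band_hazard_ratios) != length(ov$mme_band_edges) + 1 ||
      any(ov$band_hazard_ratios <= 0)) {
    stop("band_hazard_ratios must be positive, one per MME band", call. = FALSE)
  }
  if (ov$base_daily_hazard < 0 || ov$base_daily_hazard > 1) {
    stop("base_daily_hazard must be a probability", call. = FALSE)
  }
  tr <- params$treatment
  if (abs(sum(tr$modality_probs) - 1) > 1e-9) {
    stop("modality_probs must sum to 1", call. = FALSE)
  }
  for (m in c("cess_methadone", "cess_buprenorphine", "cess_naltrexone")) {
    ms <- tr[[m]]
    if (any(ms < 0) || any(ms > 1) || is.unsorted(ms)) {
      stop(m, " milestones must be probabilities, non-decreasing with horizon",
           call. = FALSE)
    }
  }
  for (r in c("od_rate_methadone", "od_rate_buprenorphine",
              "od_rate_naltrexone_recent")) {
    if (tr[[r]] < 0) stop(r, " must be non-negative", call. = FALSE)
  }
  pr <- params$prescribing
  for (d in c("acute_dose_mean", "acute_dose_sd", "chronic_dose_mean",
              "chronic_dose_sd", "chronic_need_mean", "chronic_need_sd")) {
    if (pr[[d]] <= 0) stop(d, " must be positive", call. = FALSE)
  }
  for (rg in c("acute_len_days", "chronic_len_days", "misuse_range",
               "dependence_range", "acute_pain_days")) {
    if (length(pr[[rg]]) != 2 || pr[[rg]][1] > pr[[rg]][2]) {
      stop(rg, " must be an ordered pair", call. = FALSE)
    }
  }
  if (params$population$scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.abm_params <- function(x, ...) {
  cat("<abm_params>\n")
  for (blk in names(x)) {
    cat(" $", blk, ": ", length(x[[blk]]), " parameters\n", sep = "")
  }
  invisible(x)
}

#' Diversion policy scenarios
#'
#' The three policy counterfactuals compared by the model:
#' * `status_quo` — 50% of buprenorphine patients divert 1–2 doses/week and
#'   10% of agents with out-of-treatment OUD use diverted buprenorphine;
#' * `controlled_only` — no diversion at all (both probabilities exactly 0);
#' * `increased_diversion` — 95% divert and 50% of agents with OUD use
#'   diverted buprenorphine.
#'
#' @param name One of `"status_quo"`, `"controlled_only"`,
#'   `"increased_diversion"`.
#' @param p_divert_given_rx,p_use_diverted_given_oud Optional overrides of the
#'   scenario's diversion probabilities (e.g. 0.90 for the lower
#'   increased-diversion variant).
#' @return A list of class `"abm_scenario"`.
#' @export
scenario_config <- function(name = c("status_quo", "controlled_only",
                                     "increased_diversion"),
                            p_divert_given_rx = NULL,
                            p_use_diverted_given_oud = NULL) {
  name <- match.arg(name)
  vals <- switch(name,
    status_quo          = c(0.50, 0.10),
    controlled_only     = c(0.00, 0.00),
    increased_diversion = c(0.95, 0.50)
  )
  if (name == "controlled_only" &&
      (!is.null(p_divert_given_rx) || !is.null(p_use_diverted_given_oud))) {
    stop("controlled_only forces both diversion probabilities to 0", call. = FALSE)
  }
  structure(list(
    name = name,
    p_divert_given_rx = p_divert_given_rx %||% vals[1],
    p_use_diverted_given_oud = p_use_diverted_given_oud %||% vals[2]
  ), class = "abm_scenario")
}

#' Sensitivity analyses
#'
#' * `s1` doubles the overdose rate while using diverted buprenorphine
#'   (2.08 to 4.16 per 100 person-years);
#' * `s2` raises the daily probability of using diverted buprenorphine from
#'   15% to 25%;
#' * `s3` raises it to 50%;
#' * `s4` leaks 3% of diverted doses to randomly chosen opioid-naive agents,
#'   who consume with probability 1% and die of overdose with probability
#'   0.3% upon consumption.
#'
#' @param id One of `"none"`, `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @return A list of class `"abm_sensitivity"`.
#' @export
sensitivity_config <- function(id = c("none", "s1", "s2", "s3", "s4")) {
  id <- match.arg(id)
  structure(list(id = id), class = "abm_sensitivity")
}

#' Resolve a full parameter set for a scenario/sensitivity pair
#'
#' @param params Base `abm_params`.
#' @param scenario An `abm_scenario` (or scenario name).
#' @param sensitivity An `abm_sensitivity` (or id).
#' @return An `abm_params` with the diversion/overdose knobs set.
#' @export
apply_scenario <- function(params = abm_params(),
                           scenario = scenario_config("status_quo"),
                           sensitivity = sensitivity_config("none")) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  if (is.character(sensitivity)) sensitivity <- sensitivity_config(sensitivity)
  params$diversion$p_divert_given_rx <- scenario$p_divert_given_rx
  params$diversion$p_use_diverted_given_oud <- scenario$p_use_diverted_given_oud
  params <- switch(sensitivity$id,
    none = params,
    s1 = params_update(params, "overdose.od_rate_diverted_bupe" = 4.16),
    s2 = params_update(params, "diversion.p_daily_use_diverted" = 0.25),
    s3 = params_update(params, "diversion.p_daily_use_diverted" = 0.50),
    s4 = {
      params$diversion$naive_leak_fraction <- 0.03
      params
    }
  )
  validate_params(params)
  params
}

#' Read / write parameter configuration files
#'
#' Parameters round-trip through a YAML file whose blocks mirror the
#' parameter sections (pain and opioid use states, physician behaviours,
#' treatment, buprenorphine diversion, overdose).
#'
#' @param path File path.
#' @param params An `abm_params` object.
#' @return `read_params_yaml` returns an `abm_params`;
#'   `write_params_yaml` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops names on unnamed numeric sequences; restore known named vectors
  p <- do.call(abm_params, lapply(raw, function(blk) blk))
  p$population$oud_mix <- unlist(p$population$oud_mix)
  p$treatment$modality_probs <- unlist(p$treatment$modality_probs)
  for (m in c("cess_methadone", "cess_buprenorphine", "cess_naltrexone")) {
    p$treatment[[m]] <- unlist(p$treatment[[m]])
  }
  for (f in names(p$prescribing)) p$prescribing[[f]] <- unlist(p$prescribing[[f]])
  for (f in names(p$overdose)) p$overdose[[f]] <- unlist(p$overdose[[f]])
  for (f in names(p$diversion)) p$diversion[[f]] <- unlist(p$diversion[[f]])
  validate_params(p)
  p
}

#' @rdname read_params_yaml
#' @export
write_params_yaml <- function(params, path) {
  validate_params(params)
  # named numeric vectors (modality probabilities, cessation milestones keyed
  # by day) must round-trip as YAML maps, not bare sequences
  out <- lapply(unclass(params), function(blk) {
    lapply(blk, function(x) {
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
    })
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
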