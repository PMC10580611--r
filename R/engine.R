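#' Run one simulation
#'
#' Executes `365 * years` daily steps over `n_agents` agents under a
#' scenario/sensitivity pair.  Each day runs pain onset, prescribing and
#' refills, misuse/dependence/heroin transitions, treatment entry and
#' cessation, buprenorphine diversion (supply, sourcing, replacement-day
#' use), consumption with internal-state updates, overdose occurrence and
#' resolution, and weekly network growth.  The run is bit-reproducible for a
#' fixed seed.
#'
#' @param scenario An [scenario_config()] or scenario name.
#' @param sensitivity A [sensitivity_config()] or id.
#' @param n_agents Number of agents.
#' @param years Years simulated (365-day years; `years = 0` gives an empty
#'   run).
#' @param seed Integer seed.
#' @param params Base [abm_params()] (before scenario application).
#' @param record_events Keep the per-event overdose log?
#' @param keep_population Return the final population tibble?
#' @return An object of class `"abm_run"`: a list with `daily` (tibble of
#'   day, overdoses, fatal_overdoses, treatment_census, diverted_users_ever),
#'   `totals`, `sharer_degrees`, `conservation`, `events`, optionally
#'   `population`, and `meta`.
#' @examples
#' r <- run_simulation("status_quo", n_agents = 500, years = 1, seed = 1)
#' r$totals$overdoses
#' @export
run_simulation <- function(scenario = scenario_config("status_quo"),
                           sensitivity = sensitivity_config("none"),
                           n_agents = 10000, years = 5, seed = 1,
                           params = abm_params(),
                           record_events = TRUE,
                           keep_population = FALSE) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  if (is.character(sensitivity)) sensitivity <- sensitivity_config(sensitivity)
  params <- apply_scenario(params, scenario, sensitivity)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })

  ndays <- as.integer(365 * years)
  sim <- sim_setup(params, n_agents, seed, record_events)
  od <- integer(ndays); fod <- integer(ndays)
  census <- integer(ndays); dusers <- integer(ndays)
  for (d in seq_len(ndays)) {
    sim_day(sim)
    od[d] <- sim$od_today
    fod[d] <- sim$fatal_today
    census[d] <- sim$census
    dusers[d] <- sim$n_div_users_ever
  }
  sharers <- which(sim$is_diverter & sim$alive)
  res <- list(
    daily = tibble::tibble(
      day = seq_len(ndays), overdoses = od, fatal_overdoses = fod,
      treatment_census = census, diverted_users_ever = dusers
    ),
    totals = list(
      overdoses = sum(od),
      fatal_overdoses = sum(fod),
      diverted_users = sim$n_div_users_ever,
      deaths = sum(!sim$alive),
      entrants_per_year = if (years > 0) sim$entrants / years else NA_real_
    ),
    sharer_degrees = net_degree(sim$net, sharers, sim$alive),
    conservation = list(
      diverted_total = sim$div_total,
      to_peers = sim$div_to_peers,
      to_dealer = sim$div_to_dealer,
      to_naive = sim$div_to_naive,
      consumed = sim$div_consumed,
      naive_consumed = sim$naive_consumed,
      naive_discarded = sim$naive_discarded,
      stocks_remaining = sum(sim$stock),
      dealer_pool = sim$dealer_pool
    ),
    events = tibble::tibble(
      day = sim$ev_day, agent_id = sim$ev_agent, opioid_type = sim$ev_type,
      naloxone_available = sim$ev_nal, reversed = sim$ev_rev,
      fatal = sim$ev_fatal
    ),
    meta = list(scenario = scenario$name, sensitivity = sensitivity$id,
                n_agents = n_agents, years = years, seed = seed,
                scale_factor = params$population$scale_factor)
  )
  if (keep_population) res$population <- pop_as_tibble(sim)
  structure(res, class = "abm_run")
}

#' @export
print.abm_run <- function(x, ...) {
  cat("<abm_run> scenario:", x$meta$scenario,
      "| sensitivity:", x$meta$sensitivity,
      "| agents:", x$meta$n_agents, "| years:", x$meta$years, "\n")
  cat("  overdoses:", x$totals$overdoses,
      "| fatal:", x$totals$fatal_overdoses,
      "| diverted-bup users:", x$totals$diverted_users, "\n")
  invisible(x)
}

#' Run a Monte-Carlo experiment
#'
#' Repeats [run_simulation()] `n_runs` times with per-run seeds derived
#' deterministically from `base_seed` so that runs are independent and
#' individually reproducible, and paired across scenarios under a common
#' `base_seed` (common random numbers).
#'
#' @inheritParams run_simulation
#' @param n_runs Number of Monte-Carlo runs.
#' @param base_seed Base integer seed.
#' @return An object of class `"abm_experiment"`: list with `runs` (tibble,
#'   one row per run), `daily_fatal` (days x runs matrix of fatal counts),
#'   `sharer_degrees` (list), and `meta`.
#' @export
run_experiment <- function(scenario = scenario_config("status_quo"),
                           sensitivity = sensitivity_config("none"),
                           n_runs = 100, n_agents = 10000, years = 5,
                           base_seed = 1, params = abm_params()) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  if (is.character(sensitivity)) sensitivity <- sensitivity_config(sensitivity)
  stopifnot(n_runs >= 1)
  seeds <- run_seeds(base_seed, n_runs)
  ndays <- as.integer(365 * years)
  daily_fatal <- matrix(0L, nrow = ndays, ncol = n_runs)
  degs <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- run_simulation(scenario, sensitivity, n_agents, years, seeds[r],
                          params, record_events = FALSE)
    daily_fatal[, r] <- run$daily$fatal_overdoses
    degs[[r]] <- run$sharer_degrees
    rows[[r]] <- tibble::tibble(
      run_id = r, seed = seeds[r],
      overdoses = run$totals$overdoses,
      fatal_overdoses = run$totals$fatal_overdoses,
      diverted_users = run$totals$diverted_users,
      mean_sharer_degree = if (length(run$sharer_degrees)) {
        mean(run$sharer_degrees)
      } else NA_real_
    )
  }
  structure(list(
    runs = dplyr::bind_rows(rows),
    daily_fatal = daily_fatal,
    sharer_degrees = degs,
    meta = list(scenario = scenario$name, sensitivity = sensitivity$id,
                n_runs = n_runs, n_agents = n_agents, years = years,
                base_seed = base_seed,
                scale_factor = params$population$scale_factor)
  ), class = "abm_experiment")
}

# Per-run seeds are drawn through the RNG rather than by arithmetic spacing:
# Mersenne-Twister streams initialized from nearby integer seeds start out
# correlated, which would correlate runs within an experiment.
run_seeds <- function(base_seed, n_runs) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(base_seed) %% 2147483646L)
  sample.int(2147483646L, n_runs)
}

#' @export
print.abm_experiment <- function(x, ...) {
  cat("<abm_experiment>", x$meta$n_runs, "runs | scenario:", x$meta$scenario,
      "| sensitivity:", x$meta$sensitivity, "\n")
  print(summarize_runs(x))
  invisible(x)
}

#' Summarize Monte-Carlo runs
#'
#' Scaled means and 90% credible intervals (5th-95th percentile across runs,
#' linear interpolation between closest order statistics) for cumulative
#' total overdoses, cumulative fatal overdoses, and the count of agents who
#' ever used diverted buprenorphine.
#'
#' @param experiment An `abm_experiment` (or a tibble of per-run outcomes
#'   with columns `overdoses`, `fatal_overdoses`, `diverted_users`).
#' @param scale_factor Population scale factor (defaults to the experiment's;
#'   1,050 scales 10,000 agents to 10.5 million residents).
#' @return A tibble of class `"abm_summary"`: `metric`, `mean`, `ci_lo`,
#'   `ci_hi`, `scale`, `n_runs`.
#' @export
summarize_runs <- function(experiment, scale_factor = NULL) {
  runs <- if (inherits(experiment, "abm_experiment")) experiment$runs
          else tibble::as_tibble(experiment)
  if (nrow(runs) < 1) stop("no runs to summarize", call. = FALSE)
  if (is.null(scale_factor)) {
    scale_factor <- if (inherits(experiment, "abm_experiment")) {
      experiment$meta$scale_factor
    } else 1
  }
  metrics <- c("overdoses", "fatal_overdoses", "diverted_users")
  out <- purrr::map_dfr(metrics, function(m) {
    x <- runs[[m]] * scale_factor
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
    tibble::tibble(metric = m, mean = mean(x), ci_lo = q[1], ci_hi = q[2])
  })
  if ("mean_sharer_degree" %in% names(runs) &&
      any(is.finite(runs$mean_sharer_degree))) {
    x <- runs$mean_sharer_degree[is.finite(runs$mean_sharer_degree)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "mean_sharer_degree", mean = mean(x),
      ci_lo = stats::quantile(x, 0.05, names = FALSE),
      ci_hi = stats::quantile(x, 0.95, names = FALSE)
    ))
    out$scale <- c(rep(scale_factor, 3), 1)
  } else {
    out$scale <- scale_factor
  }
  out$n_runs <- nrow(runs)
  class(out) <- c("abm_summary", class(out))
  out
}

#' Compare two scenario summaries
#'
#' Averted events in the alternative scenario relative to the baseline:
#' `averted_count = baseline_mean - alternative_mean` and
#' `averted_pct = 100 * averted_count / baseline_mean`.  Positive values are
#' averted events, negative values additional events.
#'
#' @param baseline,alternative `abm_summary` tibbles on the same scale.
#' @param metric Which metric to compare (default fatal overdoses).
#' @return A one-row tibble: `metric`, `baseline_mean`, `alternative_mean`,
#'   `averted_count`, `averted_pct` (NA when the baseline mean is 0).
#' @examples
#' # 10,658 vs 10,301 fatal overdoses -> 357 averted (3.35%)
#' @export
compare_scenarios <- function(baseline, alternative,
                              metric = "fatal_overdoses") {
  b <- baseline$mean[baseline$metric == metric]
  a <- alternative$mean[alternative$metric == metric]
  if (!length(b) || !length(a)) stop("metric not found in summaries", call. = FALSE)
  averted <- b - a
  tibble::tibble(
    metric = metric, baseline_mean = b, alternative_mean = a,
    averted_count = averted,
    averted_pct = if (b == 0) NA_real_ else 100 * averted / b
  )
}

#' Run the full scenario-by-sensitivity grid
#'
#' Produces the full comparison matrix: three scenarios (status quo,
#' controlled prescription only, increased diversion) under the main
#' analysis and each sensitivity.  The controlled-only scenario involves no
#' diverted buprenorphine, so its results are identical across sensitivity
#' blocks; the engine runs it once and reuses the rows.  Comparisons are
#' computed within each block against that block's status quo.
#'
#' @inheritParams run_experiment
#' @param sensitivities Character vector of blocks to run.
#' @return A tibble with one row per block x scenario: summary means and
#'   credible intervals plus averted fatal overdoses vs. that block's status
#'   quo.
#' @export
run_experiment_grid <- function(sensitivities = c("none", "s1", "s2", "s3", "s4"),
                                n_runs = 100, n_agents = 10000, years = 5,
                                base_seed = 1, params = abm_params()) {
  scen_names <- c("status_quo", "controlled_only", "increased_diversion")
  b_exp <- run_experiment("controlled_only", "none", n_runs, n_agents, years,
                          base_seed, params)
  b_sum <- summarize_runs(b_exp)
  rows <- list()
  for (sens in sensitivities) {
    sums <- list()
    for (sc in scen_names) {
      sums[[sc]] <- if (sc == "controlled_only") {
        b_sum  # identical across blocks: no diverted buprenorphine involved
      } else {
        summarize_runs(run_experiment(sc, sens, n_runs, n_agents, years,
                                      base_seed, params))
      }
    }
    for (sc in scen_names) {
      s <- sums[[sc]]
      cmp <- if (sc == "status_quo") {
        tibble::tibble(averted_count = NA_real_, averted_pct = NA_real_)
      } else {
        compare_scenarios(sums$status_quo, s)[, c("averted_count", "averted_pct")]
      }
      g <- function(m, f) s[[f]][s$metric == m]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = sens, scenario = sc,
        total_mean = g("overdoses", "mean"),
        total_lo = g("overdoses", "ci_lo"), total_hi = g("overdoses", "ci_hi"),
        fatal_mean = g("fatal_overdoses", "mean"),
        fatal_lo = g("fatal_overdoses", "ci_lo"),
        fatal_hi = g("fatal_overdoses", "ci_hi"),
        diverted_users_mean = g("diverted_users", "mean"),
        averted_fatal = cmp$averted_count, averted_pct = cmp$averted_pct
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Scaled cumulative fatal-overdose curves
#'
#' Daily cumulative fatal overdoses per scenario, averaged across runs and
#' scaled to the reference population, suitable for plotting the five-year
#' trajectories.
#'
#' @param experiments A named list of `abm_experiment` objects (names are
#'   used as scenario labels), or a single experiment.
#' @return A tibble of class `"abm_curves"`: `scenario`, `day`,
#'   `cumulative_fatal` (monotone non-decreasing per scenario).
#' @export
cumulative_curves <- function(experiments) {
  if (inherits(experiments, "abm_experiment")) {
    experiments <- stats::setNames(list(experiments),
                                   experiments$meta$scenario)
  }
  out <- purrr::imap_dfr(experiments, function(ex, nm) {
    if (nrow(ex$daily_fatal) == 0) {
      return(tibble::tibble(scenario = character(0), day = integer(0),
                            cumulative_fatal = numeric(0)))
    }
    cum <- apply(ex$daily_fatal, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    tibble::tibble(
      scenario = nm, day = seq_len(nrow(cum)),
      cumulative_fatal = rowMeans(cum) * ex$meta$scale_factor
    )
  })
  class(out) <- c("abm_curves", class(out))
  out
}
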