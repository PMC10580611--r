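test_that("runs are bit-reproducible under a fixed seed", {
  r1 <- small_run(n_agents = 2000, years = 1, seed = 42)
  r2 <- small_run(n_agents = 2000, years = 1, seed = 42)
  expect_identical(r1$daily, r2$daily)
  expect_identical(r1$totals, r2$totals)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$sharer_degrees, r2$sharer_degrees)
  # and the caller's RNG state is left untouched
  set.seed(1); before <- .Random.seed
  invisible(small_run(n_agents = 500, years = 1, seed = 7))
  expect_identical(before, .Random.seed)
})

test_that("controlled-only equals status quo with diversion probabilities zeroed", {
  r1 <- small_run("controlled_only", n_agents = 2000, years = 1, seed = 11)
  p0 <- abm_params()
  sc <- scenario_config("status_quo")
  sc$p_divert_given_rx <- 0
  sc$p_use_diverted_given_oud <- 0
  r2 <- run_simulation(sc, "none", n_agents = 2000, years = 1, seed = 11,
                       params = p0)
  expect_identical(r1$daily, r2$daily)
  expect_identical(r1$totals, r2$totals)
})

test_that("years = 0 yields an empty run", {
  r <- run_simulation("status_quo", "none", n_agents = 100, years = 0, seed = 1)
  expect_equal(nrow(r$daily), 0)
  expect_equal(r$totals$overdoses, 0)
  expect_equal(r$totals$fatal_overdoses, 0)
})

test_that("summaries use scaled means and type-7 percentile credible intervals", {
  # degenerate spread: identical runs
  runs <- tibble::tibble(overdoses = rep(80, 5), fatal_overdoses = rep(10, 5),
                         diverted_users = rep(3, 5))
  s <- summarize_runs(runs, scale_factor = 1050)
  expect_equal(s$mean[s$metric == "fatal_overdoses"], 10500)
  expect_equal(s$ci_lo[s$metric == "fatal_overdoses"], 10500)
  expect_equal(s$ci_hi[s$metric == "fatal_overdoses"], 10500)
  # brute-force percentile oracle on 1..100 at scale 1: sort and interpolate
  runs <- tibble::tibble(overdoses = 1:100, fatal_overdoses = 1:100,
                         diverted_users = 0)
  s <- summarize_runs(runs, scale_factor = 1)
  x <- sort(1:100)
  h <- 0.05 * 99 + 1  # type-7 position for the 5th percentile
  lo <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  h <- 0.95 * 99 + 1
  hi <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  expect_equal(s$mean[1], 50.5)
  expect_equal(s$ci_lo[1], lo)
  expect_equal(s$ci_hi[1], hi)
  expect_error(summarize_runs(runs[0, ]), "no runs")
})

test_that("scaling is linear: summarize at scale 1 then multiply", {
  ex <- cached_experiment("tiny_sq", run_experiment(
    "status_quo", "none", n_runs = 3, n_agents = 1500, years = 1, base_seed = 5))
  s1 <- summarize_runs(ex, scale_factor = 1)
  s2 <- summarize_runs(ex, scale_factor = 1050)
  m <- s1$metric %in% c("overdoses", "fatal_overdoses", "diverted_users")
  expect_equal(s1$mean[m] * 1050, s2$mean[m])
  expect_equal(s1$ci_lo[m] * 1050, s2$ci_lo[m])
})

test_that("scenario comparisons report averted counts and percentages", {
  mk <- function(fatal) {
    s <- summarize_runs(tibble::tibble(overdoses = fatal * 8,
                                       fatal_overdoses = fatal,
                                       diverted_users = 0), 1)
    s
  }
  cmp <- compare_scenarios(mk(10658), mk(10301))
  expect_equal(cmp$averted_count, 357)
  expect_equal(cmp$averted_pct, 100 * 357 / 10658, tolerance = 1e-9)
  cmp <- compare_scenarios(mk(10658), mk(10741))
  expect_equal(cmp$averted_count, -83)
  expect_lt(cmp$averted_pct, 0)
  cmp <- compare_scenarios(mk(5), mk(5))
  expect_equal(cmp$averted_count, 0)
  expect_equal(cmp$averted_pct, 0)
  expect_true(is.na(compare_scenarios(mk(0), mk(0))$averted_pct))
})

test_that("the experiment grid has 15 rows with the controlled-only row shared", {
  grid <- cached_experiment("tiny_grid", run_experiment_grid(
    sensitivities = c("none", "s1", "s2", "s3", "s4"),
    n_runs = 2, n_agents = 1000, years = 1, base_seed = 9))
  expect_equal(nrow(grid), 15)
  expect_equal(unique(grid$scenario),
               c("status_quo", "controlled_only", "increased_diversion"))
  b <- grid[grid$scenario == "controlled_only", ]
  for (col in c("total_mean", "fatal_mean", "fatal_lo", "fatal_hi")) {
    expect_true(all(b[[col]] == b[[col]][1]))
  }
  # comparisons are within-block: status quo rows have no comparison
  expect_true(all(is.na(grid$averted_fatal[grid$scenario == "status_quo"])))
  expect_true(all(!is.na(grid$averted_fatal[grid$scenario != "status_quo"])))
})

test_that("cumulative curves are monotone and consistent with totals", {
  ex <- cached_experiment("tiny_sq", run_experiment(
    "status_quo", "none", n_runs = 3, n_agents = 1500, years = 1, base_seed = 5))
  cv <- cumulative_curves(list(status_quo = ex))
  expect_equal(nrow(cv), 365)
  expect_true(all(diff(cv$cumulative_fatal) >= 0))
  s <- summarize_runs(ex)
  expect_equal(cv$cumulative_fatal[365], s$mean[s$metric == "fatal_overdoses"])
  # zero-overdose curve is flat at zero
  p0 <- abm_params(overdose = list(base_daily_hazard = 0),
                   treatment = list(od_rate_methadone = 0,
                                    od_rate_buprenorphine = 0,
                                    od_rate_naltrexone_recent = 0))
  ex0 <- run_experiment("status_quo", "none", n_runs = 1, n_agents = 500,
                        years = 1, base_seed = 2, params = p0)
  cv0 <- cumulative_curves(list(a = ex0))
  expect_true(all(cv0$cumulative_fatal == 0))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("tidy and glance methods expose experiment summaries", {
  ex <- cached_experiment("tiny_sq", run_experiment(
    "status_quo", "none", n_runs = 3, n_agents = 1500, years = 1, base_seed = 5))
  td <- generics::tidy(ex)
  expect_true(all(c("metric", "mean", "ci_lo", "ci_hi") %in% names(td)))
  gl <- generics::glance(ex)
  expect_equal(gl$n_runs, 3)
  expect_equal(gl$scenario, "status_quo")
})

test_that("parameters validate, update by path, and round-trip through YAML", {
  p <- abm_params()
  expect_silent(validate_params(p))
  p2 <- params_update(p, "overdose.base_daily_hazard" = 1e-4)
  expect_equal(p2$overdose$base_daily_hazard, 1e-4)
  expect_error(params_update(p, "overdose.nope" = 1), "unknown parameter path")
  expect_error(abm_params(nonsense = list(a = 1)), "unknown parameter block")
  expect_error(abm_params(overdose = list(p_fatal_given_od = 2)), NA)
  expect_error(validate_params(abm_params(
    overdose = list(p_fatal_given_od = 2))), "probability")
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(p, f)
  p3 <- read_params_yaml(f)
  expect_equal(p3$overdose$base_daily_hazard, p$overdose$base_daily_hazard)
  expect_equal(unname(p3$treatment$modality_probs),
               unname(p$treatment$modality_probs))
  expect_equal(p3$prescribing$misuse_range, p$prescribing$misuse_range)
  unlink(f)
})

test_that("scenario configuration enforces the controlled-only contract", {
  sc <- scenario_config("controlled_only")
  expect_identical(sc$p_divert_given_rx, 0)
  expect_identical(sc$p_use_diverted_given_oud, 0)
  expect_error(scenario_config("controlled_only", p_divert_given_rx = 0.5),
               "forces")
  # the lower increased-diversion variant is reachable by override
  sc <- scenario_config("increased_diversion", p_divert_given_rx = 0.90)
  expect_equal(sc$p_divert_given_rx, 0.90)
  s <- sensitivity_config("s3")
  p <- apply_scenario(abm_params(), "status_quo", s)
  expect_equal(p$diversion$p_daily_use_diverted, 0.50)
  p <- apply_scenario(abm_params(), "status_quo", "s1")
  expect_equal(p$overdose$od_rate_diverted_bupe, 4.16)
  p <- apply_scenario(abm_params(), "status_quo", "s4")
  expect_equal(p$diversion$naive_leak_fraction, 0.03)
})
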