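test_that("population initialization hits expected prevalences and is reproducible", {
  p <- abm_params()
  pop <- init_population(p, n_agents = 10000, seed = 1)
  expect_equal(nrow(pop), 10000)
  # chronic pain prevalence 1,671,000 / 10,500,000
  expect_equal(mean(pop$pain == "chronic"), 1671000 / 10500000, tolerance = 0.015)
  # treatment census scaled from the statewide 24,227
  expect_equal(sum(pop$use_state == "in_treatment"),
               round(24227 / 10500000 * 10000), tolerance = 0)
  # opioid-naive agents start at (0, 0, 0)
  naive <- pop$use_state == "opioid_naive" & !pop$ever_exposed
  expect_true(all(pop$desire[naive] == 0))
  expect_true(all(pop$tolerance[naive] == 0))
  expect_true(all(pop$satiation[naive] == 0))
  # bit-reproducible
  expect_identical(pop, init_population(p, n_agents = 10000, seed = 1))
})

test_that("expected chronic-pain count matches a binomial draw over many seeds", {
  p <- abm_params()
  counts <- vapply(1:20, function(s) {
    sum(init_population(p, n_agents = 2000, seed = s)$pain == "chronic")
  }, numeric(1))
  expected <- 2000 * 1671000 / 10500000
  se <- sqrt(2000 * 0.159 * 0.841 / 20)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("degenerate populations initialize cleanly", {
  p <- abm_params(population = list(chronic_pain_prevalence = 0,
                                    initial_oud_prevalence = 0,
                                    treatment_census = 0))
  pop <- init_population(p, n_agents = 1, seed = 1)
  expect_equal(nrow(pop), 1)
  expect_equal(pop$use_state, "opioid_naive")
  expect_equal(c(pop$desire, pop$tolerance, pop$satiation), c(0, 0, 0))
  expect_error(init_population(p, n_agents = 0), ">= 1")
  bad <- p; bad$population$initial_oud_prevalence <- 1.5
  expect_error(init_population(bad, 10), "probability")
})

test_that("internal state obeys its invariants under random consumption streams", {
  dyn <- abm_params()$internal
  set.seed(31)
  for (rep in 1:25) {
    st <- list(desire = 0, tolerance = 0, satiation = 0)
    need <- sample(c(0, 6, 30, 52), 1)
    beta <- sample(c(1, 1.1, 1.2), 1)
    for (d in 1:200) {
      cons <- sample(c(0, 0, 10, 30, 60, 120), 1)
      st <- update_internal_state(st, cons, dyn, need = need, beta = beta)
      expect_gte(st$satiation, 0); expect_lte(st$satiation, 1)
      expect_gte(st$tolerance, 0)
      expect_gte(st$desire, 0); expect_lte(st$desire, dyn$desire_cap)
    }
  }
})

test_that("zero exposure is a fixed point and constant dosing converges to it", {
  dyn <- abm_params()$internal
  st <- update_internal_state(list(desire = 0, tolerance = 0, satiation = 0), 0, dyn)
  expect_equal(unlist(st), c(desire = 0, tolerance = 0, satiation = 0))
  # constant dose D: tolerance fixed point is D (independent oracle: iterate)
  D <- 40
  st <- list(desire = 0, tolerance = 0, satiation = 0)
  for (i in 1:2000) st <- update_internal_state(st, D, dyn)
  expect_equal(st$tolerance, D, tolerance = 1e-6)
  expect_lte(st$tolerance, D + 1e-9)
  # a day consuming at least desire is fully satiating
  st <- update_internal_state(list(desire = 50, tolerance = 40, satiation = 0), 50, dyn)
  expect_equal(st$satiation, 1)
  expect_error(update_internal_state(st, -1), "non-negative")
})

test_that("daily consumption maps states to sources and respects death", {
  p <- abm_params()
  pop <- init_population(p, n_agents = 200, seed = 2)
  cons <- daily_consumption(pop, p)
  naive <- pop$use_state == "opioid_naive"
  expect_true(all(cons$consumed_mme[naive] == 0))
  rx <- pop$use_state == "prescribed_po" & pop$rx_active
  expect_equal(cons$consumed_mme[rx], pop$rx_dose[rx])
  expect_true(all(cons$opioid_type[rx] == "prescribed_po"))
  # an agent on a 30 MME acute prescription with desire <= 30 takes the dose
  one <- pop[1, ]; one$use_state <- "prescribed_po"; one$rx_active <- TRUE
  one$rx_dose <- 30; one$desire <- 20
  expect_equal(daily_consumption(one, p)$consumed_mme, 30)
  # heroin user consumes desire
  one$use_state <- "heroin_fentanyl"; one$desire <- 50
  out <- daily_consumption(one, p)
  expect_equal(out$consumed_mme, 50)
  expect_equal(out$opioid_type, "heroin_fentanyl")
  one$alive <- FALSE
  expect_error(daily_consumption(one, p), "dead")
})

test_that("dead agents take no further part in the simulation", {
  r <- small_run(n_agents = 4000, years = 3, seed = 12, keep_population = TRUE)
  pop <- r$population
  dead <- pop[!pop$alive, ]
  if (nrow(dead)) {
    expect_true(all(dead$use_state == "dead"))
    expect_true(all(!dead$rx_active))
    expect_true(all(!dead$is_diverter & !dead$is_diverted_user))
    # overdose count per agent never exceeds events attributed to them, and
    # every dead agent's final event was fatal
    fatal_agents <- r$events$agent_id[r$events$fatal]
    expect_setequal(dead$agent_id, fatal_agents)
  }
  expect_true(all(pop$overdose_count >= 0))
})
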