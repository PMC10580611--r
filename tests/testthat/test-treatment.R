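test_that("piecewise hazards reproduce the cessation milestones exactly", {
  # buprenorphine: 0.31 by day 30, 0.735 by day 365
  expect_equal(cumulative_cessation_prob("buprenorphine", c(30, 365)),
               c(0.31, 0.735), tolerance = 1e-12)
  # methadone: 0.55 by one year; naltrexone: 0.52 / 0.95
  expect_equal(cumulative_cessation_prob("methadone", 365), 0.55, tolerance = 1e-12)
  expect_equal(cumulative_cessation_prob("naltrexone", c(30, 365)),
               c(0.52, 0.95), tolerance = 1e-12)
  # hazard constant within pieces, continuing beyond the last milestone
  h <- cessation_hazard("buprenorphine", c(1, 15, 30, 31, 200, 365, 400))
  expect_equal(h[1], h[3])         # days 1..30 share the first piece
  expect_equal(h[4], h[7])         # day 31 onward share the second piece
  expect_false(isTRUE(all.equal(h[1], h[4])))
  expect_error(cessation_hazard("buprenorphine", -1), ">= 0")
})

test_that("zero milestone probabilities give zero hazard (nobody ceases)", {
  p <- abm_params(treatment = list(cess_methadone = c("365" = 0)))
  expect_equal(cessation_hazard("methadone", 1:400, p), rep(0, 400))
})

test_that("milestones out of order are a configuration error", {
  p <- abm_params()
  p$treatment$cess_buprenorphine <- c("30" = 0.8, "365" = 0.5)
  expect_error(validate_params(p), "non-decreasing")
})

test_that("modality assignment reproduces the 59/38/3 split", {
  set.seed(7)
  draws <- assign_moud(10000)
  freq <- tabulate(draws, 3) / 10000
  chi <- suppressWarnings(stats::chisq.test(tabulate(draws, 3),
                                            p = c(0.59, 0.38, 0.03)))
  expect_gt(chi$p.value, 0.01)
  expect_equal(freq, c(0.59, 0.38, 0.03), tolerance = 0.05)
  # degenerate: all mass on methadone
  expect_true(all(assign_moud(50, c(1, 0, 0)) == 1L))
  expect_error(assign_moud(1, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("on-treatment overdose rates follow modality and the naltrexone window", {
  expect_equal(moud_overdose_rate("buprenorphine", 100), 2.08)
  expect_equal(moud_overdose_rate("methadone", c(1, 400)), c(2, 2))
  expect_equal(moud_overdose_rate("naltrexone", c(10, 45)), c(3.85, 0))
  expect_error(moud_overdose_rate("acupuncture", 1), "unknown modality")
  expect_equal(rate_to_daily_prob(moud_overdose_rate("naltrexone", 45)), 0)
})

test_that("daily treatment seeking probability composes to the annual 25%", {
  pd <- seek_treatment_daily_prob()
  expect_equal(pd, 1 - 0.75^(1 / 365), tolerance = 1e-12)
  set.seed(11)
  sought <- stats::rbinom(20000, 365, pd) > 0
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(mean(sought) - 0.25), 3.3 * se)
})

test_that("simulated cessation reproduces milestones (Kaplan-Meier check)", {
  # simulate episode lengths directly from the daily hazards
  set.seed(5)
  n <- 4000
  p <- abm_params()
  sim_len <- function(mod) {
    h <- cessation_hazard(mod, 1:400, p)
    vapply(seq_len(n), function(i) {
      u <- stats::runif(400)
      d <- which(u < h)[1]
      if (is.na(d)) 401L else d
    }, integer(1))
  }
  len <- sim_len("buprenorphine")
  expect_equal(mean(len <= 30), 0.31, tolerance = 0.03)
  expect_equal(mean(len <= 365), 0.735, tolerance = 0.03)
  len <- sim_len("methadone")
  expect_equal(mean(len <= 365), 0.55, tolerance = 0.03)
})

test_that("agents leaving treatment return to their prior use state", {
  r <- small_run(n_agents = 4000, years = 2, seed = 3, keep_population = TRUE)
  pop <- r$population
  # everyone currently in treatment has a modality; nobody else does
  trt <- pop$use_state == "in_treatment"
  expect_true(all(!is.na(pop$treat_modality[trt])))
  expect_true(all(is.na(pop$treat_modality[!trt & pop$alive])))
  # treated agents never consume illicit opioids in the same step: their
  # overdose events carry the moud label only
  mo <- r$events[r$events$opioid_type == "moud", ]
  expect_true(all(mo$agent_id %in% pop$agent_id))
})
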