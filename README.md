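# diversim

Agent-based simulation of buprenorphine diversion and opioid overdose at
statewide scale.

## The problem

Buprenorphine-naloxone halves overdose risk for people in treatment for
opioid use disorder (OUD), and observational work suggests it is protective
even when obtained outside formal care.  Policies that lower prescribing
barriers are nevertheless criticized for enabling *diversion* — prescribed
doses rerouted to people they were not prescribed to.  Whether increased
diversion raises or lowers population-level overdose deaths cannot be
answered by trial: `diversim` answers it *in silico*, with a daily-step
agent-based model of a 10.5-million-resident state (North Carolina scale)
sampled as 10,000 agents.

The model simulates, per agent and per day:

* pain onset and physician prescribing (acute 30 MME/day, chronic
  50 MME/day prescriptions, refills, a 90 MME/day cap with 92.7%
  compliance);
* internal state — *desire* (MME/day sought), *tolerance* (MME/day needed
  to reach satiation, exponential smoothing toward the consumed dose), and
  *satiation* (bounded ratio of consumption to desire);
* progression from prescribed use to misuse (8–16% of the ever-prescribed),
  dependence (2–14%) and heroin/fentanyl use;
* treatment with medications for OUD (59% methadone / 38% buprenorphine /
  3% naltrexone; piecewise-exponential retention reproducing the published
  cessation milestones, e.g. buprenorphine 0.31 by one month, 0.735 by one
  year);
* buprenorphine diversion through an assortatively mixed peer network
  (assortativity 0.45): diverters share 1–2 doses/week with 1–2 peers,
  recipients source 80% from friends (one dose) vs. dealers (up to 3), and
  a diverted-buprenorphine day *replaces* the day's other opioid use;
* overdose: a dose-band hazard (MME < 20, 20–49, 50–99, ≥ 100 with ratios
  1, 1.44, 3.73, 8.87), a 1.7× heroin/fentanyl multiplier, person-year
  rates while on MOUD (2 / 2.08 / 3.85 per 100 p-y), naloxone availability
  27.6% with 87.5% reversal, and conditional fatality 0.17 (× 1.5 for
  heroin).

Three policy scenarios are compared over 5 years × 100 runs: **status quo**
(50% of buprenorphine patients divert; 10% of OUD agents use diverted
buprenorphine), **controlled prescription only** (no diversion), and
**increased diversion** (95% divert; 50% use), plus four sensitivity
analyses (doubled diverted-bup overdose risk; 25% and 50% daily-use
probability; 3% leakage to opioid-naive individuals with 1% consumption and
0.3% case fatality).

## Worked example

```r
library(diversim)

ex <- run_experiment("status_quo", "none",
                     n_runs = 10, n_agents = 10000, years = 5,
                     base_seed = 1)
summarize_runs(ex)
#> # A tibble: 4 x 6
#>   metric                mean   ci_lo    ci_hi scale n_runs
#>   <chr>                <dbl>   <dbl>    <dbl> <dbl>  <int>
#> 1 overdoses          80955   70822.  98595     1050     10
#> 2 fatal_overdoses     9345    5722.  13178.    1050     10
#> 3 diverted_users     19215   15750   23205     1050     10
#> 4 mean_sharer_degree     4.8     3.5     6.55     1     10
```

Reading the output: over five simulated years the status-quo scenario
produces ≈ 81,000 opioid overdoses and ≈ 9,300 fatal overdoses scaled to
the 10.5-million-person state (the published experiment reports 80,833 and
10,658; at 10 runs the Monte-Carlo error on the fatal mean is ≈ ±1,100),
with ≈ 19,000 people ever using diverted buprenorphine and sharers
connected to ≈ 5 peers.  `ci_lo`/`ci_hi` are the 90% credible interval
(5th–95th percentile across runs).

Compare scenarios and draw the cumulative fatal-overdose curves:

```r
exb <- run_experiment("controlled_only", "none", n_runs = 10, base_seed = 1)
compare_scenarios(summarize_runs(ex), summarize_runs(exb))
autoplot(cumulative_curves(list(status_quo = ex, controlled_only = exb)))
```

`run_experiment_grid()` produces the full 15-row scenario × sensitivity
matrix; `tidy()`/`glance()` give broom-style summaries; a command-line
front end lives at `inst/cli/diversim.R`
(`Rscript inst/cli/diversim.R run --scenario status_quo --runs 10 --out out/`).

Parameters are a nested `abm_params()` object round-tripping through YAML
(`inst/extdata/default-params.yaml`); every default is the published point
estimate, except two constants (`overdose$base_daily_hazard`,
`population$initial_oud_prevalence`) calibrated once against the published
status-quo totals — see the methods vignette
(`vignettes/model-and-methods.Rmd`).

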