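---
title: "Model and methods: simulating buprenorphine diversion and opioid overdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`diversim` is a daily-step agent-based model of prescription-opioid use,
opioid use disorder (OUD), treatment, buprenorphine diversion and overdose
in a synthetic population representing a 10.5-million-resident state at a
1:1,050 sampling ratio (10,000 agents).  This vignette explains the model,
the functional forms chosen where the literature gives only qualitative
guidance, the calibration protocol, and what the package's tests do and do
not establish.

## The daily cycle

Each simulated day every agent passes through a fixed sequence:

1. **Pain.** Acute pain begins with daily probability
   $1-(1-0.15)^{1/365}$ (15% per 12 months) and lasts 7–14 days; chronic
   pain is assigned at initialization (prevalence 1,671,000/10.5 M) and
   persists.
2. **Prescribing.** Presenting agents receive an opioid with probability
   0.22 (acute; 30 MME/day, SD 10, 3–7 days) or 0.30 (chronic; 50 MME/day,
   SD 10, 7–28 days).  92.7% of prescriptions comply with the < 90 MME/day
   cap.  At expiry, the agent's physician refills with per-physician
   probability (acute mean 25% SD 10%, chronic mean 90% SD 10%), escalating
   the dose by 25% when desire exceeds the current dose; 77.5% of
   physicians honour prescription-monitoring rules and deny overlapping
   prescriptions.
3. **Use-state transitions.** Lifetime propensities are drawn per agent
   (misuse ~ U(0.08, 0.16); dependence ~ U(0.02, 0.14), truncated at the
   misuse draw so dependence lies within the misuse pathway).  Misuse
   onset is evaluated at prescription-course boundaries with per-course
   probability `mis_prop / misuse_courses_scale`; dependent agents whose
   desire exceeds obtainable supply (prescription plus a 60 MME/day illicit
   pill ceiling) for 7 consecutive days escalate to heroin/fentanyl with a
   small daily probability.
4. **Treatment.** Agents misusing opioids or using heroin seek treatment
   with daily probability $1-(1-0.25)^{1/365}$; entrants are assigned
   methadone/buprenorphine/naltrexone at 59/38/3%.  Retention follows
   piecewise-exponential hazards that reproduce the published milestones
   exactly (buprenorphine 0.31 by day 30 and 0.735 by day 365; naltrexone
   0.52/0.95; methadone 0.55 by one year).  On cessation the agent returns
   to the most recent active use state.
5. **Diversion.** Buprenorphine patients divert 1–2 doses per week to 1–2
   network peers (diverter probability is the scenario knob); flagged users
   take diverted buprenorphine with daily probability 0.15, sourcing 80%
   from friends (one dose) and otherwise from a dealer pool (up to 3
   doses).  A buprenorphine day replaces all other opioid use that day.
6. **Consumption and internal state** (below).
7. **Overdose** (below).
8. **Network growth** (below).

Diversion runs before consumption because replacement-day semantics must
be settled before the day's exposure is known; everything else follows the
natural causal order of a clinic day.

## Internal state: desire, tolerance, satiation

The three internal variables lack quantitative literature, so the package
uses the simplest forms with the right qualitative behaviour:

* **Tolerance** chases the consumed dose by exponential smoothing,
  $T_{t+1} = (1-a)T_t + a\,C_t$, with $a = 0.05$ while using
  ($C_t \ge T_t$; tolerance builds over weeks) and $a = 0.01$ in
  abstinence (tolerance wanes over months).  The asymmetry reflects opioid
  pharmacology — tolerance develops faster than it resolves — and it
  matters here: replacement days (buprenorphine) pull tolerance, and hence
  subsequent desire and dose, downward only slowly, so occasional
  substitution does not implausibly collapse an agent's use.
* **Satiation** is the bounded ratio
  $\min(1, C_t / \max(D_t, 1\,\text{MME}))$.
* **Desire** is the larger of the pain-driven need (6 or 30 MME acute,
  N(52, 10) chronic) and $\beta T$, capped at 200 MME/day, with
  $\beta = 1$ for compliant patients, 1.1 for misuse and 1.2 for
  dependence/heroin — the margin by which seeking outruns tolerance.

Opioid-naive agents sit at the fixed point $(0, 0, 0)$ and stay there
without exposure; a lapsed patient whose tolerance decays below 1 MME
returns to the opioid-naive state.

## Treatment census

The published inputs give a standing census of 24,227 people in treatment
and about 5,167 new entrants per year.  Those two numbers imply a mean
system residence of several years, which cannot be produced by 25%/year
seeking combined with the one-year cessation milestones alone (the
equilibrium census would be roughly a quarter of the out-of-treatment
pool).  The package therefore treats the census as an operating capacity:
freed slots are re-offered to the eligible pool with a mean two-week
waiting delay, in addition to spontaneous seeking.  This holds the census
near its initialized value — matching the standing count the model is
anchored to — while retention within an episode still follows the
milestone hazards.  The annual-entrant count is reported as a diagnostic
(`totals$entrants_per_year`), not used as a flow control.

## Overdose

Prescription-opioid exposure carries a piecewise-constant daily hazard
over the standard MME risk bands (< 20, 20–49, 50–99, ≥ 100) with hazard
ratios (1, 1.44, 3.73, 8.87), scaled by one free constant
(`base_daily_hazard`); heroin/fentanyl multiplies the band value by 1.7.
Person-year rates (2, 2.08, 3.85 per 100 p-y on methadone, buprenorphine
and recent naltrexone; 2.08 on a diverted-buprenorphine day) convert to
daily probabilities via $1-e^{-r/36500}$.  After the 30-day naltrexone
window the injection has lapsed for risk purposes; because agents in
treatment consume no illicit opioids, their hazard is then zero.

On an overdose, naloxone is available with probability 0.276 and reverses
with probability 0.875; a reversed overdose is never fatal.  The published
0.17 fatality is read as conditional on non-reversal (sequential
composition); heroin multiplies it by 1.5.  A configuration flag
(`fatal_model = "marginal"`) instead treats 0.17 as the marginal fatality
and rescales accordingly — the two readings are observationally similar at
the aggregate level, and the sequential one is the default because the
0.17 was calibrated jointly with naloxone coverage in the source model.

## Peer network

Agents who have ever held a buprenorphine prescription or used diverted
buprenorphine form an active network.  New members join with 3 ties;
partner choice is assortative: with probability 0.45 the partner is drawn
from the ever-buprenorphine pool, otherwise uniformly from the living
population.  Members add roughly one tie per hundred weeks
(`weekly_tie_prob = 0.009`), maintain at least 3 surviving ties, and are
capped at 10.  The initial degree, growth rate and cap were fixed once so
that the emergent statistic among sharers matches the published
description — a mean of about 5 peers with an observed range inside
3–10 — mirroring the source model's treatment of mixing as an
experimental parameter.

## Calibration

Two constants are free: `overdose$base_daily_hazard` (4.47e-5/day) and
`population$initial_oud_prevalence` (0.10% out-of-treatment OUD at day 0).
They were fixed by a grid search at reduced replication (batches of 16–80
runs of 10,000 agents × 5 years, ~200 runs pooled at the final structure)
so that the status-quo scenario's scaled five-year means fall inside the
published 90% credible intervals (total overdoses 77,736–84,016; fatal
9,699–11,679), then frozen for every other scenario and sensitivity.

The structural defaults that shape composition were settled during model
construction and then left alone: the published fatal-to-total ratio
(10,658/80,833 ≈ 0.132) pins the heroin/fentanyl share of overdoses to a
small value, because under the naloxone mechanics a prescription-opioid
overdose is fatal with probability (1 − 0.276·0.875)·0.17 ≈ 0.129 while a
heroin overdose is fatal with ≈ 0.193 — the printed ratio only leaves room
for a minority heroin share.  Hence the OUD pool mix defaults to 50%
misuse / 40% dependent / 10% heroin and the dependence-to-heroin
escalation rate is small (0.0003/day once supply has been inadequate for a
week).  A consequence worth stating plainly: with little heroin exposure
among diverted-buprenorphine users, the per-day protection of a
replacement dose is modest, so the simulated averted-overdose effects of
diversion sit at the low end of the published point estimates (which the
source analysis itself describes as within-noise).

## Monte-Carlo design and what the tests show

Each run derives three RNG substreams (main dynamics, diversion/network,
overdose resolution) from its seed, so paired-seed scenario comparisons
share most of their randomness.  Runs are bit-reproducible; per-run seeds
derive deterministically from the experiment's base seed.

Summaries report scaled means and 90% credible intervals as the 5th–95th
percentile across runs (type-7 linear interpolation between order
statistics).  One caveat a user should know: with ~10 fatal events per
10,000-agent run, the across-run percentile interval is several times
wider than the published interval, whose width is closer to a standard
error of the mean over 100 runs.  The package reports the percentile
definition; the *means* are the comparable quantities.

Scenario differences (83–578 scaled fatal overdoses) are small relative to
run-to-run noise — the source analysis itself notes its credible intervals
overlap and attributes small differences to stochasticity.  The test suite
therefore checks levels against the published intervals, and checks the
direction and ordering of scenario effects with explicit Monte-Carlo error
margins estimated from paired runs, rather than asserting noise-level
point values.

Problem sizes: unit tests use 500–5,000 agents over 1–3 years; the
reproduction checks and `scripts/acceptance.R` use 16–36 runs of 10,000
agents over 5 years, the sizes at which the calibration anchors hold.

## What the synthetic population does not capture

The population is closed (no births, ageing, migration or non-overdose
mortality) and urban/rural structure, treatment-access heterogeneity,
money or goods exchange for diverted medication, illicitly manufactured
buprenorphine, fentanyl exposure through stimulants, and polysubstance use
(beyond the sensitivity-1 risk multiplier) are not modelled.  The
opioid-naive leakage sensitivity models only acute exposure outcomes —
naive agents do not progress into sustained OUD.  Passing tests establish
internal consistency with the published parameters and totals, not
fidelity to any future real-world trajectory.
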