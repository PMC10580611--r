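population:
  chronic_pain_prevalence: 0.1591429
  reference_population: 1.05e+07
  treatment_census: 24227.0
  initial_oud_prevalence: 0.001
  oud_mix:
    misuse: 0.5
    dependent: 0.4
    heroin: 0.1
  scale_factor: 1050.0
internal:
  alpha: 0.05
  alpha_decay: 0.01
  beta_misuse: 1.1
  beta_dependent: 1.2
  epsilon: 1.0
  desire_cap: 200.0
  recreational_increment: 0.0
  naive_revert_tol: 1.0
  treatment_tolerance_decay: 0.0
prescribing:
  p_acute_pain_12mo: 0.15
  acute_pain_days:
  - 7.0
  - 14.0
  p_rx_given_acute: 0.22
  p_rx_given_chronic: 0.3
  acute_dose_mean: 30.0
  acute_dose_sd: 10.0
  chronic_dose_mean: 50.0
  chronic_dose_sd: 10.0
  dose_min: 1.0
  acute_len_days:
  - 3.0
  - 7.0
  chronic_len_days:
  - 7.0
  - 28.0
  refill_acute_mean: 0.25
  refill_acute_sd: 0.1
  refill_chronic_mean: 0.9
  refill_chronic_sd: 0.1
  dose_escalation_pct: 0.25
  p_dose_cap_compliant: 0.927
  dose_cap_mme: 90.0
  p_pdmp_compliant: 0.775
  acute_need_mme:
  - 6.0
  - 30.0
  acute_need_split: 0.7
  chronic_need_mean: 52.0
  chronic_need_sd: 10.0
  chronic_represent_annual: 0.25
  misuse_range:
  - 0.08
  - 0.16
  dependence_range:
  - 0.02
  - 0.14
  misuse_courses_scale: 40.0
  dependence_horizon_days: 365.0
  illicit_po_max_mme: 60.0
  heroin_escalation_unmet_days: 7.0
  p_heroin_escalation_daily: 0.0003
treatment:
  p_seek_annual: 0.25
  modality_probs:
    methadone: 0.59
    buprenorphine: 0.38
    naltrexone: 0.03
  od_rate_methadone: 2.0
  od_rate_buprenorphine: 2.08
  od_rate_naltrexone_recent: 3.85
  naltrexone_recent_days: 30.0
  cess_methadone:
    '365': 0.55
  cess_buprenorphine:
    '30': 0.31
    '365': 0.735
  cess_naltrexone:
    '30': 0.52
    '365': 0.95
  annual_entrants: 5167.0
  capacity_refill: yes
  refill_delay_days: 14.0
diversion:
  p_divert_given_rx: 0.5
  p_use_diverted_given_oud: 0.1
  p_daily_use_diverted: 0.15
  p_source_friend: 0.8
  doses_per_week:
  - 1.0
  - 2.0
  share_targets:
  - 1.0
  - 2.0
  friend_doses: 1.0
  dealer_max_doses: 3.0
  dealer_fraction: 0.2
  naive_leak_fraction: 0.0
  p_naive_misuse: 0.01
  p_naive_fatal_od: 0.003
network:
  assortativity: 0.45
  init_degree: 3.0
  weekly_tie_prob: 0.009
  degree_cap: 10.0
  maintain_min_degree: 3.0
overdose:
  mme_band_edges:
  - 20.0
  - 50.0
  - 100.0
  band_hazard_ratios:
  - 1.0
  - 1.44
  - 3.73
  - 8.87
  base_daily_hazard: 4.47e-05
  heroin_od_multiplier: 1.7
  p_fatal_given_od: 0.17
  heroin_fatal_multiplier: 1.5
  p_naloxone_available: 0.276
  p_reversal_given_naloxone: 0.875
  od_rate_diverted_bupe: 2.08
  fatal_model: sequential
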