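# Internal daily-step machinery.  The simulation state lives in an
# environment of parallel vectors (one entry per agent) plus the peer
# network, the dealer pool, counters and the RNG streams.  Daily work is
# kept proportional to the number of opioid-exposed agents by maintaining
# index sets (active opioid states, in-treatment, acute pain) instead of
# scanning the whole population.
#
# Within-day order: pain -> prescribing -> use-state transitions ->
# treatment -> diversion -> consumption/internal-state -> overdose ->
# network growth.  Diversion precedes consumption because a diverted
# buprenorphine dose replaces the day's opioid consumption.

is_oud_state <- function(use) use == U_MISUSE | use == U_DEP | use == U_HEROIN

# --- RNG streams -----------------------------------------------------------
# Three independent substreams (main dynamics / diversion + network /
# overdose resolution) so that paired-seed scenario comparisons share the
# bulk of their randomness (common random numbers).

make_streams <- function(seed, n_streams = 3L) {
  set.seed(seed)
  ints <- sample.int(.Machine$integer.max - 1L, n_streams)
  lapply(ints, function(s) {
    set.seed(s)
    get(".Random.seed", envir = globalenv())
  })
}

use_stream <- function(sim, k) {
  if (sim$cur_stream == k) return(invisible())
  sim$streams[[sim$cur_stream]] <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", sim$streams[[k]], envir = globalenv())
  sim$cur_stream <- k
  invisible()
}

# --- index-set bookkeeping -------------------------------------------------
# idx_active: agents in states prescribed_po..heroin_fentanyl (the only
# agents that consume opioids and carry internal-state dynamics).
# idx_treat: agents in treatment.  idx_acute: agents in acute pain.

idx_add <- function(sim, field, ids) {
  if (length(ids)) sim[[field]] <- c(sim[[field]], ids)
  invisible()
}

idx_remove <- function(sim, field, ids) {
  if (length(ids)) sim[[field]] <- sim[[field]][!(sim[[field]] %in% ids)]
  invisible()
}

# --- setup -----------------------------------------------------------------

sim_setup <- function(params, n_agents, seed, record_events = TRUE) {
  streams <- make_streams(seed)
  assign(".Random.seed", streams[[1]], envir = globalenv())

  sim <- pop_from_tibble(init_population(params, n_agents))
  sim$streams <- streams
  sim$cur_stream <- 1L
  sim$params <- params
  sim$n <- as.integer(n_agents)
  sim$day <- 0L

  po <- params$population; pr <- params$prescribing
  tr <- params$treatment; ov <- params$overdose
  sim$p_onset <- annual_to_daily_prob(pr$p_acute_pain_12mo)
  sim$p_represent <- annual_to_daily_prob(pr$chronic_represent_annual)
  sim$p_seek <- annual_to_daily_prob(tr$p_seek_annual)
  sim$p_dep_daily <- 1 - (1 - sim$dep_prop / sim$mis_prop)^(1 / pr$dependence_horizon_days)
  sim$capacity <- min(round(po$treatment_census / po$reference_population * sim$n),
                      sim$n)
  sim$p_trt_od <- c(rate_to_daily_prob(tr$od_rate_methadone),
                    rate_to_daily_prob(tr$od_rate_buprenorphine),
                    rate_to_daily_prob(tr$od_rate_naltrexone_recent))
  sim$p_bupe_day <- rate_to_daily_prob(ov$od_rate_diverted_bupe)
  sim$cess <- lapply(MOD_LEVELS, function(m) {
    hz <- milestone_hazards(milestones_for(m, tr))
    list(breaks = hz$breaks, p = 1 - exp(-hz$hazard))
  })

  sim$cons <- numeric(sim$n)
  sim$cons_type <- integer(sim$n)    # 0 none, 1 PO, 2 heroin, 3 diverted bupe
  sim$bupe_today <- logical(sim$n)
  sim$new_oud <- integer(0)          # agents newly eligible as diverted users
  sim$new_bupe <- integer(0)         # agents newly entering bupe treatment

  sim$idx_active <- which(sim$use >= U_RX & sim$use <= U_HEROIN)
  sim$idx_treat <- which(sim$use == U_TREAT)
  sim$idx_acute <- integer(0)
  sim$chronic_ids <- which(sim$pain == 2L)
  sim$n_painfree <- sim$n - length(sim$chronic_ids)

  sim$net <- new_network(sim$n)
  sim$dealer_pool <- 0L
  sim$div_total <- 0L; sim$div_to_peers <- 0L
  sim$div_to_dealer <- 0L; sim$div_to_naive <- 0L
  sim$div_consumed <- 0L; sim$naive_consumed <- 0L; sim$naive_discarded <- 0L
  sim$entrants <- 0L
  sim$census <- length(sim$idx_treat)
  sim$n_div_users_ever <- sum(sim$ever_div_use)
  sim$od_today <- 0L; sim$fatal_today <- 0L
  sim$record_events <- record_events
  sim$ev_day <- integer(0); sim$ev_agent <- integer(0)
  sim$ev_type <- character(0); sim$ev_nal <- logical(0)
  sim$ev_rev <- logical(0); sim$ev_fatal <- logical(0)

  # initial diversion roles and network membership (diversion stream)
  use_stream(sim, 2L)
  sim_assign_roles(sim, sim$idx_treat[sim$treat_mod[sim$idx_treat] == 2L],
                   sim$idx_active[is_oud_state(sim$use[sim$idx_active])])
  sim_net_join(sim, which(sim$ever_bupe | sim$ever_div_use | sim$is_diverted_user))
  use_stream(sim, 1L)
  sim
}

sim_assign_roles <- function(sim, bupe_idx, oud_idx) {
  dv <- sim$params$diversion
  if (length(bupe_idx)) {
    sim$is_diverter[bupe_idx] <- stats::runif(length(bupe_idx)) < dv$p_divert_given_rx
  }
  if (length(oud_idx)) {
    sim$is_diverted_user[oud_idx] <-
      stats::runif(length(oud_idx)) < dv$p_use_diverted_given_oud
  }
  invisible()
}

sim_bupe_pool <- function(sim) {
  pool <- which(sim$ever_bupe | sim$ever_div_use)
  pool[sim$alive[pool]]
}

sim_net_join <- function(sim, members) {
  if (!length(members)) return(invisible())
  nw <- sim$params$network
  bupe_pool <- sim_bupe_pool(sim)
  for (i in members) {
    net_join(sim$net, i, nw$init_degree, bupe_pool, sim$alive, nw$assortativity,
             nw$degree_cap)
  }
  invisible()
}

# --- daily sections --------------------------------------------------------

step_pain <- function(sim) {
  # resolve ongoing acute pain
  if (length(sim$idx_acute)) {
    sim$pain_days[sim$idx_acute] <- sim$pain_days[sim$idx_acute] - 1L
    done <- sim$idx_acute[sim$pain_days[sim$idx_acute] <= 0L]
    if (length(done)) {
      sim$pain[done] <- 0L
      sim$n_painfree <- sim$n_painfree + sum(sim$alive[done])
      idx_remove(sim, "idx_acute", done)
    }
  }
  # acute onsets: binomial count over the pain-free pool, then draw ids
  sim$presenting_acute <- integer(0)
  if (sim$n_painfree > 0L) {
    k <- stats::rbinom(1L, sim$n_painfree, sim$p_onset)
    if (k > 0L) {
      onset <- integer(0)
      while (length(onset) < k) {
        cand <- sample.int(sim$n, 1L)
        if (sim$alive[cand] && sim$pain[cand] == 0L && !(cand %in% onset)) {
          onset <- c(onset, cand)
        }
      }
      pd <- sim$params$prescribing$acute_pain_days
      sim$pain[onset] <- 1L
      sim$pain_days[onset] <- as.integer(stats::runif(k, pd[1], pd[2] + 1))
      sim$n_painfree <- sim$n_painfree - k
      idx_add(sim, "idx_acute", onset)
      sim$presenting_acute <- onset
    }
  }
  invisible()
}

sim_issue <- function(sim, idx, type) {
  if (!length(idx)) return(invisible())
  pr <- sim$params$prescribing
  if (type == 1L) {
    d <- draw_rx_dose(length(idx), pr$acute_dose_mean, pr$acute_dose_sd, pr)
    len <- pr$acute_len_days
  } else {
    d <- draw_rx_dose(length(idx), pr$chronic_dose_mean, pr$chronic_dose_sd, pr)
    len <- pr$chronic_len_days
  }
  sim$rx_active[idx] <- TRUE
  sim$rx_dose[idx] <- d$dose
  sim$rx_capped[idx] <- d$capped
  sim$rx_days[idx] <- len[1] + sample.int(len[2] - len[1] + 1L, length(idx),
                                          replace = TRUE) - 1L
  sim$rx_type[idx] <- type
  sim$courses[idx] <- sim$courses[idx] + 1L
  naive <- idx[sim$use[idx] == U_NAIVE]
  if (length(naive)) {
    sim$use[naive] <- U_RX
    idx_add(sim, "idx_active", naive)
  }
  sim$ever_exposed[idx] <- TRUE
  invisible()
}

step_prescribing <- function(sim) {
  pr <- sim$params$prescribing
  # acute presentations (today's onsets in an eligible, unprescribed state)
  pres <- sim$presenting_acute
  pres <- pres[(sim$use[pres] == U_NAIVE | sim$use[pres] == U_RX) &
                 !sim$rx_active[pres]]
  if (length(pres)) {
    sim_issue(sim, pres[stats::runif(length(pres)) < pr$p_rx_given_acute], 1L)
  }
  # chronic re-presentation (chronic-pain roster is fixed at initialization)
  ch <- sim$chronic_ids
  cand <- ch[sim$alive[ch] & !sim$rx_active[ch] &
               (sim$use[ch] == U_NAIVE | sim$use[ch] == U_RX)]
  if (length(cand)) {
    pres <- cand[stats::runif(length(cand)) < sim$p_represent]
    if (length(pres)) {
      sim_issue(sim, pres[stats::runif(length(pres)) < pr$p_rx_given_chronic], 2L)
    }
  }
  # expiry, refills and course-boundary misuse conversion
  act <- sim$idx_active[sim$rx_active[sim$idx_active]]
  if (length(act)) {
    sim$rx_days[act] <- sim$rx_days[act] - 1L
    ex <- act[sim$rx_days[act] <= 0L]
    if (length(ex)) {
      still <- ifelse(sim$rx_type[ex] == 1L, sim$pain[ex] == 1L, sim$pain[ex] == 2L)
      p_ref <- ifelse(sim$rx_type[ex] == 1L,
                      sim$phys_refill_acute[ex], sim$phys_refill_chronic[ex])
      grant <- still & stats::runif(length(ex)) < p_ref
      g <- ex[grant]
      if (length(g)) {
        esc <- g[sim$desire[g] > sim$rx_dose[g]]
        sim$rx_dose[esc] <- sim$rx_dose[esc] * (1 + pr$dose_escalation_pct)
        over <- esc[sim$rx_capped[esc] & sim$rx_dose[esc] >= pr$dose_cap_mme]
        sim$rx_dose[over] <- pr$dose_cap_mme - 1e-6
        len1 <- pr$acute_len_days; len2 <- pr$chronic_len_days
        len <- ifelse(sim$rx_type[g] == 1L,
                      len1[1] + sample.int(len1[2] - len1[1] + 1L,
                                           length(g), replace = TRUE) - 1L,
                      len2[1] + sample.int(len2[2] - len2[1] + 1L,
                                           length(g), replace = TRUE) - 1L)
        sim$rx_days[g] <- as.integer(len)
        sim$courses[g] <- sim$courses[g] + 1L
      }
      den <- ex[!grant]
      sim$rx_active[den] <- FALSE
      sim$rx_days[den] <- 0L
      # course boundary: lifetime misuse propensity spread over typical courses
      cb <- ex[sim$use[ex] == U_RX]
      if (length(cb)) {
        conv <- cb[stats::runif(length(cb)) <
                     sim$mis_prop[cb] / pr$misuse_courses_scale]
        if (length(conv)) {
          sim$use[conv] <- U_MISUSE
          sim$new_oud <- c(sim$new_oud, conv)
        }
      }
    }
  }
  invisible()
}

step_transitions <- function(sim) {
  pr <- sim$params$prescribing
  idx <- sim$idx_active
  # misuse -> dependence
  mis <- idx[sim$use[idx] == U_MISUSE]
  if (length(mis)) {
    dep <- mis[stats::runif(length(mis)) < sim$p_dep_daily[mis]]
    sim$use[dep] <- U_DEP
  }
  # dependence -> heroin/fentanyl when desire outstrips obtainable supply
  dep <- idx[sim$use[idx] == U_DEP]
  if (length(dep)) {
    supply <- ifelse(sim$rx_active[dep], sim$rx_dose[dep], 0) + pr$illicit_po_max_mme
    unmet <- sim$desire[dep] > supply
    sim$unmet_days[dep] <- ifelse(unmet, sim$unmet_days[dep] + 1L, 0L)
    elig <- dep[sim$unmet_days[dep] >= pr$heroin_escalation_unmet_days]
    if (length(elig)) {
      esc <- elig[stats::runif(length(elig)) < pr$p_heroin_escalation_daily]
      if (length(esc)) {
        sim$use[esc] <- U_HEROIN
        sim$rx_active[esc] <- FALSE
        sim$new_oud <- c(sim$new_oud, esc)
      }
    }
  }
  invisible()
}

step_treatment <- function(sim) {
  tr <- sim$params$treatment
  elig <- sim$idx_active[is_oud_state(sim$use[sim$idx_active])]
  enter <- integer(0)
  if (length(elig)) {
    enter <- elig[stats::runif(length(elig)) < sim$p_seek]
    if (isTRUE(tr$capacity_refill)) {
      gap <- sim$capacity - (sim$census + length(enter))
      rest <- setdiff(elig, enter)
      if (gap > 0 && length(rest)) {
        k <- stats::rbinom(1, gap, 1 / tr$refill_delay_days)
        k <- min(k, length(rest))
        if (k > 0) enter <- c(enter, rest[sample.int(length(rest), k)])
      }
    }
  }
  if (length(enter)) {
    sim$entrants <- sim$entrants + length(enter)
    sim$census <- sim$census + length(enter)
    sim$prev_use[enter] <- sim$use[enter]
    sim$use[enter] <- U_TREAT
    sim$treat_days[enter] <- 0L
    sim$treat_mod[enter] <- assign_moud(length(enter), tr$modality_probs)
    sim$rx_active[enter] <- FALSE
    sim$is_diverted_user[enter] <- FALSE
    sim$bupe_today[enter] <- FALSE
    idx_remove(sim, "idx_active", enter)
    idx_add(sim, "idx_treat", enter)
    nb <- enter[sim$treat_mod[enter] == 2L]
    sim$ever_bupe[nb] <- TRUE
    sim$new_bupe <- c(sim$new_bupe, nb)
  }
  # cessation among previously treated agents
  intr <- setdiff(sim$idx_treat, enter)
  if (length(intr)) {
    sim$treat_days[intr] <- sim$treat_days[intr] + 1L
    h <- numeric(length(intr))
    for (m in 1:3) {
      mi <- sim$treat_mod[intr] == m
      if (any(mi)) {
        cz <- sim$cess[[m]]
        piece <- pmin(findInterval(sim$treat_days[intr][mi], cz$breaks,
                                   left.open = TRUE) + 1L, length(cz$p))
        h[mi] <- cz$p[piece]
      }
    }
    ex <- intr[stats::runif(length(intr)) < h]
    if (length(ex)) {
      decay <- sim$params$internal$treatment_tolerance_decay
      if (decay > 0) {
        sim$tolerance[ex] <- sim$tolerance[ex] *
          (1 - decay)^pmax(sim$treat_days[ex], 0)
      }
      sim$use[ex] <- sim$prev_use[ex]
      sim$desire[ex] <- pmin(sim$params$internal$desire_cap,
                             pmax(agent_need(sim, ex),
                                  desire_beta(sim$use[ex], sim$params$internal) *
                                    sim$tolerance[ex]))
      sim$treat_mod[ex] <- 0L
      sim$treat_days[ex] <- 0L
      sim$is_diverter[ex] <- FALSE
      sim$census <- sim$census - length(ex)
      idx_remove(sim, "idx_treat", ex)
      idx_add(sim, "idx_active", ex)
      sim$new_oud <- c(sim$new_oud, ex)
    }
  }
  invisible()
}

step_diversion <- function(sim) {
  dv <- sim$params$diversion
  use_stream(sim, 2L)
  # role draws for today's eligibility transitions
  sim_assign_roles(sim, sim$new_bupe, sim$new_oud)
  joiners <- unique(c(sim$new_bupe,
                      sim$new_oud[sim$is_diverted_user[sim$new_oud]]))
  joiners <- joiners[!sim$net$active[joiners]]
  sim_net_join(sim, joiners)
  sim$new_bupe <- integer(0); sim$new_oud <- integer(0)

  # weekly diverted supply (per-agent week offset avoids synchronization)
  div <- sim$idx_treat[sim$is_diverter[sim$idx_treat] &
                         sim$treat_mod[sim$idx_treat] == 2L]
  div <- div[(sim$day %% 7L) == (div %% 7L)]
  for (i in div) {
    d <- dv$doses_per_week[1] +
      sample.int(dv$doses_per_week[2] - dv$doses_per_week[1] + 1L, 1) - 1L
    sim$div_total <- sim$div_total + d
    n_leak <- if (dv$naive_leak_fraction > 0) {
      stats::rbinom(1, d, dv$naive_leak_fraction)
    } else 0L
    if (n_leak > 0) sim_leak_naive(sim, n_leak)
    d <- d - n_leak
    if (d == 0) next
    peers <- sim$net$nbrs[[i]]
    peers <- peers[sim$alive[peers] & sim$is_diverted_user[peers] &
                     is_oud_state(sim$use[peers])]
    n_t <- dv$share_targets[1] +
      sample.int(dv$share_targets[2] - dv$share_targets[1] + 1L, 1) - 1L
    targets <- if (length(peers)) {
      peers[sample.int(length(peers), min(n_t, length(peers)))]
    } else integer(0)
    for (dose in seq_len(d)) {
      if (length(targets) && stats::runif(1) >= dv$dealer_fraction) {
        j <- targets[sample.int(length(targets), 1)]
        sim$stock[j] <- sim$stock[j] + 1L
        sim$div_to_peers <- sim$div_to_peers + 1L
      } else {
        sim$dealer_pool <- sim$dealer_pool + 1L
        sim$div_to_dealer <- sim$div_to_dealer + 1L
      }
    }
  }

  # daily replacement decision among diverted users
  users <- sim$idx_active[sim$is_diverted_user[sim$idx_active]]
  if (length(users)) {
    want <- users[stats::runif(length(users)) < dv$p_daily_use_diverted]
    for (i in want) {
      if (sim$stock[i] < 1L) sim_acquire(sim, i)
      if (sim$stock[i] >= 1L) {
        sim$stock[i] <- sim$stock[i] - 1L
        sim$div_consumed <- sim$div_consumed + 1L
        sim$bupe_today[i] <- TRUE
        if (!sim$ever_div_use[i]) {
          sim$ever_div_use[i] <- TRUE
          sim$n_div_users_ever <- sim$n_div_users_ever + 1L
        }
        sim$ever_bupe[i] <- TRUE
      }
    }
  }

  # weekly network maintenance and assortative growth
  mem <- which(sim$net$active)
  mem <- mem[sim$alive[mem]]
  mem <- mem[(sim$day %% 7L) == (mem %% 7L)]
  if (length(mem)) {
    nw <- sim$params$network
    bupe_pool <- sim_bupe_pool(sim)
    for (i in mem) {
      deg <- net_degree(sim$net, i, sim$alive)
      if (deg < nw$maintain_min_degree) {
        net_join(sim$net, i, nw$maintain_min_degree, bupe_pool, sim$alive,
                 nw$assortativity, nw$degree_cap)
      } else if (deg < nw$degree_cap && stats::runif(1) < nw$weekly_tie_prob) {
        p <- net_pick_partner(sim$net, i, bupe_pool, sim$alive,
                              nw$assortativity, nw$degree_cap)
        if (!is.na(p)) net_add_tie(sim$net, i, p)
      }
    }
  }
  use_stream(sim, 1L)
  invisible()
}

sim_acquire <- function(sim, i) {
  dv <- sim$params$diversion
  from_dealer <- function() {
    if (sim$dealer_pool >= 1L) {
      k <- min(sample.int(dv$dealer_max_doses, 1), sim$dealer_pool)
      sim$dealer_pool <- sim$dealer_pool - k
      sim$stock[i] <- sim$stock[i] + k
      TRUE
    } else FALSE
  }
  if (stats::runif(1) < dv$p_source_friend) {
    peers <- sim$net$nbrs[[i]]
    peers <- peers[sim$alive[peers] & sim$stock[peers] > 0L]
    if (length(peers)) {
      j <- peers[sample.int(length(peers), 1)]
      sim$stock[j] <- sim$stock[j] - dv$friend_doses
      sim$stock[i] <- sim$stock[i] + dv$friend_doses
    } else {
      from_dealer()  # fall back only if the dealer pool is stocked
    }
  } else {
    from_dealer()
  }
  invisible()
}

sim_leak_naive <- function(sim, k) {
  dv <- sim$params$diversion
  holders <- integer(0)
  tries <- 0L
  while (length(holders) < k && tries < 200L) {
    cand <- sample.int(sim$n, 1L)
    if (sim$alive[cand] && sim$use[cand] == U_NAIVE &&
        !sim$ever_exposed[cand] && !(cand %in% holders)) {
      holders <- c(holders, cand)
    }
    tries <- tries + 1L
  }
  if (!length(holders)) return(invisible())
  sim$div_to_naive <- sim$div_to_naive + length(holders)
  consumed <- stats::runif(length(holders)) < dv$p_naive_misuse
  sim$naive_discarded <- sim$naive_discarded + sum(!consumed)
  ci <- holders[consumed]
  if (length(ci)) {
    sim$naive_consumed <- sim$naive_consumed + length(ci)
    sim$n_div_users_ever <- sim$n_div_users_ever + sum(!sim$ever_div_use[ci])
    sim$ever_div_use[ci] <- TRUE
    sim$ever_bupe[ci] <- TRUE
    fatal <- ci[stats::runif(length(ci)) < dv$p_naive_fatal_od]
    for (a in fatal) {
      sim$od_count[a] <- sim$od_count[a] + 1L
      sim_record_event(sim, a, "naive_bupe", FALSE, FALSE, TRUE)
      sim_kill(sim, a)
    }
    sim$od_today <- sim$od_today + length(fatal)
    sim$fatal_today <- sim$fatal_today + length(fatal)
  }
  invisible()
}

step_consumption <- function(sim) {
  int <- sim$params$internal; pr <- sim$params$prescribing
  idx <- sim$idx_active
  if (!length(idx)) return(invisible())
  use_i <- sim$use[idx]
  rx_sup <- ifelse(sim$rx_active[idx], sim$rx_dose[idx], 0)
  cons <- numeric(length(idx))
  type <- integer(length(idx))
  i <- use_i == U_RX
  cons[i] <- rx_sup[i]
  type[i] <- ifelse(cons[i] > 0, 1L, 0L)
  i <- use_i == U_MISUSE | use_i == U_DEP
  cons[i] <- pmin(sim$desire[idx][i], rx_sup[i] + pr$illicit_po_max_mme)
  type[i] <- ifelse(cons[i] > 0, 1L, 0L)
  i <- use_i == U_HEROIN
  cons[i] <- sim$desire[idx][i]
  type[i] <- 2L
  # a diverted-buprenorphine day replaces all other opioid use
  bd <- sim$bupe_today[idx]
  cons[bd] <- 0
  type[bd] <- 3L
  # internal-state update (tolerance chases the consumed agonist dose,
  # building quickly with use and waning slowly in abstinence)
  a <- ifelse(cons >= sim$tolerance[idx], int$alpha, int$alpha_decay)
  tol <- (1 - a) * sim$tolerance[idx] + a * cons
  sat <- pmin(1, cons / pmax(sim$desire[idx], int$epsilon))
  need <- agent_need(sim, idx)
  des <- pmin(int$desire_cap,
              pmax(need, desire_beta(use_i, int) * tol) +
                int$recreational_increment)
  des[tol == 0 & cons == 0 & need == 0] <- 0
  sim$tolerance[idx] <- tol
  sim$satiation[idx] <- sat
  sim$desire[idx] <- des
  sim$ever_exposed[idx] <- sim$ever_exposed[idx] | cons > 0
  sim$cons[idx] <- cons
  sim$cons_type[idx] <- type
  # lapsed patients whose tolerance has decayed revert to opioid-naive
  rev <- idx[use_i == U_RX & !sim$rx_active[idx] & tol < int$naive_revert_tol]
  if (length(rev)) {
    sim$use[rev] <- U_NAIVE
    sim$tolerance[rev] <- 0
    sim$desire[rev] <- 0
    sim$satiation[rev] <- 0
    sim$cons[rev] <- 0
    sim$cons_type[rev] <- 0L
    idx_remove(sim, "idx_active", rev)
  }
  invisible()
}

step_overdose <- function(sim) {
  ov <- sim$params$overdose
  risk <- c(sim$idx_active, sim$idx_treat)
  if (!length(risk)) return(invisible())
  p <- numeric(length(risk))
  ct <- sim$cons_type[risk]
  i <- ct == 1L | ct == 2L
  if (any(i)) {
    band <- findInterval(sim$cons[risk][i], ov$mme_band_edges) + 1L
    p[i] <- ov$base_daily_hazard * ov$band_hazard_ratios[band]
    her <- ct[i] == 2L
    p[i][her] <- p[i][her] * ov$heroin_od_multiplier
    zero <- sim$cons[risk][i] == 0
    p[i][zero] <- 0
  }
  p[ct == 3L] <- sim$p_bupe_day
  trt <- sim$use[risk] == U_TREAT
  if (any(trt)) {
    m <- sim$treat_mod[risk][trt]
    pt <- sim$p_trt_od[m]
    recent <- sim$treat_days[risk][trt] < sim$params$treatment$naltrexone_recent_days
    pt[m == 3L & !recent] <- 0
    p[trt] <- pt
  }
  ev <- risk[stats::runif(length(risk)) < p]
  if (length(ev)) {
    use_stream(sim, 3L)
    heroin <- sim$cons_type[ev] == 2L
    k <- length(ev)
    nal <- stats::runif(k) < ov$p_naloxone_available
    revd <- nal & stats::runif(k) < ov$p_reversal_given_naloxone
    pf <- pmin(1, ov$p_fatal_given_od *
                 ifelse(heroin, ov$heroin_fatal_multiplier, 1))
    if (identical(ov$fatal_model, "marginal")) {
      # 0.17 is the marginal fatality: rescale so reversal doesn't dilute it
      pf <- pmin(1, pf / (1 - ov$p_naloxone_available *
                            ov$p_reversal_given_naloxone))
    }
    fatal <- !revd & stats::runif(k) < pf
    sim$od_count[ev] <- sim$od_count[ev] + 1L
    types <- c("none", "po", "heroin_fentanyl", "diverted_bupe")[sim$cons_type[ev] + 1L]
    types[sim$use[ev] == U_TREAT] <- "moud"
    types[types == "po"] <- ifelse(sim$use[ev][types == "po"] == U_RX,
                                   "prescribed_po", "illicit_po")
    if (sim$record_events) {
      sim$ev_day <- c(sim$ev_day, rep(sim$day, k))
      sim$ev_agent <- c(sim$ev_agent, ev)
      sim$ev_type <- c(sim$ev_type, types)
      sim$ev_nal <- c(sim$ev_nal, nal)
      sim$ev_rev <- c(sim$ev_rev, revd)
      sim$ev_fatal <- c(sim$ev_fatal, fatal)
    }
    for (a in ev[fatal]) sim_kill(sim, a)
    sim$od_today <- sim$od_today + k
    sim$fatal_today <- sim$fatal_today + sum(fatal)
    use_stream(sim, 1L)
  }
  sim$cons[risk] <- 0
  sim$cons_type[risk] <- 0L
  invisible()
}

sim_record_event <- function(sim, agent, type, nal, revd, fatal) {
  if (!sim$record_events) return(invisible())
  sim$ev_day <- c(sim$ev_day, sim$day)
  sim$ev_agent <- c(sim$ev_agent, agent)
  sim$ev_type <- c(sim$ev_type, type)
  sim$ev_nal <- c(sim$ev_nal, nal)
  sim$ev_rev <- c(sim$ev_rev, revd)
  sim$ev_fatal <- c(sim$ev_fatal, fatal)
  invisible()
}

sim_kill <- function(sim, a) {
  if (sim$use[a] == U_TREAT) {
    sim$census <- sim$census - 1L
    idx_remove(sim, "idx_treat", a)
  }
  if (sim$use[a] >= U_RX && sim$use[a] <= U_HEROIN) {
    idx_remove(sim, "idx_active", a)
  }
  if (sim$pain[a] == 0L) {
    sim$n_painfree <- sim$n_painfree - 1L
  } else if (sim$pain[a] == 1L) {
    idx_remove(sim, "idx_acute", a)
  }
  sim$alive[a] <- FALSE
  sim$use[a] <- U_DEAD
  sim$rx_active[a] <- FALSE
  sim$is_diverter[a] <- FALSE
  sim$is_diverted_user[a] <- FALSE
  sim$bupe_today[a] <- FALSE
  sim$pain[a] <- 0L
  invisible()
}

sim_day <- function(sim) {
  sim$day <- sim$day + 1L
  sim$od_today <- 0L; sim$fatal_today <- 0L
  sim$bupe_today[] <- FALSE
  step_pain(sim)
  step_prescribing(sim)
  step_transitions(sim)
  step_treatment(sim)
  step_diversion(sim)
  step_consumption(sim)
  step_overdose(sim)
  invisible()
}
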