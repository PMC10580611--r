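# Peer network: adjacency list over agent ids.  Only agents who have ever
# held a buprenorphine prescription, ever used diverted buprenorphine, or are
# flagged diverted users participate actively; ties to bystanders are allowed
# (uniform partner draws) so the network stays sparse at population scale.

new_network <- function(n) {
  net <- new.env(parent = emptyenv())
  net$n <- n
  net$nbrs <- vector("list", n)
  net$active <- logical(n)
  net
}

net_degree <- function(net, idx, alive = NULL) {
  vapply(idx, function(i) {
    nb <- net$nbrs[[i]]
    if (is.null(nb)) return(0L)
    if (is.null(alive)) length(nb) else sum(alive[nb])
  }, integer(1))
}

net_add_tie <- function(net, a, b) {
  if (a == b) return(invisible(FALSE))
  if (b %in% net$nbrs[[a]]) return(invisible(FALSE))
  net$nbrs[[a]] <- c(net$nbrs[[a]], b)
  net$nbrs[[b]] <- c(net$nbrs[[b]], a)
  invisible(TRUE)
}

# Draw one partner for agent i: with probability `assortativity` from the
# ever-buprenorphine pool, otherwise uniformly from the living population.
# Active-network members already at the degree cap are not eligible partners.
net_pick_partner <- function(net, i, bupe_pool, alive, assortativity,
                             degree_cap = Inf) {
  assort <- stats::runif(1) < assortativity && length(bupe_pool) > 1
  if (assort) {
    pool <- setdiff(bupe_pool, c(i, net$nbrs[[i]]))
    if (is.finite(degree_cap) && length(pool)) {
      full <- net$active[pool] & net_degree(net, pool) >= degree_cap
      pool <- pool[!full]
    }
    if (length(pool)) return(pool[sample.int(length(pool), 1)])
    # exhausted ever-buprenorphine pool: fall through to a uniform partner
    # (under strict homophily, assortativity 1, no fallback is allowed)
    if (assortativity >= 1) return(NA_integer_)
  }
  # uniform branch: rejection-sample the (large) living population
  for (t in 1:10) {
    cand <- sample.int(net$n, 1L)
    if (alive[cand] && cand != i && !(cand %in% net$nbrs[[i]]) &&
        !(is.finite(degree_cap) && net$active[cand] &&
            length(net$nbrs[[cand]]) >= degree_cap)) {
      return(cand)
    }
  }
  NA_integer_
}

# Join the active network with init_degree ties (or top back up to the
# maintenance minimum after deaths).
net_join <- function(net, i, target, bupe_pool, alive, assortativity,
                     degree_cap = Inf) {
  tries <- 0L
  while (net_degree(net, i, alive) < target && tries < 20L) {
    p <- net_pick_partner(net, i, bupe_pool, alive, assortativity, degree_cap)
    if (is.na(p)) break
    net_add_tie(net, i, p)
    tries <- tries + 1L
  }
  net$active[i] <- TRUE
  invisible(net)
}

#' Build the assortatively mixed peer network
#'
#' Forms initial ties for every network-active agent (ever prescribed
#' buprenorphine, ever used diverted buprenorphine, or flagged as a diverted
#' user).  When an active agent forms a tie, with probability equal to the
#' assortativity parameter (45%) the partner is drawn from the
#' ever-buprenorphine pool, otherwise uniformly from the living population.
#' During a simulation the engine grows the network incrementally: each
#' active agent adds a tie with `weekly_tie_prob` per week up to
#' `degree_cap`, and tops back up to `maintain_min_degree` surviving peers.
#'
#' @param pop Population tibble from [init_population()].
#' @param params An [abm_params()] object.
#' @param seed Optional seed for reproducibility.
#' @return An edge list tibble (`from`, `to`) with one row per undirected
#'   tie, with attribute `"degree"` giving each agent's degree.
#' @export
build_network <- function(pop, params = abm_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nw <- params$network
  if (nw$assortativity < 0 || nw$assortativity > 1) {
    stop("assortativity must lie in [0, 1]", call. = FALSE)
  }
  net <- new_network(nrow(pop))
  members <- which(pop$ever_bupe | pop$ever_used_diverted_bupe |
                     pop$is_diverted_user)
  bupe_pool <- which(pop$ever_bupe | pop$ever_used_diverted_bupe)
  for (i in members) {
    net_join(net, i, nw$init_degree, bupe_pool, pop$alive, nw$assortativity,
             nw$degree_cap)
  }
  net_as_edges(net)
}

net_as_edges <- function(net) {
  from <- rep.int(seq_len(net$n), lengths(net$nbrs))
  to <- unlist(net$nbrs, use.names = FALSE)
  if (is.null(to)) to <- integer(0)
  keep <- from < to
  out <- tibble::tibble(from = from[keep], to = to[keep])
  attr(out, "degree") <- lengths(net$nbrs)
  out
}

#' Assign diversion roles for a scenario
#'
#' Each agent currently in buprenorphine treatment becomes a diverter with
#' probability `p_divert_given_rx`; each agent misusing prescription opioids
#' or using heroin/fentanyl becomes a diverted-buprenorphine user with
#' probability `p_use_diverted_given_oud`.  Under the controlled-prescription
#' -only scenario both probabilities are exactly 0 and no roles are ever
#' assigned.  Roles persist for the treatment episode (diverters) and are
#' re-drawn on each eligibility transition (users).
#'
#' @param pop Population tibble.
#' @param params An [abm_params()] object (after [apply_scenario()]).
#' @return The tibble with `is_diverter` / `is_diverted_user` updated.
#' @export
assign_diversion_roles <- function(pop, params = abm_params()) {
  dv <- params$diversion
  n <- nrow(pop)
  elig_div <- pop$has_bupe_rx & pop$alive
  elig_use <- pop$use_state %in% c("misuse_po", "dependent_po",
                                   "heroin_fentanyl") & pop$alive
  pop$is_diverter <- elig_div & stats::runif(n) < dv$p_divert_given_rx
  pop$is_diverted_user <- elig_use & stats::runif(n) < dv$p_use_diverted_given_oud
  pop
}

#' Outcomes of diverted buprenorphine reaching opioid-naive agents
#'
#' Under sensitivity 4, 3% of diverted doses are rerouted to randomly chosen
#' opioid-naive agents.  A naive holder consumes the dose with probability
#' 1%; upon consumption the outcome is a fatal overdose with probability
#' 0.3% (the Poison-Control-derived estimate), otherwise a non-fatal use
#' that marks the agent as having used diverted buprenorphine.
#'
#' @param n Number of naive dose-holders.
#' @param params An [abm_params()] object with `naive_leak_fraction > 0`
#'   (i.e. sensitivity 4 active).
#' @return Character vector of outcomes: `"none"`, `"nonfatal_use"`,
#'   `"fatal_overdose"`.
#' @export
naive_exposure <- function(n, params = abm_params()) {
  dv <- params$diversion
  if (dv$naive_leak_fraction <= 0) {
    stop("naive exposure applies only when the opioid-naive leakage pathway ",
         "(sensitivity 4) is active", call. = FALSE)
  }
  consumed <- stats::runif(n) < dv$p_naive_misuse
  fatal <- consumed & stats::runif(n) < dv$p_naive_fatal_od
  out <- rep("none", n)
  out[consumed] <- "nonfatal_use"
  out[fatal] <- "fatal_overdose"
  out
}
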