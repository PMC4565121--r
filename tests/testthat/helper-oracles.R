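# Independent oracles for the stochastic graph dynamics:
#  - exhaustive continuous-time Markov chain over all reachable graph states
#    of a small (<= 4 edge) system, solved exactly for its stationary law;
#  - long-time ODE integration of the mass-action system (deSolve).
# Both are kept independent of the simulation engine they check.

# all partitions of the endpoint set {0, ..., 2n-1} into blocks of size <= 3
# with no block holding both endpoints of one edge (single-edge self-loop)
enumerate_graph_states <- function(n_edges) {
  elems <- 0:(2 * n_edges - 1)
  states <- list()
  recurse <- function(remaining, blocks) {
    if (length(remaining) == 0) {
      key <- state_key_blocks(blocks)
      states[[key]] <<- blocks
      return(invisible())
    }
    x <- remaining[1]
    rest <- remaining[-1]
    # open a new block
    recurse(rest, c(blocks, list(x)))
    # join an existing block
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      if (length(blk) >= 3) next
      if (any(bitwXor(blk, 1L) == x)) next  # sibling endpoint -> self-loop
      nb <- blocks
      nb[[b]] <- sort(c(blk, x))
      recurse(rest, nb)
    }
  }
  recurse(elems, list())
  states
}

state_key_blocks <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = "."),
                    character(1))), collapse = "|")
}

state_key_nodes <- function(node_of_endpoint) {
  blocks <- split(seq_along(node_of_endpoint) - 1L, node_of_endpoint)
  state_key_blocks(blocks)
}

# exact generator over the enumerated states; rates follow the reaction
# channels of the model (kp, lp are the effective pairwise rates)
ctmc_generator <- function(states, kp, km, lp, lm) {
  keys <- names(states)
  m <- length(keys)
  idx <- setNames(seq_len(m), keys)
  G <- matrix(0, m, m)
  for (s in seq_len(m)) {
    blocks <- states[[s]]
    degs <- lengths(blocks)
    add <- function(nblocks, rate) {
      j <- idx[[state_key_blocks(nblocks)]]
      G[s, j] <<- G[s, j] + rate
    }
    tips <- which(degs == 1)
    bulks <- which(degs == 2)
    branches <- which(degs == 3)
    # tip-to-tip fusion
    if (length(tips) >= 2) {
      for (i in seq_along(tips)) for (j in seq_along(tips)) {
        if (j <= i) next
        a <- blocks[[tips[i]]][1]; b <- blocks[[tips[j]]][1]
        if (bitwXor(a, 1L) == b) next  # isolated edge closing on itself
        nb <- blocks[-c(tips[i], tips[j])]
        nb <- c(nb, list(sort(c(a, b))))
        add(nb, kp)
      }
    }
    # bulk fission
    for (b in bulks) {
      nb <- blocks[-b]
      nb <- c(nb, list(blocks[[b]][1]), list(blocks[[b]][2]))
      add(nb, km)
    }
    # tip-to-side fusion
    for (t in tips) for (b in bulks) {
      a <- blocks[[t]][1]
      if (any(bitwXor(blocks[[b]], 1L) == a)) next  # own edge ends in b
      nb <- blocks[-c(t, b)]
      nb <- c(nb, list(sort(c(blocks[[b]], a))))
      add(nb, lp)
    }
    # branch fission: detach one of the three endpoints uniformly
    for (b in branches) {
      for (k in 1:3) {
        rest <- blocks[[b]][-k]
        nb <- blocks[-b]
        nb <- c(nb, list(sort(rest)), list(blocks[[b]][k]))
        add(nb, lm / 3)
      }
    }
  }
  diag(G) <- -rowSums(G)
  list(G = G, keys = keys)
}

ctmc_stationary <- function(gen) {
  m <- length(gen$keys)
  A <- rbind(t(gen$G), rep(1, m))
  b <- c(rep(0, m), 1)
  pi <- qr.solve(A, b)
  setNames(pmax(pi, 0) / sum(pmax(pi, 0)), gen$keys)
}

# deterministic mass-action equilibrium by long-time integration
ode_equilibrium <- function(Q1, alpha1, alpha2, t_end = 1e5) {
  rhs <- function(t, u, parms) {
    list(mitoreticulum:::mass_action_rhs(u, alpha1, alpha2))
  }
  out <- deSolve::lsoda(y = c(2 * Q1, 0, 0), times = c(0, t_end), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[2, 2:4])
}

# stationary samples of the engine taken at fixed time spacing (after a
# time-based burn-in), for comparison with the exact CTMC law
sample_engine_states <- function(n_edges, kp, km, lp, lm, n_samples, dt,
                                 burn_t, seed) {
  set.seed(seed)
  state <- init_fragmented(n_edges)$node_of_endpoint
  res <- mitoreticulum:::gillespie_run_cpp(n_edges, state, kp, km, lp, lm,
                                           0, 1e9, 0L, burn_t)
  state <- res$node_of_endpoint
  keys <- character(n_samples)
  for (i in seq_len(n_samples)) {
    res <- mitoreticulum:::gillespie_run_cpp(n_edges, state, kp, km, lp, lm,
                                             0, 1e9, 0L, dt)
    state <- res$node_of_endpoint
    keys[i] <- state_key_nodes(state)
  }
  keys
}
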