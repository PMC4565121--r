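# Agent-based (exact stochastic) simulation of the fission/fusion graph.
# Edges are fixed-length mitochondrial units; nodes (degree 1-3) are fused
# groups of edge endpoints. The compiled engine conserves the edge count
# exactly and never creates a node of degree > 3 or a single-edge self-loop.

#' Create a mitochondrial graph
#'
#' `init_fragmented()` returns the maximally fragmented state (`n` isolated
#' edges, `u1 = 2n`); `mito_graph()` additionally offers a fully fused
#' linear chain, used to verify that stationary summaries do not depend on
#' the initial condition.
#'
#' @param n_edges number of edges (fixed-length mitochondrial units).
#' @param topology `"fragmented"` (isolated edges) or `"chain"` (one linear
#'   segment).
#' @param edge_length physical length of one edge (um).
#' @return an object of class `mito_graph`: list with `n_edges`,
#'   `node_of_endpoint` (0-based node index of endpoints `2e`, `2e+1` of
#'   edge `e`), and `edge_length`.
#' @examples
#' g <- init_fragmented(5)
#' node_degrees(g)  # ten free ends
#' @export
mito_graph <- function(n_edges, topology = c("fragmented", "chain"),
                       edge_length = 0.2) {
  topology <- match.arg(topology)
  n_edges <- as.integer(n_edges)
  if (n_edges < 1) stop("n_edges must be >= 1", call. = FALSE)
  node <- switch(topology,
    fragmented = seq_len(2L * n_edges) - 1L,
    chain = {
      # endpoint 2e fused with endpoint 2e-1 of the previous edge
      ep <- integer(2L * n_edges)
      ep[seq(1L, 2L * n_edges, by = 2L)] <- 0:(n_edges - 1L)   # left ends
      ep[seq(2L, 2L * n_edges, by = 2L)] <- 1:n_edges          # right ends
      ep
    })
  structure(list(n_edges = n_edges, node_of_endpoint = node,
                 edge_length = edge_length),
            class = "mito_graph")
}

#' @rdname mito_graph
#' @export
init_fragmented <- function(n_edges, edge_length = 0.2) {
  mito_graph(n_edges, "fragmented", edge_length)
}

#' @export
print.mito_graph <- function(x, ...) {
  d <- node_degrees(x)
  cat(sprintf("mito_graph: %d edges (%g um each); nodes u1 = %d, u2 = %d, u3 = %d\n",
              x$n_edges, x$edge_length, d[["1"]], d[["2"]], d[["3"]]))
  invisible(x)
}

#' Node degree counts of a graph
#'
#' @param g a `mito_graph`.
#' @return named vector with counts of degree-1, -2 and -3 nodes.
#' @export
node_degrees <- function(g) {
  tab <- tabulate(tabulate(g$node_of_endpoint + 1L,
                           nbins = max(g$node_of_endpoint) + 1L), nbins = 3L)
  setNames(tab, c("1", "2", "3"))
}

#' Reaction-channel propensities
#'
#' Enumerates the four channels from the current degree counts, with the
#' forbidden single-edge self-loop pairs excluded exactly: tip-to-tip
#' fusion acts on `u1 (u1 - 1) / 2 - n_iso` pairs (isolated edges cannot
#' close on themselves) and tip-to-side fusion on `u1 u2 - n_mix` pairs
#' (an edge with endpoint degrees 1 and 2 cannot bend onto its own bulk
#' node). Bimolecular rates carry the volume scaling `1 / omega`.
#'
#' @param g a `mito_graph`.
#' @param alpha1,alpha2 fusion-to-fission rate ratios of the shell.
#' @param kminus,lminus absolute fission rates (1/time); the stationary
#'   structure depends only on the ratios.
#' @param omega volume scaling of the bimolecular channels (see
#'   [radial_ensemble()]).
#' @return a `data.frame` with `kind` and `propensity`.
#' @export
propensities <- function(g, alpha1, alpha2, kminus = 1, lminus = 1,
                         omega = 1) {
  deg_of_node <- tabulate(g$node_of_endpoint + 1L,
                          nbins = max(g$node_of_endpoint) + 1L)
  u <- tabulate(deg_of_node, nbins = 3L)
  ep_deg <- deg_of_node[g$node_of_endpoint + 1L]
  d1 <- ep_deg[seq(1L, length(ep_deg), by = 2L)]
  d2 <- ep_deg[seq(2L, length(ep_deg), by = 2L)]
  n_iso <- sum(d1 == 1L & d2 == 1L)
  n_mix <- sum((d1 == 1L & d2 == 2L) | (d1 == 2L & d2 == 1L))
  data.frame(
    kind = c("tip_tip_fuse", "deg2_fission", "tip_side_fuse", "deg3_fission"),
    propensity = c(
      alpha1 * kminus / omega * max(0, u[1] * (u[1] - 1) / 2 - n_iso),
      kminus * u[2],
      alpha2 * lminus / omega * max(0, u[1] * u[2] - n_mix),
      lminus * u[3]))
}

#' Run the stochastic fission/fusion dynamics
#'
#' Standard two-random-number event selection (exponential waiting time,
#' propensity-proportional channel choice, uniform choice of concrete nodes
#' within the channel). The run burns in for `burn_factor * n_edges` events,
#' then samples `sample_factor * n_edges` events during which time-averaged
#' node counts are accumulated. When `check_stationarity` is on, the u1/u2
#' snapshot series of the sampling window is split in two and the burn-in is
#' doubled (up to `max_extensions` times) while the halves differ at the 95%
#' level, implementing "record after full equilibration" without fixing an
#' arbitrary horizon.
#'
#' @param g a `mito_graph` (its state is the initial condition).
#' @inheritParams propensities
#' @param burn_factor,sample_factor events per edge for burn-in / sampling.
#' @param seed optional integer seed.
#' @param check_stationarity test for a residual trend and extend burn-in.
#' @param max_extensions maximum number of burn-in doublings.
#' @param snapshot_every events between snapshots (default: 50 per window).
#' @return an object of class `mito_sim`: list with the final `graph`,
#'   time-averaged counts `u_mean`, final counts `u_final`, `max_degree`,
#'   `absorbed`, `equilibrated`, elapsed `time`, `events` and the snapshot
#'   matrix.
#' @export
simulate_graph <- function(g, alpha1, alpha2, kminus = 1, lminus = 1,
                           omega = 1, burn_factor = 20, sample_factor = 5,
                           seed = NULL, check_stationarity = TRUE,
                           max_extensions = 2L, snapshot_every = NULL) {
  stopifnot(inherits(g, "mito_graph"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- g$n_edges
  kplus <- alpha1 * kminus / omega
  lplus <- alpha2 * lminus / omega
  burn <- max(100, ceiling(burn_factor * n))
  samp <- max(100, ceiling(sample_factor * n))
  if (is.null(snapshot_every)) snapshot_every <- max(1L, samp %/% 50L)
  state <- g$node_of_endpoint
  total_time <- 0
  total_events <- 0
  maxdeg <- 0
  equilibrated <- !check_stationarity
  res <- NULL
  for (round in 0:max_extensions) {
    res <- gillespie_run_cpp(n, state, kplus, kminus, lplus, lminus,
                             burn, samp, as.integer(snapshot_every))
    state <- res$node_of_endpoint
    total_time <- total_time + res$time
    total_events <- total_events + res$events
    maxdeg <- max(maxdeg, res$max_degree)
    if (res$absorbed || !check_stationarity) {
      equilibrated <- TRUE
      break
    }
    if (is_stationary(res$snapshots)) {
      equilibrated <- TRUE
      break
    }
    # residual trend: treat the whole previous stretch as burn-in and retry
    burn <- 0
  }
  out <- list(
    graph = structure(list(n_edges = n, node_of_endpoint = res$node_of_endpoint,
                           edge_length = g$edge_length), class = "mito_graph"),
    u_mean = setNames(res$u_mean, c("u1", "u2", "u3")),
    u_final = setNames(res$u, c("u1", "u2", "u3")),
    max_degree = maxdeg,
    absorbed = res$absorbed,
    equilibrated = equilibrated,
    time = total_time,
    events = total_events,
    snapshots = res$snapshots)
  class(out) <- "mito_sim"
  out
}

# two-sample comparison of the halves of the snapshot series; TRUE when no
# significant level shift remains in u1 or u2
is_stationary <- function(snaps, level = 0.05) {
  m <- nrow(snaps)
  if (is.null(m) || m < 10) return(TRUE)
  half <- seq_len(m %/% 2)
  for (col in 1:2) {
    a <- snaps[half, col]
    b <- snaps[-half, col]
    if (sd(a) < 1e-12 && sd(b) < 1e-12) next
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    if (is.finite(p) && p < level) return(FALSE)
  }
  TRUE
}

#' @export
print.mito_sim <- function(x, ...) {
  cat(sprintf("mito_sim: %d edges, %g events, max degree %d%s\n",
              x$graph$n_edges, x$events, x$max_degree,
              if (x$absorbed) " (absorbed)" else ""))
  cat(sprintf("  time-averaged nodes: u1 = %.1f, u2 = %.1f, u3 = %.1f\n",
              x$u_mean[1], x$u_mean[2], x$u_mean[3]))
  invisible(x)
}

#' Connected components of a mitochondrial graph
#'
#' Component sizes are measured in edges; their sum equals the (conserved)
#' edge count. The default traversal runs in compiled code; `method =
#' "igraph"` rebuilds the graph with the igraph package and serves as an
#' independent cross-check.
#'
#' @param g a `mito_graph`.
#' @param method `"unionfind"` (compiled) or `"igraph"`.
#' @return integer vector of component sizes, decreasing.
#' @export
cluster_sizes <- function(g, method = c("unionfind", "igraph")) {
  method <- match.arg(method)
  if (method == "unionfind")
    return(component_sizes_cpp(g$node_of_endpoint))
  el <- cbind(g$node_of_endpoint[seq(1L, 2L * g$n_edges, by = 2L)],
              g$node_of_endpoint[seq(2L, 2L * g$n_edges, by = 2L)]) + 1L
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(ig)$membership
  sizes <- tabulate(memb[el[, 1]])
  sort(sizes[sizes > 0], decreasing = TRUE)
}

#' Fraction of the largest cluster
#'
#' @param sizes component sizes (edges) of one graph, or a list of such
#'   vectors for an ensemble.
#' @param n_edges total edge count.
#' @return the (mean) largest-component fraction.
#' @export
largest_cluster_fraction <- function(sizes, n_edges) {
  if (is.list(sizes))
    return(mean(vapply(sizes, function(s) max(s) / n_edges, numeric(1))))
  max(sizes) / n_edges
}

#' Aggregate an ensemble of component-size vectors
#'
#' @param size_list list of per-run component-size vectors.
#' @return a `data.frame` with `size`, `count` and `probability` (fraction
#'   of clusters), with the run count and mean largest-cluster fraction as
#'   attributes.
#' @export
cluster_size_distribution <- function(size_list) {
  all_sizes <- unlist(size_list)
  tab <- table(all_sizes)
  out <- data.frame(size = as.integer(names(tab)),
                    count = as.integer(tab))
  out$probability <- out$count / sum(out$count)
  attr(out, "runs") <- length(size_list)
  attr(out, "mean_largest") <- mean(vapply(size_list, max, numeric(1)))
  out
}

#' Apportion mitochondrial edges over radial shells
#'
#' Shell quotas are proportional to `Q1(r) * dr`; the integer allocation
#' uses largest-remainder rounding so that the summed reticulum length is
#' exactly `round(M / edge_length)` edges — the simulated graph carries the
#' configured mitochondrial mass exactly.
#'
#' @param Q1 edge-density values per shell (from [density_profiles()]).
#' @param dr shell width (um).
#' @param edge_length edge length (um).
#' @param M total mitochondrial length (um).
#' @return integer vector of edge counts per shell.
#' @export
allocate_shell_edges <- function(Q1, dr, edge_length, M) {
  n_total <- as.integer(round(M / edge_length))
  w <- pmax(0, Q1) * dr
  if (sum(w) <= 0) stop("no populated shells to allocate edges to", call. = FALSE)
  quota <- w / sum(w) * n_total
  base <- floor(quota)
  short <- n_total - sum(base)
  frac_order <- order(quota - base, decreasing = TRUE)
  add <- integer(length(Q1))
  if (short > 0) add[frac_order[seq_len(short)]] <- 1L
  as.integer(base + add)
}

#' Stochastic ensembles along the cell radius
#'
#' Runs independent Gillespie ensembles shell by shell: each shell receives
#' its edge allotment from `Q1(r)`, its rate ratios from the rate fields,
#' and the volume scaling `omega = dr / edge_length` that makes the
#' count-level mass action agree with the deterministic shell equations.
#' Each run is recorded once after equilibration (burn-in of
#' `burn_factor * n` events plus a stationarity check), and cluster
#' statistics are accumulated across runs.
#'
#' @param cfg a [mito_config()].
#' @param gamma,psi,runs overrides of the configuration values.
#' @param radii radii of interest (um; nearest shells are used); `NULL`
#'   runs every shell with at least `min_edges` edges.
#' @param min_edges shells with fewer edges are skipped (with a notice).
#' @param profiles optional precomputed [density_profiles()].
#' @param burn_factor passed to [simulate_graph()].
#' @param capacity passed to [occupancy()].
#' @return an object of class `radial_ensemble`: list with `summary` (one
#'   row per simulated shell: `r`, `n_edges`, `runs`, ensemble means and
#'   standard errors of the node counts, mean largest-cluster fraction)
#'   and `clusters` (per-shell [cluster_size_distribution()] tables).
#' @export
radial_ensemble <- function(cfg = mito_config(), gamma = cfg$gamma,
                            psi = cfg$psi, runs = cfg$runs, radii = NULL,
                            min_edges = 2L, profiles = NULL,
                            burn_factor = 20, capacity = "warn") {
  if (is.null(profiles))
    profiles <- density_profiles(cfg, psi = psi, capacity = capacity)
  rates <- rate_fields(profiles, gamma = gamma)
  tab <- profiles$table
  n_shell <- allocate_shell_edges(tab$Q1, cfg$dr, cfg$edge_length, cfg$M)
  idx <- if (is.null(radii)) {
    seq_along(n_shell)
  } else {
    unique(vapply(radii, function(x) which.min(abs(tab$r - x)), integer(1)))
  }
  omega <- cfg$dr / cfg$edge_length
  rows <- list()
  clusters <- list()
  for (i in idx) {
    n <- n_shell[i]
    if (n < min_edges) {
      if (!is.null(radii))
        message(sprintf("shell at r = %.2f um has %d edge(s); skipped", tab$r[i], n))
      next
    }
    u_acc <- matrix(NA_real_, nrow = runs, ncol = 3)
    lf <- numeric(runs)
    sizes <- vector("list", runs)
    for (k in seq_len(runs)) {
      sim <- simulate_graph(init_fragmented(n, cfg$edge_length),
                            alpha1 = rates$alpha1[i], alpha2 = rates$alpha2[i],
                            omega = omega, burn_factor = burn_factor,
                            seed = child_seed(cfg$seed, i * 100003L + k))
      u_acc[k, ] <- sim$u_mean
      sz <- cluster_sizes(sim$graph)
      sizes[[k]] <- sz
      lf[k] <- max(sz) / n
    }
    rows[[length(rows) + 1L]] <- data.frame(
      r = tab$r[i], n_edges = n, runs = runs,
      u1 = mean(u_acc[, 1]), u2 = mean(u_acc[, 2]), u3 = mean(u_acc[, 3]),
      se_u1 = sd(u_acc[, 1]) / sqrt(runs),
      se_u2 = sd(u_acc[, 2]) / sqrt(runs),
      se_u3 = sd(u_acc[, 3]) / sqrt(runs),
      largest_frac = mean(lf),
      se_largest_frac = sd(lf) / sqrt(runs))
    clusters[[as.character(tab$r[i])]] <- cluster_size_distribution(sizes)
  }
  structure(list(summary = do.call(rbind, rows), clusters = clusters,
                 cfg = cfg, gamma = gamma, psi = psi, omega = omega),
            class = "radial_ensemble")
}

#' @export
print.radial_ensemble <- function(x, ...) {
  cat(sprintf("radial ensemble: gamma = %g, psi = %g, %d shell(s), %d runs each\n",
              x$gamma, x$psi, nrow(x$summary), x$summary$runs[1]))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Export a mitochondrial graph
#'
#' Writes a plain edge-list CSV (`edge`, `node_a`, `node_b`) or GraphML
#' (via igraph).
#'
#' @param g a `mito_graph`.
#' @param path output file.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  a <- g$node_of_endpoint[seq(1L, 2L * g$n_edges, by = 2L)]
  b <- g$node_of_endpoint[seq(2L, 2L * g$n_edges, by = 2L)]
  if (format == "csv") {
    write.csv(data.frame(edge = seq_len(g$n_edges) - 1L,
                         node_a = a, node_b = b),
              path, row.names = FALSE)
  } else {
    ig <- igraph::graph_from_edgelist(cbind(a, b) + 1L, directed = FALSE)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
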