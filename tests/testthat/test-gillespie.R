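test_that("initial graphs have the expected node structure", {
  g1 <- init_fragmented(1)
  expect_equal(unname(node_degrees(g1)), c(2L, 0L, 0L))
  g <- init_fragmented(5000)
  d <- node_degrees(g)
  expect_equal(unname(d), c(10000L, 0L, 0L))
  expect_equal(g$n_edges * g$edge_length, 1000)  # the reference chondriome
  expect_equal(cluster_sizes(g), rep(1L, 5000))
  ch <- mito_graph(6, "chain")
  expect_equal(unname(node_degrees(ch)), c(2L, 5L, 0L))
  expect_equal(cluster_sizes(ch), 6L)
  expect_equal(largest_cluster_fraction(cluster_sizes(ch), 6), 1.0)
})

test_that("propensities honor the channel structure and exclusions", {
  # fragmented: no fission substrate
  p <- propensities(init_fragmented(4), alpha1 = 2, alpha2 = 3)
  expect_equal(p$propensity[p$kind == "deg2_fission"], 0)
  expect_equal(p$propensity[p$kind == "deg3_fission"], 0)
  expect_equal(p$propensity[p$kind == "tip_side_fuse"], 0)
  # u1(u1-1)/2 - n_iso pairs: 4 edges -> 28 - 4
  expect_equal(p$propensity[p$kind == "tip_tip_fuse"], 2 * (28 - 4))
  # a single isolated edge cannot fuse onto itself
  p1 <- propensities(init_fragmented(1), alpha1 = 5, alpha2 = 5)
  expect_equal(sum(p1$propensity), 0)
  # 3-edge chain: u1 = 2, u2 = 2, n_iso = 0, n_mix = 2
  pc <- propensities(mito_graph(3, "chain"), alpha1 = 1, alpha2 = 1, omega = 1)
  expect_equal(pc$propensity[pc$kind == "tip_tip_fuse"], 1)   # the two chain ends
  expect_equal(pc$propensity[pc$kind == "deg2_fission"], 2)
  expect_equal(pc$propensity[pc$kind == "tip_side_fuse"], 2 * 2 - 2)
})

test_that("pure fission reaches the absorbing fragmented state", {
  sim <- simulate_graph(mito_graph(30, "chain"), alpha1 = 0, alpha2 = 0,
                        seed = 4, check_stationarity = FALSE)
  expect_true(sim$absorbed)
  expect_equal(unname(sim$u_final), c(60, 0, 0))
})

test_that("the engine conserves edges and caps degrees through long runs", {
  sim <- simulate_graph(init_fragmented(400), alpha1 = 1.5, alpha2 = 0.3,
                        omega = 400 / 50, seed = 10, sample_factor = 10)
  expect_equal(length(sim$graph$node_of_endpoint), 800L)
  d <- node_degrees(sim$graph)
  expect_equal(sum(d * 1:3), 800L)          # every endpoint accounted for
  expect_lte(sim$max_degree, 3L)
  expect_equal(sum(cluster_sizes(sim$graph)), 400L)
  # reproducible per seed
  sim2 <- simulate_graph(init_fragmented(400), alpha1 = 1.5, alpha2 = 0.3,
                         omega = 400 / 50, seed = 10, sample_factor = 10)
  expect_identical(sim$graph$node_of_endpoint, sim2$graph$node_of_endpoint)
})

test_that("compiled components agree with an igraph traversal", {
  for (seed in 1:3) {
    sim <- simulate_graph(init_fragmented(250), alpha1 = 2, alpha2 = 0.5,
                          omega = 5, seed = seed, check_stationarity = FALSE)
    expect_identical(cluster_sizes(sim$graph, "unionfind"),
                     cluster_sizes(sim$graph, "igraph"))
  }
})

test_that("a two-edge system obeys detailed balance exactly", {
  # tip-to-tip only: stationary law from the exact CTMC; by detailed balance
  # pi(two free edges) / pi(one specific chain) = km / kp
  kp <- 1.3; km <- 0.7
  states <- enumerate_graph_states(2)
  gen <- ctmc_generator(states, kp, km, 0, 0)
  pi <- ctmc_stationary(gen)
  frag_key <- state_key_nodes(init_fragmented(2)$node_of_endpoint)
  chain_key <- state_key_nodes(mito_graph(2, "chain")$node_of_endpoint)
  expect_equal(unname(pi[frag_key] / pi[chain_key]), km / kp, tolerance = 1e-10)
  # engine occupation of the fragmented state matches the CTMC
  keys <- sample_engine_states(2, kp, km, 0, 0, n_samples = 4000, dt = 4,
                               burn_t = 50, seed = 123)
  reachable <- pi[pi > 1e-12]
  obs <- table(factor(keys, levels = names(reachable)))
  gof <- suppressWarnings(chisq.test(as.numeric(obs),
                                     p = as.numeric(reachable) / sum(reachable)))
  expect_gt(gof$p.value, 0.01)
})

test_that("the three-edge stationary law matches the exhaustive CTMC", {
  kp <- 1.1; km <- 1; lp <- 1.6; lm <- 0.9
  states <- enumerate_graph_states(3)
  gen <- ctmc_generator(states, kp, km, lp, lm)
  pi <- ctmc_stationary(gen)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  keys <- sample_engine_states(3, kp, km, lp, lm, n_samples = 4000, dt = 4,
                               burn_t = 50, seed = 7)
  expect_true(all(keys %in% names(pi)[pi > 1e-14]))
  agg <- sort(pi[pi > 0.004], decreasing = TRUE)
  obs <- table(factor(keys, levels = names(agg)))
  other <- sum(keys %in% setdiff(names(pi), names(agg)))
  gof <- suppressWarnings(chisq.test(c(as.numeric(obs), other),
                                     p = c(as.numeric(agg), 1 - sum(agg))))
  expect_gt(gof$p.value, 0.01)
})

test_that("stationary summaries do not depend on the initial condition", {
  n <- 300
  runs <- 12
  u_frag <- t(sapply(seq_len(runs), function(k)
    simulate_graph(init_fragmented(n), 1.2, 0.15, omega = n / 60,
                   seed = 300 + k)$u_mean))
  u_fused <- t(sapply(seq_len(runs), function(k)
    simulate_graph(mito_graph(n, "chain"), 1.2, 0.15, omega = n / 60,
                   seed = 600 + k)$u_mean))
  for (i in 1:3) {
    se <- sqrt(sd(u_frag[, i])^2 / runs + sd(u_fused[, i])^2 / runs)
    expect_lt(abs(mean(u_frag[, i]) - mean(u_fused[, i])), 4 * se + 1e-9)
  }
})

test_that("ensemble means approach the mass-action solution for large systems", {
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  ss <- solve_radial_steady_state(cfg, gamma = 0.1, profiles = pr)
  i <- which.min(abs(ss$r - 8))
  n <- 2000
  det <- c(ss$u1[i], ss$u2[i], ss$u3[i]) / (2 * ss$Q1[i]) * (2 * n)
  runs <- 30
  um <- t(sapply(seq_len(runs), function(k)
    simulate_graph(init_fragmented(n), ss$alpha1[i], ss$alpha2[i],
                   omega = n / ss$Q1[i], seed = 5000 + k,
                   check_stationarity = FALSE)$u_mean))
  for (j in 1:3) {
    se <- sd(um[, j]) / sqrt(runs)
    expect_lt(abs(mean(um[, j]) - det[j]), 4 * se)
  }
})

test_that("edge allocation is exact and proportional", {
  q1 <- c(0, 2, 5, 3, 0.2)
  n <- allocate_shell_edges(q1, dr = 0.16, edge_length = 0.2, M = 100)
  expect_equal(sum(n), 500L)
  expect_equal(n[1], 0L)
  expect_gt(n[3], n[2])
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  n_ref <- allocate_shell_edges(pr$table$Q1, cfg$dr, cfg$edge_length, cfg$M)
  expect_identical(sum(n_ref), 5000L)
  expect_equal(sum(n_ref) * cfg$edge_length, 1000)
})

test_that("radial ensembles carry per-shell statistics", {
  cfg <- mito_config(runs = 6L)
  ens <- radial_ensemble(cfg, gamma = 0.5, radii = c(4, 8))
  expect_equal(nrow(ens$summary), 2L)
  expect_equal(ens$summary$r, c(3.92, 7.92))
  expect_true(all(ens$summary$largest_frac > 0 & ens$summary$largest_frac <= 1))
  d <- ens$clusters[[1]]
  expect_equal(sum(d$probability), 1)
  expect_s3_class(d, "data.frame")
  # graph export round-trip
  g <- mito_graph(4, "chain")
  f <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, f)
  expect_equal(nrow(read.csv(f)), 4L)
})
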