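test_that("without fusion the network is fully fragmented", {
  u <- steady_state_nodes(10, 0, 0)
  expect_equal(u, c(u1 = 20, u2 = 0, u3 = 0))
})

test_that("without branching the shell reduces to the closed-form quadratic", {
  for (a1 in c(0.05, 0.5, 5)) for (Q1 in c(3, 40)) {
    u <- steady_state_nodes(Q1, a1, 0)
    u1_closed <- (-1 + sqrt(1 + 8 * a1 * Q1)) / (2 * a1)
    expect_equal(unname(u["u1"]), u1_closed, tolerance = 1e-12)
    expect_equal(unname(u["u3"]), 0)
  }
})

test_that("the algebraic root agrees with long-time ODE integration", {
  skip_if_not_installed("deSolve")
  cases <- expand.grid(Q1 = c(5, 76), a1 = c(0.01, 0.66, 4),
                       a2 = c(0, 0.006, 0.2))
  for (i in seq_len(nrow(cases))) {
    u <- steady_state_nodes(cases$Q1[i], cases$a1[i], cases$a2[i])
    ode <- ode_equilibrium(cases$Q1[i], cases$a1[i], cases$a2[i])
    expect_equal(unname(u), ode, tolerance = 1e-6)
  }
})

test_that("edge conservation holds across the (gamma, psi) plane", {
  cfg <- mito_config()
  for (psi in c(-0.2, 0, 0.2)) {
    pr <- density_profiles(cfg, psi = psi, capacity = "ignore")
    for (gam in c(1e-3, 0.1, 10)) {
      ss <- solve_radial_steady_state(cfg, gamma = gam, profiles = pr)
      res <- ss$u1 + 2 * ss$u2 + 3 * ss$u3 - 2 * ss$Q1
      expect_lt(max(abs(res) / pmax(ss$Q1, 1)), 1e-10)
      expect_true(all(ss$u1 >= 0 & ss$u2 >= 0 & ss$u3 >= 0))
    }
  }
})

test_that("the non-negative root is unique", {
  for (a1 in c(0.1, 2)) for (a2 in c(0.01, 1)) for (Q1 in c(1, 50)) {
    roots <- polyroot(c(-2 * Q1, 1, a1, 1.5 * a1 * a2))
    real <- Re(roots[abs(Im(roots)) < 1e-8])
    nonneg <- real[real >= 0]
    expect_length(nonneg, 1L)
  }
})

test_that("rate fields are gamma-linear and crossing-limited", {
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  r1 <- rate_fields(pr, gamma = 0.1)
  r2 <- rate_fields(pr, gamma = 0.2)
  expect_equal(r2$alpha1, 2 * r1$alpha1, tolerance = 1e-12)
  expect_equal(r2$alpha2, 2 * r1$alpha2, tolerance = 1e-12)
  expect_equal(rate_fields(pr, gamma = 0)$alpha1, rep(0, nrow(pr$table)))
  i4 <- which.min(abs(pr$table$r - 4))
  i12 <- which.min(abs(pr$table$r - 12))
  expect_gt(r1$alpha2[i4], r1$alpha2[i12])  # branching decays outward
  expect_true(all(r1$alpha1 >= 0 & r1$alpha2 >= 0))
  # the exposed Q1 exponent recovers the intensive normalization
  r0 <- rate_fields(pr, gamma = 0.1, q1_exponent = 2)
  nz <- pr$table$Q1 > 0
  expect_equal(r0$alpha1[nz], r1$alpha1[nz] / pr$table$Q1[nz]^2,
               tolerance = 1e-12)
})

test_that("empty shells yield empty solutions and masked segment lengths", {
  cfg <- mito_config()
  ss <- solve_radial_steady_state(cfg, gamma = 0.1)
  outer <- ss[ss$Q1 == 0, ]
  expect_true(all(outer$u1 == 0 & outer$u2 == 0 & outer$u3 == 0))
  expect_true(all(is.na(outer$s_um)))
  s <- mean_segment_length(ss, cfg$edge_length)
  expect_equal(s$s_um, ss$s_um)
})

test_that("a fragmented shell has unit segment length", {
  ss <- data.frame(r = 1, Q1 = 10, u1 = 20, u2 = 0, u3 = 0)
  expect_equal(mean_segment_length(ss, 0.2)$s_edges, 1)
  expect_equal(mean_segment_length(ss, 0.2)$s_um, 0.2)
})

test_that("branching dominates the center and bulk nodes the periphery", {
  cfg <- mito_config()
  ss <- solve_radial_steady_state(cfg, gamma = 0.1)
  # the near-window shells (r < l1) are empty; branching dominance sets in
  # where the occupied-crossing density is high, around r ~ 1 um
  i1 <- which.min(abs(ss$r - 1.2))
  expect_gt(ss$u3[i1], ss$u2[i1])
  mid <- ss[ss$r > 6 & ss$r < 14, ]
  expect_true(all(mid$u2 > mid$u3))
  b <- partition_border(ss)
  expect_true(is.finite(b) && b > 0 && b < cfg$L)
})

test_that("the partition border matches a finer-grid scan and degenerate cases", {
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  ss <- solve_radial_steady_state(cfg, gamma = 0.2, profiles = pr)
  b <- partition_border(ss)
  cfg_fine <- mito_config(dr = 0.016)
  ss_fine <- solve_radial_steady_state(cfg_fine, gamma = 0.2)
  b_fine <- partition_border(ss_fine)
  expect_lt(abs(b - b_fine), cfg$dr)
  # no branching anywhere -> no border
  ss0 <- ss
  ss0$u3 <- 0
  expect_true(is.na(partition_border(ss0)))
  # branching dominant everywhere -> border beyond the cell
  ss1 <- ss
  ss1$u3 <- ss1$u2 + 1
  expect_identical(partition_border(ss1), Inf)
})
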