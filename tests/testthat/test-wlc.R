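test_that("uniform occupancy matches the closed-form normalization", {
  cfg <- mito_config()
  eps <- occupancy(c(0.5, 3, 8, 15), cfg)
  expect_equal(eps, rep(1000 / (200 * 14.5), 4))
  expect_equal(eps[1], 0.34483, tolerance = 1e-5)
  expect_equal(occupancy(c(0.2, 15.5), cfg), c(0, 0))  # outside [l1, l2]
})

test_that("biased occupancy conserves mass and flips with the drift sign", {
  cfg <- mito_config()
  for (psi in c(-0.2, 0, 0.2)) {
    m <- integrate(function(x) occupancy(x, cfg, psi = psi, capacity = "ignore"),
                   cfg$l1, cfg$l2, rel.tol = 1e-10)$value * cfg$n_fibers
    expect_equal(m, cfg$M, tolerance = 1e-8)
  }
  rho <- seq(0.5, 15, length.out = 31)
  fwd <- occupancy(rho, cfg, psi = 0.15, capacity = "ignore")
  rev <- occupancy(cfg$l1 + cfg$l2 - rho, cfg, psi = -0.15, capacity = "ignore")
  expect_equal(fwd, rev, tolerance = 1e-12)
  expect_true(all(diff(fwd) > 0))   # positive drift accumulates outward
})

test_that("an overloaded cytoskeleton is flagged and never clipped", {
  cfg <- mito_config()
  expect_error(occupancy(8, cfg, psi = 0.4, capacity = "error"),
               "overloaded cytoskeleton")
  expect_warning(eps <- occupancy(15, cfg, psi = 0.4, capacity = "warn"),
                 "overloaded")
  expect_gt(eps, 1)  # reported as-is, not clipped
  expect_silent(occupancy(15, cfg, psi = 0.4, capacity = "ignore"))
  expect_error(occupancy(8, mito_config(M = 4000), capacity = "error"),
               "overloaded")
})

test_that("the end-to-end density is a proper distribution", {
  for (Lp in c(10, 32, 100)) for (rho in c(4, 10, 16)) {
    z <- integrate(end_to_end_pdf, 0, rho, rho = rho, Lp = Lp,
                   subdivisions = 200L)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  expect_equal(end_to_end_pdf(c(-0.1, 17), 16, 32), c(0, 0))
  expect_true(all(end_to_end_pdf(seq(0, 16, by = 0.4), 16, 10) >= 0))
})

test_that("the two evaluation branches join continuously", {
  for (Lp in c(10, 32, 100)) for (rho in c(8, 16)) {
    split <- 0.9 * rho
    lo <- end_to_end_pdf(split - 1e-8, rho, Lp)
    hi <- end_to_end_pdf(split + 1e-8, rho, Lp)
    expect_equal(lo, hi, tolerance = 1e-5)
  }
})

test_that("stiff fibers concentrate near full extension", {
  rho <- 5
  m <- integrate(function(r) r * end_to_end_pdf(r, rho, Lp = 5000), 0, rho)$value
  expect_equal(m, rho, tolerance = 0.01)
})

test_that("the density matches freely rotating chain ensembles", {
  set.seed(17)
  th <- bond_angle_for_persistence(0.02, 32)
  ee <- replicate(2000, {
    v <- frc_chain(16, 0.02, th)$vertices
    sqrt(sum(v[nrow(v), ]^2))
  })
  # every histogram bin agrees with the predicted probability within three
  # Monte Carlo standard errors of this ensemble
  breaks <- c(0, seq(12, 15.6, by = 0.4), 16)
  obs <- as.numeric(table(cut(ee, breaks)))
  p <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(end_to_end_pdf, breaks[i], breaks[i + 1], rho = 16, Lp = 32,
              subdivisions = 200L)$value, numeric(1))
  n <- length(ee)
  keep <- p * n >= 5
  z <- (obs - n * p) / sqrt(n * p * (1 - p))
  expect_lt(max(abs(z[keep])), 3)
})

test_that("the cap-area factor obeys its geometric identities", {
  expect_equal(cap_area(5, 5, 0.2), pi * 0.04)
  expect_equal(cap_area(5.2, 5, 0.2), 0)
  expect_equal(cap_area(4.8, 5, 0.2), 0)
  v <- integrate(function(x) cap_area(x, 3, 0.25), 2.75, 3.25)$value
  expect_equal(v, 4 / 3 * pi * 0.25^3, tolerance = 1e-8)
  expect_error(cap_area(1, 3, 0.2), "defined for")
  expect_error(cap_area(3, -1, 0.2), "positive")
})

test_that("radial densities conserve mitochondrial mass", {
  cfg <- mito_config()
  for (psi in c(-0.2, 0, 0.2)) {
    m <- integrate(function(r) radial_density(r, 1, cfg, psi = psi,
                                              capacity = "ignore"),
                   0, cfg$L, subdivisions = 400L, rel.tol = 1e-7)$value
    expect_lt(abs(m - cfg$M) / cfg$M, 1e-3)
  }
  expect_error(radial_density(5, 3, cfg), "steric")
})

test_that("uniform occupancy factorizes the pair density", {
  cfg <- mito_config()
  r <- c(1, 4, 8, 12, 14.5)
  q1 <- radial_density(r, 1, cfg)
  q2 <- radial_density(r, 2, cfg)
  expect_equal(q2, occupancy(8, cfg) * q1, tolerance = 1e-6)
  expect_true(all(q2 <= q1))   # eps <= 1 implies Q2 <= Q1 pointwise
})

test_that("crossing densities vanish without substrate and scale quadratically", {
  expect_equal(crossing_density(c(2, 5), function(x) numeric(length(x)), 0.2, 16),
               c(0, 0))
  expect_equal(crossing_density_asymptotic(3, 2 * 7, 0.2),
               4 * crossing_density_asymptotic(3, 7, 0.2))
  expect_equal(crossing_density_asymptotic(3, 7, 0), 0)
})

test_that("the bulk asymptotic matches the full quadrature away from the center", {
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  r <- pr$table$r
  q1 <- pr$table$Q1
  # the asymptotic assumes a locally flat density across the proximity
  # ball; exclude the collapse at the occupancy-window edges
  flat <- vapply(seq_along(r), function(i) {
    lo <- pr$Q1_fun(r[i] - cfg$sigma); hi <- pr$Q1_fun(r[i] + cfg$sigma)
    q1[i] > 0 && abs(hi - lo) < 0.1 * q1[i]
  }, logical(1))
  ok <- r > 4 * cfg$sigma & flat
  expect_gt(sum(ok), 50)
  full <- pr$table$S11[ok]
  asym <- crossing_density_asymptotic(r[ok], q1[ok], cfg$sigma)
  expect_lt(max(abs(asym - full) / full), 0.05)
})

test_that("profile tables are consistent and crossings decay outward", {
  cfg <- mito_config()
  pr <- density_profiles(cfg)
  tab <- pr$table
  expect_true(all(tab[, -1] >= 0))
  expect_equal(sum(tab$Q1) * cfg$dr, cfg$M, tolerance = 5e-3)
  # S11 inherits the sharp radial decay: non-increasing beyond its peak
  peak <- which.max(tab$S11)
  bulk <- tab$S11[tab$r > tab$r[peak] & tab$r < cfg$l2]
  expect_true(all(diff(bulk) <= 1e-9))
  expect_output(print(pr), "radial density profiles")
})
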