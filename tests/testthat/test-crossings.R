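test_that("two orthogonal chains through a common point give one crossing", {
  chains <- list(straight_vertices(c(-1, 0, 2), c(1, 0, 0), 100, 0.02),
                 straight_vertices(c(0, -1, 2), c(0, 1, 0), 100, 0.02))
  cs <- fixture_array(chains, sigma = 0.2, L = 4)
  x <- detect_crossings(cs, 0.2)
  expect_equal(nrow(x), 1L)
  expect_equal(x$chain_i, 1L)
  expect_equal(x$chain_j, 2L)
  expect_equal(x$rho_i, 1, tolerance = 0.03)   # midpoint of each chain
  expect_equal(x$rho_j, 1, tolerance = 0.03)
  expect_equal(x$r, 2, tolerance = 1e-6)
  expect_lt(x$min_dist, 1e-9)
})

test_that("parallel chains separated by 2 sigma never cross", {
  chains <- list(straight_vertices(c(0, 0, 1), c(1, 0, 0), 100, 0.02),
                 straight_vertices(c(0, 0.4, 1), c(1, 0, 0), 100, 0.02))
  cs <- fixture_array(chains, sigma = 0.2, L = 3)
  expect_equal(nrow(detect_crossings(cs, 0.2)), 0L)
})

test_that("a contiguous shallow-angle proximity region counts once", {
  # chains intersect at ~3 degrees: many bond pairs fall below sigma
  ang <- 3 * pi / 180
  chains <- list(straight_vertices(c(-2, 0, 1), c(1, 0, 0), 200, 0.02),
                 straight_vertices(c(-2, -2 * tan(ang), 1),
                                   c(cos(ang), sin(ang), 0), 200, 0.02))
  cs <- fixture_array(chains, sigma = 0.2, L = 5)
  x <- detect_crossings(cs, 0.2)
  expect_equal(nrow(x), 1L)
  expect_lt(x$min_dist, 0.02)
})

test_that("crossing detection is symmetric and rotation invariant", {
  cfg <- mito_config(n_fibers = 25L, L = 2, Lp = 5)
  cs <- cytoskeleton(cfg, seed = 31)
  x <- detect_crossings(cs, 0.2)
  expect_gt(nrow(x), 0)
  # reversing the chain order relabels but preserves the crossing set
  rev_order <- rev(seq_len(cs$n_fibers))
  vr <- do.call(rbind, lapply(rev_order, function(i)
    cs$vertices[(cs$offsets[i] + 1):cs$offsets[i + 1], ]))
  csr <- cs
  csr$vertices <- vr
  xr <- detect_crossings(csr, 0.2)
  expect_equal(nrow(xr), nrow(x))
  expect_equal(sort(xr$min_dist), sort(x$min_dist), tolerance = 1e-9)
  # a rigid rotation of the whole array changes nothing
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  cst <- cs
  cst$vertices <- cs$vertices %*% t(R)
  xt <- detect_crossings(cst, 0.2)
  expect_equal(nrow(xt), nrow(x))
  expect_equal(sort(xt$r), sort(x$r), tolerance = 1e-9)
  expect_equal(sort(xt$min_dist), sort(x$min_dist), tolerance = 1e-9)
})

test_that("the spatial hash grid reproduces the all-pairs scan exactly", {
  cfg <- mito_config(n_fibers = 15L, L = 1.5, Lp = 3)
  cs <- cytoskeleton(cfg, seed = 12)
  a <- detect_crossings(cs, 0.25, use_grid = TRUE)
  b <- detect_crossings(cs, 0.25, use_grid = FALSE)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("radial histograms conserve contour length", {
  # a single straight chain from the origin covers each shell with dr of
  # contour: density 1 everywhere up to L
  cs1 <- fixture_array(list(straight_vertices(c(0, 0, 0), c(0, 0, 1), 500, 0.02)))
  h1 <- radial_histogram(cs1, 0.1)
  expect_equal(h1$density, rep(1, nrow(h1)), tolerance = 1e-9)
  cfg <- mito_config(n_fibers = 40L, L = 4)
  cs <- cytoskeleton(cfg, seed = 8)
  h <- radial_histogram(cs, 0.05, r_max = 8)
  expect_equal(sum(h$density) * 0.05, cs$n_fibers * cs$L, tolerance = 1e-9)
  x <- detect_crossings(cs, 0.2)
  hx <- radial_histogram(x, 0.2, r_max = 8)
  expect_equal(sum(hx$density) * 0.2, nrow(x))
})

test_that("discrete crossing counts follow the crossing-density shape", {
  cfg <- mito_config()
  counts <- 0
  for (s in 1:3) {
    cs <- cytoskeleton(cfg, n_fibers = 300L, seed = 40 + s)
    counts <- counts + radial_histogram(detect_crossings(cs, 0.2), 0.16)$density
  }
  r <- seq(0.08, 15.92, by = 0.16)
  q0 <- radial_density(r, 0, cfg) / cfg$n_fibers
  q0f <- splinefun(r, q0)
  s00 <- crossing_density(r, function(x) pmax(0, q0f(x)), 0.2, 16)
  # coarse 2-um bins over the bulk: the two profiles are proportional
  bins <- cut(r, seq(2, 12, by = 2))
  ok <- !is.na(bins)
  lc <- log(tapply(counts[ok], bins[ok], sum))
  ls <- log(tapply(s00[ok], bins[ok], sum))
  expect_gt(cor(lc, ls), 0.95)
})

test_that("chain and crossing exports are well-formed CSV", {
  cfg <- mito_config(n_fibers = 3L, L = 0.4)
  cs <- cytoskeleton(cfg, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  export_csv(cs, f1)
  df <- read.csv(f1)
  expect_named(df, c("chain_id", "vertex_index", "x", "y", "z"))
  expect_equal(nrow(df), nrow(cs$vertices))
  x <- detect_crossings(cytoskeleton(cfg, n_fibers = 20L, L = 2, seed = 3), 0.3)
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_csv(x, f2)
  expect_named(read.csv(f2),
               c("chain_i", "chain_j", "rho_i", "rho_j", "r", "min_dist"))
})
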