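# Position-dependent fusion/fission rate fields and the deterministic
# (mass-action) steady state of the mitochondrial graph, solved shell by
# shell on the radial grid.

#' Cytoskeleton-dependent fusion/fission rate fields
#'
#' Tip-to-tip fusion is supported by any fusion-competent apposition of two
#' mitochondria: pairs superimposed on the same fiber (`Q2`) and occupied
#' fiber crossings (`S11`). Branching (tip-to-side) fusion requires two
#' proximal fibers and is limited by occupied crossings alone. The rate
#' ratios are therefore taken proportional to those substrate densities,
#'
#'   `alpha1(r) = gamma * rate_scale * (weight_q2 * Q2(r) + S11(r)) / Q1(r)^p`
#'   `alpha2(r) = gamma * rate_scale * S11(r) / Q1(r)^p`
#'
#' with `p = q1_exponent` (default 0) and a single scale constant
#' `rate_scale` calibrated so that the reference cell's segment-length peak
#' falls at `gamma ~ 0.1` with perinuclear segments of about a micrometer
#' (the regime the model identifies as physiological). Both rates are linear
#' in `gamma` and vanish on empty shells.
#'
#' @param profiles a [density_profiles()] object.
#' @param gamma fusion-to-fission propensity ratio.
#' @param rate_scale,weight_q2,q1_exponent model constants; default from the
#'   generating configuration.
#' @return a `data.frame` with columns `r`, `alpha1`, `alpha2`.
#' @export
rate_fields <- function(profiles, gamma = profiles$cfg$gamma,
                        rate_scale = profiles$cfg$rate_scale,
                        weight_q2 = profiles$cfg$weight_q2,
                        q1_exponent = profiles$cfg$q1_exponent) {
  stopifnot(inherits(profiles, "density_profiles"))
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  tab <- profiles$table
  denom <- ifelse(tab$Q1 > 0, tab$Q1^q1_exponent, Inf)
  alpha1 <- ifelse(tab$Q1 > 0,
                   gamma * rate_scale * (weight_q2 * tab$Q2 + tab$S11) / denom,
                   0)
  alpha2 <- ifelse(tab$Q1 > 0,
                   gamma * rate_scale * tab$S11 / denom,
                   0)
  data.frame(r = tab$r, alpha1 = alpha1, alpha2 = alpha2)
}

#' Mass-action steady state of one radial shell
#'
#' Solves the stationary balance of the fission/fusion graph for the node
#' densities: `u2 = (alpha1 / 2) u1^2` (tip-to-tip), `u3 = alpha2 u1 u2`
#' (tip-to-side), under the edge conservation `u1 + 2 u2 + 3 u3 = 2 Q1`.
#' Back-substitution reduces the system to a cubic in `u1`,
#' `u1 + alpha1 u1^2 + (3 alpha1 alpha2 / 2) u1^3 = 2 Q1`, whose left side
#' is strictly increasing on `u1 >= 0`, so the non-negative root is unique.
#' The root is taken from the polynomial solver and polished (bisection
#' fallback on `[0, 2 Q1]`), with residuals below `1e-10 * max(Q1, 1)`.
#'
#' @param Q1 edge density of the shell (`>= 0`).
#' @param alpha1,alpha2 non-negative rate ratios.
#' @return named vector `c(u1, u2, u3)`.
#' @examples
#' steady_state_nodes(10, 0, 0)      # fully fragmented: u1 = 2 Q1
#' steady_state_nodes(10, 0.5, 0.1)
#' @export
steady_state_nodes <- function(Q1, alpha1, alpha2) {
  if (Q1 < 0 || alpha1 < 0 || alpha2 < 0)
    stop("Q1, alpha1 and alpha2 must be non-negative", call. = FALSE)
  if (Q1 == 0) return(c(u1 = 0, u2 = 0, u3 = 0))
  c3 <- 1.5 * alpha1 * alpha2
  c2 <- alpha1
  f <- function(u) u * (1 + u * (c2 + u * c3)) - 2 * Q1
  u1 <- NA_real_
  if (c3 == 0 && c2 == 0) {
    u1 <- 2 * Q1
  } else {
    roots <- polyroot(c(-2 * Q1, 1, c2, c3))
    real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
    real <- real[real >= 0 & real <= 2 * Q1 * (1 + 1e-9)]
    if (length(real) > 0) u1 <- min(real)
  }
  tol <- 1e-12 * max(Q1, 1)
  if (is.na(u1) || abs(f(u1)) > tol) {
    u1 <- uniroot(f, c(0, 2 * Q1), tol = .Machine$double.eps^0.75)$root
  }
  if (abs(f(u1)) > 1e-10 * max(Q1, 1))
    stop("shell steady state failed to converge (residual ",
         signif(abs(f(u1)), 3), ")", call. = FALSE)
  u2 <- alpha1 / 2 * u1^2
  u3 <- alpha2 * u1 * u2
  c(u1 = u1, u2 = u2, u3 = u3)
}

#' Radially resolved deterministic steady state
#'
#' Solves [steady_state_nodes()] independently on every shell of the radial
#' grid (there is no radial transport of nodes at steady state) and derives
#' node fractions (of the total system size `2 Q1(r)`) and the mean segment
#' length.
#'
#' @param cfg a [mito_config()].
#' @param gamma,psi overrides of the configuration values.
#' @param profiles optionally, precomputed [density_profiles()] (must match
#'   `psi`); computed on the fly otherwise.
#' @param capacity passed to [occupancy()].
#' @return a `data.frame` of class `steady_state_profile` with columns `r`,
#'   `Q1`, `alpha1`, `alpha2`, `u1`, `u2`, `u3`, `frac1`, `frac2`, `frac3`,
#'   `s_edges`, `s_um`.
#' @export
solve_radial_steady_state <- function(cfg = mito_config(), gamma = cfg$gamma,
                                      psi = cfg$psi, profiles = NULL,
                                      capacity = "warn") {
  if (is.null(profiles))
    profiles <- density_profiles(cfg, psi = psi, capacity = capacity)
  rates <- rate_fields(profiles, gamma = gamma)
  tab <- profiles$table
  u <- t(vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(steady_state_nodes(tab$Q1[i], rates$alpha1[i], rates$alpha2[i]),
             error = function(e)
               stop("shell ", i, " (r = ", tab$r[i], " um): ",
                    conditionMessage(e), call. = FALSE))
  }, numeric(3)))
  tot <- 2 * tab$Q1
  frac <- sweep(u * rep(c(1, 2, 3), each = nrow(u)), 1, tot, "/")
  frac[tot == 0, ] <- NA_real_
  seg_den <- u[, 1] + 3 * u[, 3]
  s_edges <- ifelse(seg_den > 0, tot / seg_den, NA_real_)
  out <- data.frame(r = tab$r, Q1 = tab$Q1,
                    alpha1 = rates$alpha1, alpha2 = rates$alpha2,
                    u1 = u[, 1], u2 = u[, 2], u3 = u[, 3],
                    frac1 = frac[, 1], frac2 = frac[, 2], frac3 = frac[, 3],
                    s_edges = s_edges,
                    s_um = s_edges * cfg$edge_length)
  attr(out, "cfg") <- cfg
  attr(out, "gamma") <- gamma
  attr(out, "psi") <- psi
  class(out) <- c("steady_state_profile", "data.frame")
  out
}

#' Mean segment length of a solved shell profile
#'
#' A network with node densities `u_i` carries `(u1 + 3 u3) / 2` segments,
#' so the mean segment length is `s = 2 Q1 / (u1 + 3 u3)` edges. Shells
#' without segments (empty shells) are `NA`.
#'
#' @param u a `steady_state_profile` (or any data frame with `Q1`, `u1`,
#'   `u3`).
#' @param edge_length edge length (um) used to convert to micrometers.
#' @return a `data.frame` with `r`, `s_edges`, `s_um`.
#' @export
mean_segment_length <- function(u, edge_length = 0.2) {
  den <- u$u1 + 3 * u$u3
  s <- ifelse(den > 0, 2 * u$Q1 / den, NA_real_)
  data.frame(r = u$r, s_edges = s, s_um = s * edge_length)
}

#' Partition border between branching- and bulk-dominated reticulum
#'
#' The radius at which the dominance of branching nodes (`u3`, perinuclear
#' supercluster regime) gives way to the dominance of bulk nodes (`u2`,
#' peripheral fragmented regime): the first down-crossing of `u3 - u2`
#' (linearly interpolated between shell centers). Returns `NA` when no
#' shell is branching-dominated (no border exists) and `Inf` when branching
#' dominates out to the last populated shell (the border lies beyond the
#' cell).
#'
#' @param u a `steady_state_profile`.
#' @return border radius (um), `NA`, or `Inf`.
#' @export
partition_border <- function(u) {
  keep <- u$Q1 > 0 & is.finite(u$u2) & is.finite(u$u3)
  r <- u$r[keep]
  d <- (u$u3 - u$u2)[keep]
  if (length(r) == 0 || all(d <= 0)) return(NA_real_)
  first_dom <- which(d > 0)[1]
  after <- which(d[seq_along(d) >= first_dom] <= 0)
  if (length(after) == 0) return(Inf)
  i2 <- first_dom + after[1] - 1L
  i1 <- i2 - 1L
  # linear interpolation of the zero crossing
  r[i1] + (r[i2] - r[i1]) * d[i1] / (d[i1] - d[i2])
}

# Mass-action right-hand side of one shell; exposed for the ODE-equilibrium
# cross-check (time-dependent trajectories are not a user-facing feature).
mass_action_rhs <- function(u, alpha1, alpha2, kminus = 1, lminus = 1) {
  kplus <- alpha1 * kminus
  lplus <- alpha2 * lminus
  r_fuse_tt <- kplus / 2 * u[1]^2
  r_fis_2 <- kminus * u[2]
  r_fuse_ts <- lplus * u[1] * u[2]
  r_fis_3 <- lminus * u[3]
  c(-2 * r_fuse_tt + 2 * r_fis_2 - r_fuse_ts + r_fis_3,
    r_fuse_tt - r_fis_2 - r_fuse_ts + r_fis_3,
    r_fuse_ts - r_fis_3)
}
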