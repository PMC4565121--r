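# Semi-analytic worm-like-chain theory: end-to-end distance distribution,
# motor-biased occupancy, radial fiber/mitochondria densities and crossing
# densities for the spherically symmetric centrosome-organized cell.

# --- end-to-end distance distribution -------------------------------------

# Dimensionless radial distribution g(eta; kappa) of the relative stored
# length eta = 1 - r/rho for a semiflexible (weakly bending) chain of
# contour length rho and stiffness kappa = Lp/rho. Derived from the Laplace
# transform u/sinh(u) of the stored-length distribution; two equivalent
# resummations are used:
#   series  : g = 2 kappa pi^2 sum_k (-1)^(k+1) k^2 exp(-kappa pi^2 k^2 eta)
#   Hermite : g = (pi kappa)^(-1/2) eta^(-3/2) *
#               sum_m [ (2m+1)^2/(2 kappa eta) - 1 ] exp(-(2m+1)^2/(4 kappa eta))
# The series converges quickly away from full extension and is used for
# eta >= 0.1 (r <= 0.9 rho); the Hermite-polynomial form converges quickly
# near full extension and is used for eta < 0.1. (For very stiff chains the
# series is also used below eta = 0.1 once kappa*eta is large enough that
# both branches have decayed to zero, where the Hermite sum would need an
# impractical number of terms to represent 0.)
g_semiflex <- function(eta, kappa, terms = 200L) {
  n <- max(length(eta), length(kappa))
  eta <- rep_len(eta, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  inside <- eta > 0 & eta <= 1
  if (!any(inside)) return(out)
  e <- eta[inside]
  kap <- kappa[inside]
  val <- numeric(length(e))
  hermite <- e < 0.1 & kap * e < 25
  if (any(hermite)) {
    x <- kap[hermite] * e[hermite]
    s <- numeric(sum(hermite))
    for (m in 0:terms) {
      z2 <- (2 * m + 1)^2 / (4 * x)
      term <- (2 * z2 - 1) * exp(-z2)
      s <- s + term
      if (all(abs(term) < 1e-14 * pmax(abs(s), 1e-300))) break
    }
    val[hermite] <- s / (sqrt(pi * kap[hermite]) * e[hermite]^1.5)
  }
  if (any(!hermite)) {
    e2 <- e[!hermite]
    k2 <- kap[!hermite]
    s <- numeric(length(e2))
    k <- 1
    repeat {
      term <- (-1)^(k + 1) * k^2 * exp(-k2 * pi^2 * k^2 * e2)
      s <- s + term
      if (all(abs(term) < 1e-14 * pmax(abs(s), 1e-300))) break
      k <- k + 1
      if (k > terms) {
        if (max(abs(term)) > 1e-8 * max(abs(s), 1e-12))
          warning("end-to-end series not fully converged at the term cap")
        break
      }
    }
    val[!hermite] <- 2 * k2 * pi^2 * s
  }
  out[inside] <- pmax(val, 0)
  out
}

# Normalization Z(kappa) = int_0^1 g(eta; kappa) d eta, a universal function
# of the stiffness only. Evaluated by piecewise adaptive quadrature on
# intervals that resolve the O(1/(6 kappa)) peak near full extension, and
# cached as a spline in log10(kappa).
.wlc_cache <- new.env(parent = emptyenv())

z_semiflex_exact <- function(kappa) {
  scale <- 1 / (6 * kappa)
  cuts <- unique(pmin(1, c(0, scale * 5^(0:12), 1)))
  cuts <- cuts[c(TRUE, diff(cuts) > 1e-15)]
  tot <- 0
  for (i in seq_len(length(cuts) - 1)) {
    tot <- tot + integrate(g_semiflex, cuts[i], cuts[i + 1], kappa = kappa,
                           rel.tol = 1e-9, abs.tol = 1e-12,
                           stop.on.error = FALSE)$value
  }
  tot
}

z_semiflex <- function(kappa) {
  if (is.null(.wlc_cache$zfun)) {
    lk <- seq(-2, 7, length.out = 360)
    zv <- vapply(10^lk, z_semiflex_exact, numeric(1))
    .wlc_cache$zfun <- splinefun(lk, zv, method = "natural")
    .wlc_cache$range <- range(lk)
  }
  lk <- log10(kappa)
  out <- .wlc_cache$zfun(pmin(pmax(lk, .wlc_cache$range[1]),
                              .wlc_cache$range[2]))
  oob <- which(lk < .wlc_cache$range[1] | lk > .wlc_cache$range[2])
  if (length(oob) > 0)
    out[oob] <- vapply(kappa[oob], z_semiflex_exact, numeric(1))
  out
}

#' End-to-end distance distribution of a semiflexible chain
#'
#' Probability density `P(r, rho)` of the distance `r` between the grafted
#' end of a fiber and the point at contour length `rho`, for persistence
#' length `Lp`. The weakly bending two-branch representation is used: an
#' exponential series for `0.9 rho >= r` and its Hermite-polynomial
#' resummation for larger distances; both are resummations of the same
#' stored-length distribution and join continuously. The density is
#' normalized numerically so that it integrates to one on `[0, rho]`; the
#' approximation is quantitatively reliable for `rho / Lp` up to about one
#' (semiflexible and stiff fibers).
#'
#' @param r end-to-end distance(s) (um); the density vanishes beyond `rho`.
#' @param rho contour length of the fiber section (um), positive.
#' @param Lp persistence length (um), positive.
#' @param normalize divide by the numerical normalization constant
#'   (default); `FALSE` returns the raw two-branch evaluation.
#' @return density values (1/um), same length as `r`.
#' @examples
#' integrate(end_to_end_pdf, 0, 16, rho = 16, Lp = 32)$value  # ~1
#' @export
end_to_end_pdf <- function(r, rho, Lp, normalize = TRUE) {
  if (rho <= 0) stop("contour length rho must be positive", call. = FALSE)
  if (Lp <= 0) stop("persistence length Lp must be positive", call. = FALSE)
  kappa <- Lp / rho
  eta <- 1 - r / rho
  dens <- g_semiflex(eta, kappa) / rho
  dens[r < 0 | r > rho] <- 0
  if (normalize) dens <- dens / z_semiflex(kappa)
  dens
}

# --- occupancy ------------------------------------------------------------

#' Mitochondrial occupancy along a fiber
#'
#' Steady-state coverage fraction `eps(rho)` of the fiber contour by
#' mitochondria, from the zero-flux condition of drift-diffusion transport:
#' `psi * eps - d eps / d rho = 0` on `[l1, l2]`, zero outside, with the
#' integration constant fixed by `n_fibers * int eps = M`. For `psi = 0`
#' the profile is uniform; otherwise it is exponential in the drift
#' direction.
#'
#' The occupancy is a coverage fraction, so values above one mean the
#' requested mass exceeds the carrying capacity of the cytoskeleton. Under
#' the strongest biases considered by the model the normalized profile can
#' marginally exceed one at the domain edge; by default this is reported as
#' a warning ("overloaded cytoskeleton") so that those regimes remain
#' computable, `capacity = "error"` turns it into a hard failure, and the
#' profile is never clipped (clipping would break mass conservation).
#'
#' @param rho contour position(s) (um).
#' @param cfg a [mito_config()] supplying `M`, `n_fibers`, `l1`, `l2`.
#' @param psi drift-to-diffusion ratio (1/um); defaults to `cfg$psi`.
#' @param capacity what to do when `max(eps) > 1`: warn (default), error,
#'   or ignore.
#' @return occupancy values in `[0, max(eps)]`, same length as `rho`.
#' @examples
#' occupancy(8, mito_config())  # 1000 / (200 * 14.5) = 0.34483
#' @export
occupancy <- function(rho, cfg = mito_config(), psi = cfg$psi,
                      capacity = c("warn", "error", "ignore")) {
  capacity <- match.arg(capacity)
  C <- occupancy_norm(cfg, psi)
  emax <- C * exp(psi * if (psi >= 0) cfg$l2 else cfg$l1)
  if (emax > 1 + 1e-12) {
    msg <- sprintf(
      "overloaded cytoskeleton: occupancy reaches %.4f > 1 (M = %g um on %d fibers)",
      emax, cfg$M, cfg$n_fibers)
    if (capacity == "error") stop(msg, call. = FALSE)
    if (capacity == "warn") warning(msg, call. = FALSE)
  }
  eps <- C * exp(psi * rho)
  eps[rho < cfg$l1 | rho > cfg$l2] <- 0
  eps
}

occupancy_norm <- function(cfg, psi) {
  if (abs(psi) < 1e-12) {
    cfg$M / (cfg$n_fibers * (cfg$l2 - cfg$l1))
  } else {
    cfg$M * psi / (cfg$n_fibers * (exp(psi * cfg$l2) - exp(psi * cfg$l1)))
  }
}

# --- radial densities -----------------------------------------------------

# piecewise quadrature of fn(eta) over [0, eta_max] resolving the peak of
# the stored-length distribution at scale ~ r/(6 Lp)
integrate_eta <- function(fn, eta_max, scale) {
  cuts <- unique(pmin(eta_max, c(0, scale * 5^(0:14), eta_max)))
  cuts <- cuts[c(TRUE, diff(cuts) > 1e-15)]
  tot <- 0
  for (i in seq_len(length(cuts) - 1)) {
    tot <- tot + integrate(fn, cuts[i], cuts[i + 1],
                           rel.tol = 1e-8, abs.tol = 1e-12,
                           stop.on.error = FALSE)$value
  }
  tot
}

#' Radial density of fiber contour weighted by occupancy powers
#'
#' `Q_j(r) = n_fibers * int_r^L P(r, rho) eps(rho)^j d rho`: the density,
#' on the spherical shell at radius `r`, of microtubule contour occupied by
#' `j` superimposed mitochondria (`j = 0` is the bare cytoskeleton density).
#' Fiber sections with `rho < r` cannot reach the shell and do not
#' contribute; steric constraints limit `j < 3`. The integration runs in the
#' relative stored length `eta = 1 - r/rho`, which resolves the sharply
#' peaked stiff-fiber contribution near `rho = r`.
#'
#' @param r shell radius (um); vectorized.
#' @param j occupancy power, 0, 1 or 2.
#' @param cfg a [mito_config()].
#' @param psi,Lp overrides of the configuration values.
#' @param capacity passed to [occupancy()].
#' @return density values (um of contour per um of radius for `j = 0`;
#'   occupied contour per um of radius otherwise).
#' @examples
#' radial_density(8, 1, mito_config())
#' @export
radial_density <- function(r, j, cfg = mito_config(), psi = cfg$psi,
                           Lp = cfg$Lp, capacity = "warn") {
  if (!j %in% 0:2)
    stop("occupancy power j must be 0, 1 or 2 (steric constraints limit j < 3)",
         call. = FALSE)
  eps_fun <- if (j == 0) {
    function(rho) rep(1, length(rho))
  } else {
    # capacity is checked once here, silently reused inside the integrand
    occupancy(cfg$l1, cfg, psi, capacity = capacity)
    function(rho) suppressWarnings(occupancy(rho, cfg, psi, "ignore"))^j
  }
  rho_hi <- if (j == 0) cfg$L else cfg$l2
  rho_lo_extra <- if (j == 0) 0 else cfg$l1
  vapply(r, function(ri) {
    if (ri <= 0 || ri >= rho_hi) return(0)
    eta_max <- 1 - ri / rho_hi
    eta_min <- if (ri < rho_lo_extra) 1 - ri / rho_lo_extra else 0
    if (eta_min >= eta_max) return(0)
    fn <- function(eta) {
      rho <- ri / (1 - eta)
      kap <- Lp / rho
      g_semiflex(eta, kap) / (z_semiflex(kap) * (1 - eta)) * eps_fun(rho)
    }
    scale <- max(ri, 1e-3) / (6 * Lp)
    # shift the lower pieces when the occupancy window imposes eta_min > 0
    val <- integrate_eta(function(eta) {
      eta2 <- eta + eta_min
      keep <- eta2 < eta_max
      out <- numeric(length(eta))
      if (any(keep)) out[keep] <- fn(eta2[keep])
      out
    }, eta_max - eta_min, scale)
    cfg$n_fibers * val
  }, numeric(1))
}

# --- crossing densities ---------------------------------------------------

#' Spherical-cap geometric factor
#'
#' `A(xi, r) = 2 pi xi * (xi - (xi^2 - sigma^2 + r^2) / (2 r))`: the area of
#' the spherical shell of radius `xi` (centered at the cell center) that
#' falls inside a ball of radius `sigma` centered at distance `r`. Defined
#' for `|xi - r| <= sigma`; integrating it over `xi` recovers the ball
#' volume `4/3 pi sigma^3` (when the ball clears the centrosome).
#'
#' @param xi shell radius (um).
#' @param r center distance (um), positive.
#' @param sigma ball radius (um).
#' @return area (um^2), non-negative on its domain.
#' @export
cap_area <- function(xi, r, sigma) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (any(abs(xi - r) > sigma + 1e-12))
    stop("cap_area is defined for |xi - r| <= sigma", call. = FALSE)
  pmax(0, 2 * pi * xi * (xi - (xi^2 - sigma^2 + r^2) / (2 * r)))
}

#' Density of occupied two-fiber crossings
#'
#' `S_jj(r) = Q_j(r) * int Q_j(xi) / (4 pi xi^2) * A(xi, r) d xi` over
#' `xi` in `[r - sigma, r + sigma]` (clamped to `(0, L]`): the mitochondrial
#' (or fiber, for `j = 0`) mass inside a proximity ball of radius `sigma`,
#' multiplied by the local concentration. Where `Q_j` is locally flat this
#' reduces to the bulk asymptotic [crossing_density_asymptotic()].
#'
#' @param r shell radius (um); vectorized.
#' @param Q a function returning `Q_j(xi)` (e.g. a spline from
#'   [density_profiles()]), zero outside `(0, L]`.
#' @param sigma proximity threshold (um).
#' @param L fiber length (um), outer support of `Q`.
#' @return crossing density per um of radius.
#' @export
crossing_density <- function(r, Q, sigma, L) {
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    lo <- max(ri - sigma, 1e-9)
    hi <- min(ri + sigma, L)
    if (hi <= lo) return(0)
    qi <- Q(ri)
    if (qi <= 0) return(0)
    integrand <- function(xi) {
      # spherical shells fully inside the proximity ball (xi <= sigma - r,
      # possible near the centrosome) contribute their whole area
      a <- ifelse(xi <= sigma - ri, 4 * pi * xi^2,
                  pmax(0, 2 * pi * xi * (xi - (xi^2 - sigma^2 + ri^2) / (2 * ri))))
      Q(xi) / (4 * pi * xi^2) * a
    }
    qi * integrate(integrand, lo, hi, rel.tol = 1e-8,
                   stop.on.error = FALSE)$value
  }, numeric(1))
}

#' @rdname crossing_density
#' @param Q0 density value(s) `Q_j(r)` at the evaluation radius.
#' @details `crossing_density_asymptotic()` returns the bulk form
#'   `sigma^3 Q^2 / (3 r^2)`, valid where the density varies little across
#'   the proximity ball (`r` a few `sigma` away from the centrosome).
#' @export
crossing_density_asymptotic <- function(r, Q0, sigma) {
  sigma^3 * Q0^2 / (3 * r^2)
}

# --- bundled radial profiles ---------------------------------------------

#' Radial density profiles of the reference model
#'
#' Evaluates `Q_0`, `Q_1`, `Q_2` and the crossing densities `S_00`, `S_11`
#' on the shell grid of width `dr`, and returns them together with spline
#' interpolants (zero outside `(0, L]`) for downstream use by the rate
#' fields and the graph dynamics.
#'
#' @param cfg a [mito_config()].
#' @param psi,Lp overrides of the configuration values.
#' @param capacity passed to [occupancy()].
#' @return an object of class `density_profiles`: list with `table` (a
#'   `data.frame` of `r, Q0, Q1, Q2, S00, S11`), interpolants `Q0_fun`,
#'   `Q1_fun`, `Q2_fun`, `S11_fun`, and the generating parameters.
#' @export
density_profiles <- function(cfg = mito_config(), psi = cfg$psi,
                             Lp = cfg$Lp, capacity = "warn") {
  r <- seq(cfg$dr / 2, cfg$L - cfg$dr / 2 + 1e-12, by = cfg$dr)
  # trigger the capacity check once, then evaluate silently
  if (psi != 0) occupancy(cfg$l1, cfg, psi, capacity = capacity)
  Q0 <- radial_density(r, 0, cfg, psi = psi, Lp = Lp, capacity = "ignore")
  Q1 <- radial_density(r, 1, cfg, psi = psi, Lp = Lp, capacity = "ignore")
  Q2 <- radial_density(r, 2, cfg, psi = psi, Lp = Lp, capacity = "ignore")
  mk_fun <- function(vals) {
    sp <- splinefun(r, vals, method = "monoH.FC")
    function(x) {
      out <- numeric(length(x))
      ok <- x > 0 & x <= cfg$L
      out[ok] <- pmax(0, sp(x[ok]))
      out
    }
  }
  Q0_fun <- mk_fun(Q0)
  Q1_fun <- mk_fun(Q1)
  Q2_fun <- mk_fun(Q2)
  S00 <- crossing_density(r, Q0_fun, cfg$sigma, cfg$L)
  S11 <- crossing_density(r, Q1_fun, cfg$sigma, cfg$L)
  S11_fun <- mk_fun(S11)
  structure(list(table = data.frame(r = r, Q0 = Q0, Q1 = Q1, Q2 = Q2,
                                    S00 = S00, S11 = S11),
                 Q0_fun = Q0_fun, Q1_fun = Q1_fun, Q2_fun = Q2_fun,
                 S11_fun = S11_fun,
                 cfg = cfg, psi = psi, Lp = Lp),
            class = "density_profiles")
}

#' @export
print.density_profiles <- function(x, ...) {
  cat(sprintf("radial density profiles: %d shells of %g um (Lp = %g um, psi = %g /um)\n",
              nrow(x$table), diff(x$table$r[1:2]), x$Lp, x$psi))
  cat(sprintf("  integral of Q1 = %.2f um (M = %g um)\n",
              sum(x$table$Q1) * diff(x$table$r[1:2]), x$cfg$M))
  invisible(x)
}
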