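#' Persistence length of a freely rotating chain
#'
#' For small bond angles the discrete freely rotating chain (FRC) has the
#' worm-like-chain persistence length `Lp = 2 a / theta^2`. The inverse,
#' [bond_angle_for_persistence()], is the primary use: given a target
#' stiffness, it returns the bond angle with which chains are generated.
#'
#' @param a bond length (um), positive.
#' @param theta bond angle (radians), in (0, pi).
#' @param Lp persistence length (um), positive.
#' @return a length (um) or an angle (radians).
#' @examples
#' persistence_from_bond(0.02, 0.035355)           # ~32 um
#' bond_angle_for_persistence(0.02, 32)            # ~0.0353553
#' @export
persistence_from_bond <- function(a, theta) {
  if (!is.numeric(a) || any(a <= 0))
    stop("bond length a must be positive", call. = FALSE)
  if (!is.numeric(theta) || any(theta <= 0) || any(theta >= pi))
    stop("bond angle theta must lie in (0, pi)", call. = FALSE)
  2 * a / theta^2
}

#' @rdname persistence_from_bond
#' @export
bond_angle_for_persistence <- function(a, Lp) {
  if (!is.numeric(a) || any(a <= 0))
    stop("bond length a must be positive", call. = FALSE)
  if (!is.numeric(Lp) || any(Lp <= 0))
    stop("persistence length Lp must be positive", call. = FALSE)
  sqrt(2 * a / Lp)
}

#' Generate one freely rotating chain
#'
#' Builds a discrete polymer of `floor(L / a)` bonds of length `a`, grafted
#' at the origin with its first bond along `graft`. Every subsequent bond is
#' tilted by the fixed polar angle `theta` relative to its predecessor, with
#' torsion drawn uniformly on `[0, 2 pi)`. `theta = 0` yields a rigid rod.
#'
#' @param L contour length (um), `>= a`.
#' @param a bond length (um).
#' @param theta bond angle (radians), in `[0, pi)`.
#' @param graft unit 3-vector of the grafted-end direction.
#' @param seed optional integer; when given, the chain is reproducible.
#' @return an object of class `frc_chain`: list with `vertices`
#'   (`(n_bonds + 1) x 3` matrix, um, first row the origin), `a`, `theta`,
#'   and the realized contour length `L` (`= floor(L/a) * a`).
#' @examples
#' ch <- frc_chain(1, 0.02, 0.05, seed = 7)
#' nrow(ch$vertices)  # 51 vertices, 50 bonds
#' @export
frc_chain <- function(L, a, theta, graft = c(0, 0, 1), seed = NULL) {
  if (L < a) stop("contour length L must be >= bond length a", call. = FALSE)
  if (theta < 0 || theta >= pi) stop("theta must lie in [0, pi)", call. = FALSE)
  if (length(graft) != 3 || sqrt(sum(graft^2)) < 1e-12)
    stop("graft direction must be a non-zero 3-vector", call. = FALSE)
  n_bonds <- floor(L / a)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- frc_chain_cpp(as.integer(n_bonds), a, theta, as.numeric(graft))
  structure(list(vertices = v, a = a, theta = theta, L = n_bonds * a),
            class = "frc_chain")
}

#' @export
print.frc_chain <- function(x, ...) {
  cat(sprintf("FRC chain: %d bonds of %g um (L = %g um), bond angle %g rad\n",
              nrow(x$vertices) - 1L, x$a, x$L, x$theta))
  invisible(x)
}

# uniform direction on the unit sphere
runif_sphere <- function(n = 1) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Generate the centrosome-grafted microtubule array
#'
#' All fibers share the same contour length, bond length and stiffness; the
#' grafted-end directions are independent and uniform on the sphere. Each
#' chain draws from its own RNG substream derived from the master seed, so
#' increasing `n_fibers` extends the array without reshuffling earlier
#' chains. Chains are not confined by the cell boundary.
#'
#' @param cfg a [mito_config()]; `n_fibers`, `L`, `Lp`, `a`, `sigma` and
#'   `seed` are used (overridable via `...`).
#' @param ... named overrides of configuration fields.
#' @return an object of class `cytoskeleton`: list with `vertices` (all
#'   chains stacked), `offsets` (0-based row offsets per chain, length
#'   `n_fibers + 1`), `graft` (matrix of graft directions), and the chain
#'   parameters.
#' @examples
#' cs <- cytoskeleton(mito_config(n_fibers = 5, L = 2), seed = 1)
#' length(cs$offsets)  # 6
#' @export
cytoskeleton <- function(cfg = mito_config(), ...) {
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if ("L" %in% names(over) && !any(c("l1", "l2") %in% names(over))) {
    # geometry-only override: keep the occupancy window proportional
    cfg$l1 <- cfg$L / 32
    cfg$l2 <- 0.9375 * cfg$L
  }
  validate_config(cfg)
  theta <- bond_angle_for_persistence(cfg$a, cfg$Lp)
  n_bonds <- floor(cfg$L / cfg$a)
  nv <- n_bonds + 1L
  verts <- matrix(0, nrow = nv * cfg$n_fibers, ncol = 3)
  graft <- matrix(0, nrow = cfg$n_fibers, ncol = 3)
  offsets <- as.integer(seq(0L, by = nv, length.out = cfg$n_fibers + 1L))
  for (i in seq_len(cfg$n_fibers)) {
    set.seed(child_seed(cfg$seed, i))
    g <- runif_sphere(1)[1, ]
    graft[i, ] <- g
    verts[(offsets[i] + 1L):offsets[i + 1L], ] <-
      frc_chain_cpp(n_bonds, cfg$a, theta, g)
  }
  structure(list(vertices = verts, offsets = offsets, graft = graft,
                 n_fibers = cfg$n_fibers, L = n_bonds * cfg$a, a = cfg$a,
                 theta = theta, Lp = cfg$Lp, sigma = cfg$sigma,
                 seed = cfg$seed),
            class = "cytoskeleton")
}

#' @export
print.cytoskeleton <- function(x, ...) {
  cat(sprintf("cytoskeleton: %d fibers, L = %g um, Lp = %g um (theta = %.5f rad), seed %d\n",
              x$n_fibers, x$L, x$Lp, x$theta, x$seed))
  invisible(x)
}

# vertices of chain i as a matrix
chain_vertices <- function(cs, i) {
  cs$vertices[(cs$offsets[i] + 1L):cs$offsets[i + 1L], , drop = FALSE]
}

#' Mean squared end-to-end distance of a worm-like chain
#'
#' Closed form `<R^2> = 2 Lp L - 2 Lp^2 (1 - exp(-L / Lp))`; the continuum
#' limit against which generated chain ensembles are checked.
#'
#' @param L contour length (um).
#' @param Lp persistence length (um).
#' @return mean squared end-to-end distance (um^2).
#' @examples
#' wlc_mean_sq_ee(16, 32)  # ~218.2
#' @export
wlc_mean_sq_ee <- function(L, Lp) {
  2 * Lp * L - 2 * Lp^2 * (1 - exp(-L / Lp))
}

#' Estimate the persistence length of a fiber array
#'
#' Fits the exponential decay of the mean tangent-tangent correlation versus
#' contour separation, `<t(s) . t(s + ds)> = exp(-ds / Lp)`. Lags are used up
#' to the point where the mean correlation first drops below `min_corr` (or
#' `max_lag` bonds, whichever is smaller); nearly straight arrays whose
#' correlation never decays are returned with `flagged = TRUE` rather than
#' as an error.
#'
#' @param cs a [cytoskeleton()] (or a single `frc_chain`).
#' @param max_lag maximum contour separation used in the fit, in bonds.
#' @param min_corr correlation level at which the fit window is cut.
#' @return list with `Lp` (um), `flagged`, and the correlation table
#'   (`lag_um`, `correlation`).
#' @export
estimate_persistence <- function(cs, max_lag = NULL, min_corr = 0.2) {
  if (inherits(cs, "frc_chain"))
    cs <- list(vertices = cs$vertices,
               offsets = c(0L, nrow(cs$vertices)), a = cs$a)
  n_bonds <- diff(cs$offsets) - 1L
  if (any(n_bonds < 2L))
    stop("persistence estimation needs at least 2 bonds per chain", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(max(n_bonds) - 1L, 500L)
  corr <- tangent_correlation_cpp(cs$vertices, cs$offsets, as.integer(max_lag))
  lag <- seq_along(corr) - 1L
  tab <- data.frame(lag_um = lag * cs$a, correlation = corr)
  # initial contiguous window where the correlation is still informative
  cut <- which(corr <= min_corr | !is.finite(corr))[1]
  hi <- if (is.na(cut)) length(corr) else cut - 1L
  use <- if (hi >= 2L) 2:hi else integer(0)  # drop lag 0 (trivially 1)
  if (length(use) < 3) {
    return(list(Lp = NA_real_, flagged = TRUE, correlation = tab))
  }
  fit <- lm(log(corr[use]) ~ 0 + I(lag[use] * cs$a))
  slope <- coef(fit)[[1]]
  if (!is.finite(slope) || slope >= 0)
    return(list(Lp = Inf, flagged = TRUE, correlation = tab))
  Lp <- -1 / slope
  total_L <- max(n_bonds) * cs$a
  flagged <- !is.finite(Lp) || Lp > 50 * total_L
  list(Lp = Lp, flagged = flagged, correlation = tab)
}
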