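#' Simulation configuration
#'
#' Bundles all scalar parameters of the model cell. Defaults are the
#' reference configuration: a spherically symmetric cell of radius equal to
#' the microtubule contour length `L = 16` um, `n_fibers = 200` microtubules
#' of persistence length `Lp = 32` um built from 20-nm bonds, a proximity
#' threshold and mitochondrial edge length of 0.2 um (the typical organelle
#' diameter), a cumulative reticulum length `M = 1000` um (1 mm), uniform
#' occupancy (`psi = 0`) between contour positions `l1 = 0.5` and
#' `l2 = 15` um, and a radial discretization `dr = 0.01 * L`.
#'
#' @param n_fibers number of microtubules grafted at the centrosome.
#' @param L microtubule contour length (um); also the cell radius.
#' @param Lp microtubule persistence length (um).
#' @param a bond length of the discrete chain representation (um).
#' @param sigma proximity threshold below which two fibers can host a
#'   branching or linear fusion event (um).
#' @param edge_length length of one mitochondrial graph edge (um).
#' @param M total mitochondrial length in the cell (um).
#' @param l1,l2 contour interval on which mitochondria are positioned (um);
#'   the defaults scale with `L` and equal 0.5 and 15 um at the reference
#'   cell radius.
#' @param psi drift-to-diffusion ratio of motor-driven mitochondrial
#'   transport along a fiber (1/um); positive values push mass towards the
#'   fiber's free (peripheral) end.
#' @param gamma global fusion-to-fission propensity ratio of the
#'   fission/fusion machinery.
#' @param dr width of the radial shells (um).
#' @param rate_scale scale constant of the cytoskeleton-dependent rate
#'   fields, see [rate_fields()].
#' @param weight_q2 relative weight of same-fiber pairs versus crossings in
#'   the tip-to-tip rate field.
#' @param q1_exponent exponent of the `1/Q1^p` normalization of the rate
#'   fields (default 0).
#' @param seed master seed; every stochastic component derives its stream
#'   from it.
#' @param runs number of independent stochastic runs per ensemble.
#'
#' @return an object of class `mito_config` (a validated named list).
#' @examples
#' cfg <- mito_config()
#' cfg$M / (cfg$n_fibers * (cfg$l2 - cfg$l1))  # uniform occupancy level
#' @export
mito_config <- function(n_fibers = 200L, L = 16, Lp = 32, a = 0.02,
                        sigma = 0.2, edge_length = 0.2, M = 1000,
                        l1 = L / 32, l2 = 0.9375 * L, psi = 0, gamma = 0.1,
                        dr = 0.01 * L, rate_scale = 0.25, weight_q2 = 1,
                        q1_exponent = 0, seed = 1L, runs = 1000L) {
  cfg <- list(n_fibers = as.integer(n_fibers), L = L, Lp = Lp, a = a,
              sigma = sigma, edge_length = edge_length, M = M,
              l1 = l1, l2 = l2, psi = psi, gamma = gamma, dr = dr,
              rate_scale = rate_scale, weight_q2 = weight_q2,
              q1_exponent = q1_exponent,
              seed = as.integer(seed), runs = as.integer(runs))
  validate_config(cfg)
  class(cfg) <- "mito_config"
  cfg
}

validate_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num <- c("L", "Lp", "a", "sigma", "edge_length", "M", "l1", "l2",
           "psi", "gamma", "dr", "rate_scale", "weight_q2", "q1_exponent")
  for (f in num)
    stop_if(!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]),
            sprintf("configuration field '%s' must be a single number", f))
  stop_if(cfg$n_fibers < 1, "n_fibers must be >= 1")
  stop_if(cfg$L <= 0 || cfg$a <= 0 || cfg$Lp <= 0,
          "lengths L, a and Lp must be positive")
  stop_if(cfg$L < cfg$a, "contour length L must be at least one bond length")
  stop_if(cfg$sigma <= 0, "proximity threshold sigma must be positive")
  stop_if(cfg$M <= 0, "total mitochondrial length M must be positive")
  stop_if(cfg$edge_length <= 0, "edge_length must be positive")
  stop_if(cfg$dr <= 0, "radial discretization dr must be positive")
  stop_if(cfg$l1 < 0 || cfg$l1 >= cfg$l2,
          "occupancy interval requires 0 <= l1 < l2")
  stop_if(cfg$l2 > cfg$L, "occupancy bound l2 must not exceed the fiber length L")
  stop_if(cfg$gamma < 0, "gamma must be non-negative")
  stop_if(cfg$runs < 1, "runs must be >= 1")
  invisible(cfg)
}

#' @export
print.mito_config <- function(x, ...) {
  cat("mitoreticulum configuration\n")
  cat(sprintf("  cytoskeleton : %d fibers, L = %g um, Lp = %g um, a = %g um\n",
              x$n_fibers, x$L, x$Lp, x$a))
  cat(sprintf("  mitochondria : M = %g um on [%g, %g] um, edge = %g um, sigma = %g um\n",
              x$M, x$l1, x$l2, x$edge_length, x$sigma))
  cat(sprintf("  dynamics     : gamma = %g, psi = %g /um, dr = %g um\n",
              x$gamma, x$psi, x$dr))
  cat(sprintf("  stochastics  : seed = %d, runs = %d\n", x$seed, x$runs))
  invisible(x)
}

#' Read / write a configuration as JSON
#'
#' The resolved configuration is written beside every run's outputs so that
#' results are reproducible from `(config, seed)` alone. Unknown keys in the
#' file are rejected rather than silently dropped.
#'
#' @param path file path.
#' @param cfg a [mito_config()] object.
#' @return `read_config()` returns a `mito_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(mito_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(mito_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mito_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# derive a child seed (< 2^31) from a master seed and a stream index
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(index) + 7) %%
               2147483629)
}
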