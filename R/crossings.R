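#' Detect fiber crossings
#'
#' Scans all unordered chain pairs of an array for regions where the two
#' polylines approach closer than `sigma`. A contiguous run of sub-threshold
#' bond pairs counts as a single crossing, located at its minimum-distance
#' point; this avoids inflating the crossing statistics when two fibers run
#' alongside each other for several bonds. Candidate pairs are pruned with a
#' spatial hash grid; the result is identical to the exhaustive all-pairs
#' scan (`use_grid = FALSE`), which is retained for verification.
#'
#' @param cs a [cytoskeleton()].
#' @param sigma proximity threshold (um); defaults to the array's value.
#' @param use_grid use the hash grid (default) or the all-pairs scan.
#' @return a `data.frame` of class `crossing_set` with columns `chain_i`,
#'   `chain_j` (`i < j`), `rho_i`, `rho_j` (contour positions, um), `r`
#'   (radius of the crossing midpoint, um) and `min_dist` (um).
#' @export
detect_crossings <- function(cs, sigma = cs$sigma, use_grid = TRUE) {
  stopifnot(inherits(cs, "cytoskeleton"))
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  out <- detect_crossings_cpp(cs$vertices, cs$offsets, sigma, cs$a, use_grid)
  out <- out[order(out$chain_i, out$chain_j, out$rho_i), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  attr(out, "L") <- cs$L
  class(out) <- c("crossing_set", "data.frame")
  out
}

#' Radial histogram of fiber contour or crossings
#'
#' Bins a cytoskeleton's contour length (per bond midpoint) or a crossing
#' set's entries into spherical shells of width `dr` and divides by `dr`,
#' giving a density per unit radius. Contour histograms integrate back to
#' the total fiber length `n_fibers * L`; crossing histograms to the total
#' number of crossings (within the binned range).
#'
#' @param x a `cytoskeleton` or a `crossing_set`.
#' @param dr shell width (um).
#' @param r_max outer radius of the binned range (um); defaults to the
#'   fiber contour length.
#' @return a `data.frame` with shell centers `r` and `density` (um of
#'   contour per um of radius, or crossings per um of radius).
#' @export
radial_histogram <- function(x, dr, r_max = NULL) UseMethod("radial_histogram")

#' @export
radial_histogram.cytoskeleton <- function(x, dr, r_max = NULL) {
  if (dr <= 0) stop("dr must be positive", call. = FALSE)
  if (is.null(r_max)) r_max <- x$L
  nbins <- as.integer(ceiling(r_max / dr - 1e-9))
  # exact arc length of every bond inside every shell; a bond-count
  # histogram cannot resolve sub-bond radial contraction, which biases the
  # inner shells of stiff centrosome-grafted arrays coherently
  bins <- arc_length_profile_cpp(x$vertices, x$offsets, dr, nbins)
  data.frame(r = (seq_len(nbins) - 0.5) * dr, density = bins / dr)
}

#' @export
radial_histogram.crossing_set <- function(x, dr, r_max = NULL) {
  if (dr <= 0) stop("dr must be positive", call. = FALSE)
  if (is.null(r_max)) r_max <- attr(x, "L")
  bin_density(x$r, weight = 1, dr = dr, r_max = r_max)
}

bin_density <- function(r, weight, dr, r_max) {
  nbins <- as.integer(ceiling(r_max / dr - 1e-9))
  idx <- as.integer(floor(r / dr)) + 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nbins], nbins)
  data.frame(r = (seq_len(nbins) - 0.5) * dr, density = counts * weight / dr)
}

#' Contour-pair proximity profile
#'
#' The quantitative Monte Carlo counterpart of the analytic crossing density
#' \eqn{S_{00}(r)}: for every unordered pair of bonds on distinct chains
#' whose midpoints lie within `sigma`, the contour-pair measure `a^2` is
#' credited to the shells of both midpoints. In expectation this equals the
#' double contour integral of the proximity indicator, which is exactly the
#' quantity the mean-field crossing density (mass inside a `sigma`-sphere
#' times local concentration) computes. Discrete crossing-region counts from
#' [detect_crossings()] share the radial shape of this profile but carry a
#' different, geometry-dependent absolute scale.
#'
#' @inheritParams detect_crossings
#' @param dr shell width (um).
#' @param r_max outer radius of the binned range (um).
#' @return a `data.frame` with shell centers `r` and `density` (um^2 of
#'   contour pairs per um of radius).
#' @export
pair_contact_profile <- function(cs, sigma = cs$sigma, dr, r_max = cs$L) {
  stopifnot(inherits(cs, "cytoskeleton"))
  nbins <- as.integer(ceiling(r_max / dr - 1e-9))
  bins <- pair_contact_profile_cpp(cs$vertices, cs$offsets, sigma, cs$a,
                                   dr, nbins)
  data.frame(r = (seq_len(nbins) - 0.5) * dr, density = bins / dr)
}

#' Export a cytoskeleton or crossing set as CSV
#'
#' Chains: one row per vertex (`chain_id`, `vertex_index`, `x`, `y`, `z`,
#' um). Crossings: the columns of the crossing set.
#'
#' @param x a `cytoskeleton` or `crossing_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) UseMethod("export_csv")

#' @export
export_csv.cytoskeleton <- function(x, path) {
  nv <- diff(x$offsets)
  df <- data.frame(chain_id = rep(seq_len(x$n_fibers), nv),
                   vertex_index = sequence(nv) - 1L,
                   x = x$vertices[, 1], y = x$vertices[, 2],
                   z = x$vertices[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
export_csv.crossing_set <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
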