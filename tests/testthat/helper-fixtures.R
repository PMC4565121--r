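# Hand-built fixtures: straight polyline "chains" with exhaustively known
# geometry, assembled into the cytoskeleton container used by the package.

# report every expectation; the documented full-scale validation failures
# must not truncate the rest of the suite
options(testthat.progress.max_fails = Inf)

straight_vertices <- function(from, dir, n_bonds, a) {
  dir <- dir / sqrt(sum(dir^2))
  t(sapply(0:n_bonds, function(k) from + k * a * dir))
}

fixture_array <- function(chain_list, a = 0.02, sigma = 0.2, L = NULL) {
  nv <- vapply(chain_list, nrow, integer(1))
  if (is.null(L)) L <- (max(nv) - 1) * a
  structure(list(vertices = do.call(rbind, chain_list),
                 offsets = as.integer(cumsum(c(0L, nv))),
                 graft = NULL,
                 n_fibers = length(chain_list),
                 L = L, a = a, theta = 0, Lp = Inf, sigma = sigma,
                 seed = 0L),
            class = "cytoskeleton")
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
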