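#' Generate a synthetic two-hemisphere spherical parcellation
#'
#' Places `n_per_hemisphere` parcel centroids quasi-uniformly on the left
#' half (x < 0) of the unit sphere using a Fibonacci lattice, then mirrors
#' them across the x = 0 plane to produce the right hemisphere. The result
#' emulates the spherical (fsaverage-style) coordinates of a bilateral
#' cortical parcellation, which the spatial spin test requires.
#'
#' @param n_per_hemisphere Number of regions per hemisphere (>= 10).
#' @param seed Integer seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @return A tibble with columns `region` (label), `hemi` (`"L"`/`"R"`) and
#'   unit-norm coordinates `x`, `y`, `z`. Left/right regions are exact
#'   mirror pairs.
#' @examples
#' geom <- generate_geometry(20, seed = 1)
#' range(sqrt(geom$x^2 + geom$y^2 + geom$z^2))
#' @export
generate_geometry <- function(n_per_hemisphere, seed = 1L) {
  n <- assert_count(n_per_hemisphere, "n_per_hemisphere", min = 1L)
  if (n < 10L) {
    nv_abort("`n_per_hemisphere` must be at least 10 for a usable parcellation.",
             "nv_degenerate_geometry")
  }
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  # Each hemisphere is inflated to its own full sphere (as spherical
  # cortical-surface registrations are): a Fibonacci lattice covers the left
  # sphere; the right sphere is its mirror image across the x = 0 plane.
  x <- 1 - 2 * i / n                # uniform heights in (-1, 1)
  r <- sqrt(pmax(0, 1 - x^2))
  phi <- 2 * pi * i / golden
  left <- cbind(x = x, y = r * sin(phi), z = r * cos(phi))
  right <- left
  right[, "x"] <- -right[, "x"]
  tibble::tibble(
    region = c(sprintf("L%03d", seq_len(n)), sprintf("R%03d", seq_len(n))),
    hemi = rep(c("L", "R"), each = n),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"])
  )
}

# Internal: coordinate matrix (regions x 3) from a geometry tibble.
geometry_coords <- function(geometry) {
  m <- as.matrix(geometry[, c("x", "y", "z")])
  rownames(m) <- geometry$region
  m
}

# Internal: monomial basis of total degree <= lmax evaluated at unit-sphere
# coordinates. Restricted to the sphere these span the spherical harmonics of
# degree <= lmax, so random combinations are spatially autocorrelated maps.
# `symmetric = TRUE` keeps only even powers of x, yielding maps that are
# identical for mirrored left/right regions.
harmonic_basis <- function(coords, lmax = 4L, symmetric = TRUE) {
  pow <- expand.grid(i = 0:lmax, j = 0:lmax, k = 0:lmax)
  pow <- pow[rowSums(pow) <= lmax, , drop = FALSE]
  if (symmetric) pow <- pow[pow$i %% 2 == 0, , drop = FALSE]
  pow <- pow[order(rowSums(pow)), , drop = FALSE]
  B <- vapply(seq_len(nrow(pow)), function(m) {
    coords[, 1]^pow$i[m] * coords[, 2]^pow$j[m] * coords[, 3]^pow$k[m]
  }, numeric(nrow(coords)))
  # orthonormalize in degree order: monomials are ill-conditioned, and an
  # isotropic coefficient draw needs an orthonormal basis to spread variance
  # across all spherical-harmonic patterns of each degree
  Q <- qr.Q(qr(B))
  attr(Q, "degree") <- rowSums(pow)
  Q
}

# Internal: draw `k` smooth maps (regions x k), each standardized to mean 0,
# sd 1 across regions. Coefficients shrink with polynomial degree so low
# spatial frequencies dominate. Uses the caller's RNG stream.
random_smooth_maps <- function(coords, k, lmax = 4L, symmetric = TRUE) {
  B <- harmonic_basis(coords, lmax = lmax, symmetric = symmetric)
  degw <- 1 / (1 + attr(B, "degree"))
  coef <- matrix(rnorm(ncol(B) * k), ncol(B), k) * degw
  coef[1, ] <- 0                      # drop the constant term
  M <- B %*% coef
  scale(M)[, , drop = FALSE]
}

# Internal: orthogonalized standardized smooth factor maps (regions x k).
smooth_factor_maps <- function(coords, k, lmax = 4L) {
  raw <- random_smooth_maps(coords, k + 2L, lmax = lmax, symmetric = TRUE)
  q <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
  scale(q)[, , drop = FALSE]
}
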