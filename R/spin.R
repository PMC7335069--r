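# Spherical rotation ("spin") null model for comparing region-level cortical
# maps while preserving spatial contiguity and hemispheric symmetry.

# Internal: rotation matrices about the coordinate axes.
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# Internal: greedy matching of rotated to original regions. Processes rotated
# regions in descending order of their mean Euclidean distance to all
# original regions, assigning each to the nearest not-yet-taken original
# region (ties broken by original region order). Returns an integer vector
# `assign` with assign[j] = index of the original region matched to rotated
# region j.
greedy_match <- function(rotated, original) {
  n <- nrow(original)
  D <- outer(rowSums(rotated^2), rowSums(original^2), `+`) -
    2 * tcrossprod(rotated, original)
  D[D < 0] <- 0
  D <- sqrt(D)
  ord <- order(rowMeans(D), decreasing = TRUE)
  taken <- rep(FALSE, n)
  out <- integer(n)
  for (j in ord) {
    d <- D[j, ]
    d[taken] <- Inf
    pick <- which.min(d)          # first index on ties = label-order tie rule
    out[j] <- pick
    taken[pick] <- TRUE
  }
  out
}

# Internal: one spin. `sides` is a list of original-index vectors per
# hemisphere; the right hemisphere uses angles (a, -b, -c) so mirror
# symmetry is preserved. Returns the permutation vector perm with
# perm[i] = source region index whose value region i receives.
spin_once <- function(coords, sides, a) {
  perm <- integer(nrow(coords))
  for (h in names(sides)) {
    idx <- sides[[h]]
    ang <- if (h == "R") c(a[1], -a[2], -a[3]) else a
    R <- rot_x(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])
    rotated <- coords[idx, , drop = FALSE] %*% t(R)
    assign_to <- greedy_match(rotated, coords[idx, , drop = FALSE])
    # original region assign_to[j] receives the value of rotated region j
    perm[idx[assign_to]] <- idx
  }
  perm
}

#' Independently oriented smooth calibration maps
#'
#' Draws `k` regional maps, each a randomly oriented copy of one fixed
#' smooth template (rotation angles drawn as in [generate_spins()], with the
#' mirror-conjugate rotation applied to the right hemisphere, so maps are
#' bilaterally symmetric like the spin null itself). Two such maps are spatially smooth and independent in
#' orientation, which is exactly the null the spin test is built to
#' calibrate against; harmonic maps with independent coefficients are not,
#' because a rotation orbit cannot re-randomize high-order coefficients.
#'
#' @param geometry A parcellation tibble.
#' @param k Number of maps.
#' @param seed Integer seed.
#' @return A regions x k matrix of standardized maps.
#' @export
random_rotation_maps <- function(geometry, k, seed = 1L) {
  coords <- geometry_coords(geometry)
  hemi <- geometry$hemi
  mirror <- diag(c(-1, 1, 1))
  # multi-scale template, even in its first argument so mirrored evaluation
  # is consistent across hemispheres
  template <- function(y) {
    y[, 3] + 0.9 * (3 * y[, 3]^2 - 1) / 2 + 0.7 * y[, 2] +
      0.35 * y[, 2] * y[, 3]
  }
  with_seed(seed, {
    out <- vapply(seq_len(k), function(j) {
      a <- runif(3, 0, 2 * pi)
      Q <- rot_x(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3])
      m <- numeric(nrow(coords))
      for (h in unique(hemi)) {
        idx <- which(hemi == h)
        Qh <- if (h == "R") mirror %*% Q %*% mirror else Q
        m[idx] <- template(coords[idx, , drop = FALSE] %*% t(Qh))
      }
      m
    }, numeric(nrow(coords)))
    rownames(out) <- geometry$region
    scale(out)[, , drop = FALSE]
  })
}

#' Generate hemisphere-preserving spherical rotations of a parcellation
#'
#' Each spin rotates the left-hemisphere parcel coordinates by three random
#' angles about the x, y and z axes and applies the same rotation to the
#' right hemisphere with the sign of the y- and z-angles flipped, preserving
#' mirror symmetry. Rotated regions are then matched back to original
#' regions by nearest Euclidean distance, greedily and without replacement,
#' processing rotated regions in descending order of their mean distance to
#' the unrotated regions. Each spin is therefore a hemisphere-preserving
#' permutation of the region indices.
#'
#' @param geometry A parcellation tibble from [generate_geometry()] (columns
#'   `region`, `hemi`, `x`, `y`, `z`).
#' @param n_perm Number of spins.
#' @param seed Integer seed.
#' @return A `spin_null` object: `permutations` (n_perm x n_regions integer
#'   matrix; row `s` maps original region index `i` to source index
#'   `perm[s, i]`), `angles` (n_perm x 3, radians), `regions`, `seed`.
#' @export
generate_spins <- function(geometry, n_perm, seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm")
  coords <- geometry_coords(geometry)
  hemi <- geometry$hemi
  if (length(unique(hemi)) < 2L) {
    rlang::warn("single-hemisphere geometry: mirrored angles not applied.")
  }
  sides <- split(seq_len(nrow(coords)), hemi)
  perms <- matrix(0L, n_perm, nrow(coords))
  angles <- with_seed(seed, matrix(runif(3 * n_perm, 0, 2 * pi), n_perm, 3))
  for (s in seq_len(n_perm)) {
    perms[s, ] <- spin_once(coords, sides, angles[s, ])
  }
  colnames(perms) <- rownames(coords)
  structure(list(permutations = perms, angles = angles,
                 regions = rownames(coords), seed = seed),
            class = "spin_null")
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("Spin null: %d rotations of %d regions (seed %d)\n",
              nrow(x$permutations), ncol(x$permutations), x$seed))
  invisible(x)
}

#' Pearson correlation between two aligned regional maps
#'
#' @param map_a,map_b Numeric vectors over the same regions (named vectors
#'   are aligned by name; `change_map` tibbles are accepted).
#' @return The product-moment correlation.
#' @export
map_correlation <- function(map_a, map_b) {
  a <- change_map_vector(map_a, NULL)
  b <- change_map_vector(map_b, NULL)
  if (length(a) != length(b)) {
    nv_abort("maps have different lengths.", "nv_alignment_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    nv_abort("constant map: correlation undefined.", "nv_degenerate_response")
  }
  stats::cor(a, b)
}

#' Spin permutation test of a map-to-map correlation
#'
#' Compares the observed correlation between two regional maps to the
#' distribution of correlations obtained by spatially rotating the second
#' map.
#'
#' @param map_a,map_b Regional maps (vectors in geometry region order, or
#'   `change_map` tibbles whose region order matches the spin geometry).
#' @param spins A `spin_null` from [generate_spins()].
#' @param direction `"two_sided"` (default), `"high"` or `"low"`.
#' @return A `perm_test` with statistic "spatial correlation".
#' @export
p_spin <- function(map_a, map_b, spins, direction = "two_sided") {
  stopifnot(inherits(spins, "spin_null"))
  a <- change_map_vector(map_a, spins$regions)
  b <- change_map_vector(map_b, spins$regions)
  obs <- map_correlation(a, b)
  spun <- matrix(b[t(spins$permutations)], nrow = length(b))
  null <- as.numeric(stats::cor(a, spun))
  new_perm_test("spatial correlation", obs, null, direction,
                nrow(spins$permutations), spins$seed)
}
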