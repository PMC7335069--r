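# Subject-level coupling between peripheral gene expression and cortical
# anatomy: PLS across subjects (the shared dimension is people, not
# regions), permutation significance, and spatial comparison of the region
# loadings with a group change map.

#' Z-score columns within karyotype groups
#'
#' Removes between-karyotype-group effects: each column is standardized to
#' mean 0, sd 1 within each group, so downstream coupling reflects
#' inter-individual variation only.
#'
#' @param x A subjects x variables numeric matrix (rownames = subject ids).
#' @param groups Group label per subject (each group needs >= 3 subjects).
#' @return The within-group standardized matrix.
#' @export
scale_within_group <- function(x, groups) {
  x <- as.matrix(x)
  if (length(groups) != nrow(x)) {
    nv_abort("`groups` must have one label per row of `x`.", "nv_bad_argument")
  }
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    nv_abort(paste0("groups with fewer than 3 subjects: ",
                    paste(names(sizes)[sizes < 3], collapse = ", ")),
             "nv_bad_argument")
  }
  for (g in unique(groups)) {
    rows <- which(groups == g)
    x[rows, ] <- scale(x[rows, , drop = FALSE])
  }
  x
}

#' First PLS component of shared variance across subjects
#'
#' SIMPLS with subjects as the common dimension: the predictor block is a
#' subjects x genes expression matrix and the response block a subjects x
#' regions regional-MS matrix. Returns one loading per gene, one per region
#' and a pair of subject score vectors whose covariance the component
#' maximizes. Polarity is fixed so the two subject score vectors correlate
#' non-negatively; scores are then standardized (the loadings stay on their
#' natural scale).
#'
#' @param expression Subjects x genes matrix (rownames = subject ids).
#' @param ms Subjects x regions matrix, same subjects.
#' @return An `individual_pls` object: `gene_loadings`, `region_loadings`,
#'   `expression_scores`, `ms_scores`, `covariance` (the maximized score
#'   covariance), `n_subjects`.
#' @export
fit_individual_pls <- function(expression, ms) {
  expression <- as.matrix(expression); ms <- as.matrix(ms)
  if (!identical(rownames(expression), rownames(ms))) {
    nv_abort("expression and MS blocks have mismatched subjects.",
             "nv_alignment_error")
  }
  n <- nrow(expression)
  if (n < 5L) nv_abort("need at least 5 subjects.", "nv_bad_argument")
  X0 <- scale(expression, center = TRUE, scale = FALSE)
  Y0 <- scale(ms, center = TRUE, scale = FALSE)
  fit <- simpls(X0, Y0, 1L)
  w <- fit$W[, 1]; q <- fit$Q[, 1]; t_ <- fit$T[, 1]; u <- fit$U[, 1]
  t_ <- as.numeric(scale(t_)); u <- as.numeric(scale(u))
  if (stats::cor(t_, u) < 0) {
    w <- -w; q <- -q; t_ <- -t_; u <- -u
  }
  # cor(t, u) >= 0 leaves a joint sign free; pin it so the mean gene loading
  # is non-negative (the panel measures dosage-sensitive expression, so the
  # shared expression axis points with the genes)
  if (mean(w) < 0) {
    w <- -w; q <- -q; t_ <- -t_; u <- -u
  }
  structure(list(
    gene_loadings = stats::setNames(w, colnames(expression)),
    region_loadings = stats::setNames(q, colnames(ms)),
    expression_scores = stats::setNames(t_, rownames(expression)),
    ms_scores = stats::setNames(u, rownames(ms)),
    covariance = max_cross_covariance(X0, Y0),
    n_subjects = n
  ), class = "individual_pls")
}

# Internal: the maximized first-component covariance = leading singular
# value of the cross-covariance matrix X0'Y0 / (n - 1).
max_cross_covariance <- function(X0, Y0) {
  svd(crossprod(X0, Y0) / (nrow(X0) - 1), nu = 0L, nv = 0L)$d[1]
}

#' @export
print.individual_pls <- function(x, ...) {
  cat(sprintf("Individual PLS: %d subjects, %d genes x %d regions\n",
              x$n_subjects, length(x$gene_loadings), length(x$region_loadings)))
  cat(sprintf("  max score covariance = %.4g\n", x$covariance))
  invisible(x)
}

#' Permutation significance of the shared-variance component
#'
#' Statistic: the maximized first-component covariance between the two
#' blocks. Null: the subject rows of the expression block are permuted
#' (equivalent under the null to permuting either block); one-sided add-one
#' p. When `groups` is supplied, rows are permuted within groups: after
#' within-group scaling, group centering makes same-group subjects weakly
#' dependent, and only the within-group permutation is exchangeable under
#' the null.
#'
#' @inheritParams fit_individual_pls
#' @param groups Optional group label per subject (permute within groups).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `perm_test` object.
#' @export
component_significance <- function(expression, ms, groups = NULL,
                                   n_perm = 1000L, seed = 1L) {
  expression <- as.matrix(expression); ms <- as.matrix(ms)
  X0 <- scale(expression, center = TRUE, scale = FALSE)
  Y0 <- scale(ms, center = TRUE, scale = FALSE)
  obs <- max_cross_covariance(X0, Y0)
  n <- nrow(X0)
  draw_perm <- if (is.null(groups)) {
    function() sample.int(n)
  } else {
    idx <- split(seq_len(n), groups)
    function() {
      out <- integer(n)
      for (g in idx) out[g] <- g[sample.int(length(g))]
      out
    }
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    max_cross_covariance(X0[draw_perm(), , drop = FALSE], Y0)
  }, numeric(1)))
  new_perm_test("first-component covariance", obs, null, "high", n_perm, seed)
}

#' Compare individual-PLS region loadings with a group change map
#'
#' Reports the spatial correlation between the region loadings of the
#' subject-level PLS component and a group-level change map, its spin-test
#' p-value, and a subject-bootstrap distribution of the correlation
#' (refitting the PLS in every resample).
#'
#' @inheritParams fit_individual_pls
#' @param change_map A `change_map` tibble or named region vector over the
#'   same regions as `ms` columns.
#' @param spins A `spin_null` over those regions.
#' @param n_boot Bootstrap resamples over subjects (default 1000).
#' @param seed Integer seed.
#' @param direction Sidedness of the spin test (default `"high"`: the
#'   planted/observed coupling is positive by the polarity convention).
#' @return A list: `r` (observed correlation), `p_spin` (`perm_test`),
#'   `boot_r` (bootstrap correlations), `fit` (the `individual_pls`).
#' @export
loadings_vs_changemap <- function(expression, ms, change_map, spins,
                                  n_boot = 1000L, seed = 1L,
                                  direction = "high") {
  fit <- fit_individual_pls(expression, ms)
  map <- change_map_vector(change_map, names(fit$region_loadings))
  r <- map_correlation(unname(fit$region_loadings), map)
  ps <- p_spin(stats::setNames(unname(fit$region_loadings), spins$regions),
               stats::setNames(map, spins$regions), spins,
               direction = direction)
  n <- nrow(expression)
  boot_r <- with_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(i) {
      rows <- sample.int(n, replace = TRUE)
      if (length(unique(rows)) < 5L) return(NA_real_)
      b <- fit_individual_pls(
        `rownames<-`(expression[rows, , drop = FALSE], paste0("b", seq_len(n))),
        `rownames<-`(ms[rows, , drop = FALSE], paste0("b", seq_len(n))))
      stats::cor(unname(b$region_loadings), map)
    }, numeric(1))
  })
  list(r = r, p_spin = ps, boot_r = boot_r[!is.na(boot_r)], fit = fit)
}
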