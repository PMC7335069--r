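#' Default morphometric feature set
#'
#' Cortical thickness (CT, mm), surface area (SA, mm^2), gray matter volume
#' (GM, mm^3), mean curvature (MC, 1/mm) and intrinsic curvature (IC,
#' dimensionless).
#' @export
MS_FEATURES <- c("CT", "SA", "GM", "MC", "IC")

#' Z-score regional features within a subject
#'
#' Scales each morphometric feature to mean 0, sd 1 across regions (sample
#' n-1 standard deviation), the normalization applied before computing
#' morphometric similarity so that features with different units contribute
#' equally.
#'
#' @param subject_features A data frame with a `region` column and one
#'   numeric column per feature.
#' @param features Character vector of feature columns (default
#'   [MS_FEATURES]).
#' @return A tibble of the same shape with each feature column standardized.
#' @examples
#' df <- tibble::tibble(region = c("a", "b", "c"), CT = c(1, 2, 3))
#' zscore_features(df, features = "CT")
#' @export
zscore_features <- function(subject_features, features = MS_FEATURES) {
  df <- tibble::as_tibble(subject_features)
  missing <- setdiff(c("region", features), names(df))
  if (length(missing)) {
    nv_abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
             "nv_bad_argument")
  }
  if (nrow(df) < 3L) {
    nv_abort("at least 3 regions are required to z-score features.",
             "nv_bad_argument")
  }
  for (f in features) {
    v <- df[[f]]
    if (anyNA(v)) nv_abort(sprintf("feature '%s' contains missing values.", f),
                           "nv_bad_argument")
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      nv_abort(sprintf("feature '%s' has zero variance across regions.", f),
               "nv_constant_feature")
    }
    df[[f]] <- (v - mean(v)) / s
  }
  df
}

#' Build a morphometric similarity network for one subject
#'
#' Computes the region-by-region Pearson correlation of the (z-scored)
#' morphometric feature vectors: edge (i, j) is the correlation between
#' region i's and region j's feature profiles. The diagonal is excluded
#' (stored as `NA`) so it can never leak into nodal averages.
#'
#' @param normalized A region-by-feature table as returned by
#'   [zscore_features()].
#' @param features Feature columns to use (default [MS_FEATURES]).
#' @param subject_id Optional subject label attached to the network.
#' @return An object of class `ms_network`: a list with `subject_id`,
#'   `edges` (symmetric region x region matrix, diagonal `NA`) and
#'   `regional_ms` (per-region mean off-diagonal similarity).
#' @export
build_msn <- function(normalized, features = MS_FEATURES, subject_id = NA_character_) {
  df <- tibble::as_tibble(normalized)
  X <- as.matrix(df[, features, drop = FALSE])
  rownames(X) <- df$region
  if (any(duplicated(df$region))) {
    nv_abort("duplicated region labels in feature table.", "nv_bad_argument")
  }
  rv <- apply(X, 1, sd)
  if (any(rv == 0 | !is.finite(rv))) {
    bad <- rownames(X)[which(rv == 0 | !is.finite(rv))]
    nv_abort(paste0("regions with zero feature variance (undefined correlation): ",
                    paste(bad, collapse = ", ")),
             "nv_undefined_correlation")
  }
  edges <- stats::cor(t(X))
  diag(edges) <- NA_real_
  structure(
    list(subject_id = subject_id, edges = edges,
         regional_ms = rowMeans(edges, na.rm = TRUE)),
    class = "ms_network"
  )
}

#' @export
print.ms_network <- function(x, ...) {
  cat(sprintf("Morphometric similarity network (%s): %d regions\n",
              x$subject_id, nrow(x$edges)))
  cat(sprintf("  regional MS range: [%.3f, %.3f]\n",
              min(x$regional_ms), max(x$regional_ms)))
  invisible(x)
}

#' Regional (nodal) morphometric similarity
#'
#' The average similarity between a region and all other regions, i.e. the
#' mean of each row of the edge matrix excluding the diagonal.
#'
#' @param network An `ms_network` object.
#' @return Named numeric vector, one value per region.
#' @export
regional_ms <- function(network) {
  stopifnot(inherits(network, "ms_network"))
  rowMeans(network$edges, na.rm = TRUE)
}

#' Per-subject regional MS for a whole cohort
#'
#' Runs [zscore_features()] and [build_msn()] for every subject in a cohort
#' table and collects the regional MS values.
#'
#' @param cohort A cohort table: one row per subject x region with feature
#'   columns and per-subject covariates (see [generate_cohort()]).
#' @param features Feature columns (default [MS_FEATURES]).
#' @return A tibble `subject_id`, `region`, `regional_ms` (long format).
#' @export
compute_cohort_ms <- function(cohort, features = MS_FEATURES) {
  cohort <- tibble::as_tibble(cohort)
  split(cohort, cohort$subject_id) |>
    purrr::map(function(d) {
      net <- build_msn(zscore_features(d[, c("region", features)], features),
                       features = features, subject_id = d$subject_id[[1]])
      tibble::tibble(subject_id = d$subject_id[[1]],
                     region = rownames(net$edges),
                     regional_ms = unname(net$regional_ms))
    }) |>
    purrr::list_rbind()
}

#' Per-subject MSN edge matrices for a whole cohort
#'
#' @inheritParams compute_cohort_ms
#' @return A named list of `ms_network` objects, one per subject, in the
#'   order subjects first appear in the cohort table.
#' @export
compute_cohort_msns <- function(cohort, features = MS_FEATURES) {
  cohort <- tibble::as_tibble(cohort)
  ids <- unique(cohort$subject_id)
  nets <- purrr::map(ids, function(id) {
    d <- cohort[cohort$subject_id == id, , drop = FALSE]
    build_msn(zscore_features(d[, c("region", features)], features),
              features = features, subject_id = id)
  })
  stats::setNames(nets, ids)
}

#' Per-subject covariates of a cohort table
#'
#' @param cohort A cohort table (one row per subject x region).
#' @return One row per subject with the covariate columns
#'   (`group`, `age`, `sex`, and `xan`/`yan` or `dx` when present).
#' @export
cohort_covariates <- function(cohort) {
  keep <- intersect(c("subject_id", "group", "age", "sex", "xan", "yan", "dx"),
                    names(cohort))
  dplyr::distinct(tibble::as_tibble(cohort)[, keep])
}
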