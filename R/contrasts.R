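# Linear-model change maps for gene-dosage contrasts.
#
# Two designs are supported, mirroring how dosage effects are usually
# modelled in case-control neurogenetics:
#   aneuploidy:   response ~ intercept + age + sex + xan + yan
#   case_control: response ~ intercept + age + sex + dx
# The per-region two-sided T statistic of the dosage coefficient
# (patient - control polarity) is the change map.

# Internal: design matrix for a contrast model.
contrast_design <- function(covariates, model = c("aneuploidy", "case_control"),
                            extra_covariates = character()) {
  model <- match.arg(model)
  covariates <- tibble::as_tibble(covariates)
  need <- switch(model,
                 aneuploidy = c("age", "sex", "xan", "yan"),
                 case_control = c("age", "sex", "dx"))
  missing <- setdiff(c(need, extra_covariates), names(covariates))
  if (length(missing)) {
    nv_abort(paste0("covariates missing for model '", model, "': ",
                    paste(missing, collapse = ", ")), "nv_bad_argument")
  }
  covariates$sex <- as.numeric(factor(covariates$sex, levels = sort(unique(covariates$sex)))) - 1
  rhs <- paste(c(need, extra_covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    nv_abort(paste0("singular design; aliased columns: ",
                    paste(aliased, collapse = ", ")), "nv_singular_design")
  }
  X
}

# Internal: vectorized OLS t statistics for one coefficient over a matrix of
# responses (subjects x responses). Returns list(t, p, beta, df).
ols_t <- function(X, Y, coef_name) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) {
    nv_abort("too few subjects for the requested model.", "nv_bad_argument")
  }
  j <- match(coef_name, colnames(X))
  if (is.na(j)) nv_abort(sprintf("coefficient '%s' not in design.", coef_name),
                         "nv_bad_argument")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)          # p x m coefficients
  resid <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- B[j, ] / se
  # a response that the design fits exactly (e.g. constant across subjects)
  # has no evidence either way: report T = 0, not 0/0 noise
  exact_fit <- sigma2 <= 1e-20 * pmax(1, colMeans(Y^2))
  tval[exact_fit | se == 0] <- 0
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), beta = B[j, ], df = df)
}

# Internal: long (subject_id, region, value) table -> subjects x regions matrix
# aligned with a covariate table's subject order.
response_matrix <- function(tbl, covariates, value_col) {
  wide <- tidyr::pivot_wider(tbl, id_cols = "subject_id",
                             names_from = "region",
                             values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  if (!all(covariates$subject_id %in% rownames(m))) {
    nv_abort("subjects in covariates absent from response table.",
             "nv_bad_argument")
  }
  m[covariates$subject_id, , drop = FALSE]
}

#' Fit a regional dosage-contrast change map
#'
#' Ordinary least squares per region. For the `aneuploidy` model the response
#' is regressed on age, sex and the supernumerary X and Y counts (`xan`,
#' `yan`) and the T statistic of the requested dosage coefficient is
#' extracted; for the `case_control` model the binary diagnosis `dx`
#' (patient = 1, contrast = patient - control) takes that role.
#'
#' @param ms A long tibble `subject_id`, `region`, plus the response column
#'   (default `regional_ms`, as from [compute_cohort_ms()]).
#' @param covariates Per-subject covariates (see [cohort_covariates()]).
#' @param model `"aneuploidy"` or `"case_control"`.
#' @param coef Coefficient of interest: `"dx"` (case_control) or
#'   `"xan"`/`"yan"` (aneuploidy).
#' @param response Name of the response column in `ms`.
#' @param extra_covariates Optional additional covariate columns (e.g. a
#'   total surface area column for the brain-size robustness check).
#' @return A `change_map` tibble: `region`, `t`, `z` (t z-scored across
#'   regions, for plotting), `p`; attributes record the model and
#'   coefficient.
#' @export
fit_regional_contrast <- function(ms, covariates,
                                  model = c("case_control", "aneuploidy"),
                                  coef = NULL, response = "regional_ms",
                                  extra_covariates = character()) {
  model <- match.arg(model)
  coef <- coef %||% switch(model, case_control = "dx", aneuploidy = "xan")
  covariates <- tibble::as_tibble(covariates)
  X <- contrast_design(covariates, model, extra_covariates)
  Y <- response_matrix(tibble::as_tibble(ms), covariates, response)
  fit <- ols_t(X, Y, coef)
  new_change_map(colnames(Y), fit$t, fit$p, model = model, coef = coef,
                 n = nrow(X))
}

# Internal: change_map constructor.
new_change_map <- function(regions, t, p, model, coef, n) {
  s <- if (length(t) > 1) sd(t) else 0
  z <- if (is.finite(s) && s > 0) (t - mean(t)) / s else t * 0
  out <- tibble::tibble(region = regions, t = unname(t), z = unname(z),
                        p = unname(p))
  structure(out, class = c("change_map", class(out)),
            model = model, coef = coef, n_subjects = n)
}

#' Change map from a single raw anatomical feature
#'
#' Applies the same dosage-contrast model as [fit_regional_contrast()] but
#' with one raw regional morphometric feature (e.g. `GM`) as the response
#' instead of regional MS.
#'
#' @param cohort A cohort table (one row per subject x region).
#' @param feature Feature column name.
#' @inheritParams fit_regional_contrast
#' @return A `change_map` tibble.
#' @export
single_feature_contrast <- function(cohort, feature,
                                    model = c("case_control", "aneuploidy"),
                                    coef = NULL, extra_covariates = character()) {
  cohort <- tibble::as_tibble(cohort)
  if (!feature %in% names(cohort)) {
    nv_abort(sprintf("feature '%s' not in cohort table.", feature),
             "nv_bad_argument")
  }
  fit_regional_contrast(cohort[, c("subject_id", "region", feature)],
                        cohort_covariates(cohort), model = model, coef = coef,
                        response = feature, extra_covariates = extra_covariates)
}

#' Fit edge-level dosage contrasts and classify edge effects
#'
#' Applies the regional contrast model to every off-diagonal MSN edge, and
#' annotates each edge with one of four effect classes from the sign of the
#' mean control edge weight and the sign of the edge T statistic:
#' `(+,+)` hypercoupling, `(-,+)` dedifferentiation, `(+,-)` decoupling,
#' `(-,-)` hyperdifferentiation.
#'
#' @param msns A named list of `ms_network` objects (one per subject), as
#'   from [compute_cohort_msns()].
#' @inheritParams fit_regional_contrast
#' @return An `edge_stats` object: list with symmetric matrices `edge_t`,
#'   `control_mean_edge` and `category` (character), plus the model metadata.
#' @export
fit_edge_contrast <- function(msns, covariates,
                              model = c("case_control", "aneuploidy"),
                              coef = NULL, extra_covariates = character()) {
  model <- match.arg(model)
  coef <- coef %||% switch(model, case_control = "dx", aneuploidy = "xan")
  covariates <- tibble::as_tibble(covariates)
  regions <- rownames(msns[[1]]$edges)
  nr <- length(regions)
  ut <- upper.tri(msns[[1]]$edges)
  Y <- t(vapply(msns[covariates$subject_id], function(net) net$edges[ut],
                numeric(sum(ut))))
  X <- contrast_design(covariates, model, extra_covariates)
  fit <- ols_t(X, Y, coef)
  is_control <- if ("dx" %in% names(covariates)) {
    covariates$dx == 0
  } else {
    covariates$xan == 0 & covariates$yan == 0
  }
  if (!any(is_control)) {
    nv_abort("no control subjects found for control mean edge weights.",
             "nv_bad_argument")
  }
  ctrl <- Reduce(`+`, purrr::map(msns[covariates$subject_id[is_control]],
                                 "edges")) / sum(is_control)
  edge_t <- matrix(0, nr, nr, dimnames = list(regions, regions))
  edge_t[ut] <- fit$t
  edge_t <- edge_t + t(edge_t)
  diag(edge_t) <- NA_real_
  category <- classify_edges(ctrl, edge_t)
  structure(list(edge_t = edge_t, control_mean_edge = ctrl,
                 category = category, model = model, coef = coef),
            class = "edge_stats")
}

#' Classify edge effects from control weight and contrast signs
#'
#' @param control_weight Mean control edge weight(s) (scalar, vector or
#'   matrix).
#' @param edge_t Edge contrast T statistic(s), same shape.
#' @return Character array of the same shape with values `hypercoupling`,
#'   `dedifferentiation`, `decoupling`, `hyperdifferentiation`. Exact zeros
#'   are assigned to the positive branch (deterministic tie rule).
#' @export
classify_edges <- function(control_weight, edge_t) {
  if (length(control_weight) != length(edge_t)) {
    nv_abort("control_weight and edge_t must have the same shape.",
             "nv_bad_argument")
  }
  wpos <- control_weight >= 0           # zeros -> positive branch
  tpos <- edge_t >= 0
  out <- ifelse(wpos & tpos, "hypercoupling",
         ifelse(!wpos & tpos, "dedifferentiation",
         ifelse(wpos & !tpos, "decoupling", "hyperdifferentiation")))
  out[is.na(control_weight) | is.na(edge_t)] <- NA_character_
  if (is.matrix(edge_t)) dimnames(out) <- dimnames(edge_t)
  out
}

#' Edge-effect composition of the most-changed regions
#'
#' For the `k` regions with the most positive and the `k` with the most
#' negative regional T statistics, sums the absolute edge T values of their
#' incident edges within each of the four edge-effect classes.
#'
#' @param change_map A `change_map` tibble.
#' @param edge_stats An `edge_stats` object from [fit_edge_contrast()].
#' @param k Number of top regions per polarity (default 10).
#' @return A tibble `region`, `polarity` (`top_positive`/`top_negative`),
#'   `category`, `abs_sum`, with zero rows filled in for absent categories.
#' @export
edge_annotation_summary <- function(change_map, edge_stats, k = 10L) {
  k <- assert_count(k, "k")
  nr <- nrow(change_map)
  if (k > nr / 2) {
    nv_abort("`k` must be at most half the number of regions.", "nv_bad_bound")
  }
  ord <- order(change_map$t, decreasing = TRUE)
  sel <- tibble::tibble(
    region = change_map$region[c(head(ord, k), utils::tail(ord, k))],
    polarity = rep(c("top_positive", "top_negative"), each = k)
  )
  cats <- c("hypercoupling", "dedifferentiation", "decoupling",
            "hyperdifferentiation")
  purrr::pmap(sel, function(region, polarity) {
    tv <- abs(edge_stats$edge_t[region, ])
    cv <- edge_stats$category[region, ]
    keep <- !is.na(cv)
    sums <- vapply(cats, function(cc) sum(tv[keep][cv[keep] == cc]), numeric(1))
    tibble::tibble(region = region, polarity = polarity, category = cats,
                   abs_sum = unname(sums))
  }) |> purrr::list_rbind()
}

#' Leave-one-feature-out robustness of a change map
#'
#' Recomputes the MSN change map with each morphometric feature excluded in
#' turn and reports the spatial correlation of each reduced map with the
#' full-feature map. The feature whose exclusion lowers that correlation the
#' most is flagged as contributing most to the contrast.
#'
#' @param cohort A cohort table.
#' @inheritParams fit_regional_contrast
#' @param features Full feature set (default [MS_FEATURES]).
#' @return A list with `full` (the full-feature `change_map`), `maps` (named
#'   list of reduced `change_map`s), and `similarity` (tibble
#'   `excluded_feature`, `r`, `most_contributing`).
#' @export
leave_one_feature_out_maps <- function(cohort,
                                       model = c("case_control", "aneuploidy"),
                                       coef = NULL, features = MS_FEATURES) {
  model <- match.arg(model)
  if (length(features) < 4L) {
    nv_abort("need at least 4 features so 3 remain after exclusion.",
             "nv_bad_argument")
  }
  covs <- cohort_covariates(cohort)
  full <- fit_regional_contrast(compute_cohort_ms(cohort, features), covs,
                                model = model, coef = coef)
  maps <- purrr::map(stats::setNames(features, features), function(f) {
    fit_regional_contrast(compute_cohort_ms(cohort, setdiff(features, f)),
                          covs, model = model, coef = coef)
  })
  r <- vapply(maps, function(m) stats::cor(m$t, full$t), numeric(1))
  sim <- tibble::tibble(excluded_feature = features, r = unname(r),
                        most_contributing = seq_along(features) == which.min(r))
  list(full = full, maps = maps, similarity = sim)
}

#' Screen for dosage-by-covariate interactions
#'
#' Reports per-region p-values for the `xan:sex` and `xan:yan` interaction
#' terms in the aneuploidy model, as a pre-check before interpreting additive
#' dosage coefficients.
#'
#' @inheritParams fit_regional_contrast
#' @return A tibble `region`, `term`, `p`.
#' @export
screen_interactions <- function(ms, covariates) {
  covariates <- tibble::as_tibble(covariates)
  covariates$sex <- as.numeric(factor(covariates$sex)) - 1
  Y <- response_matrix(tibble::as_tibble(ms), covariates, "regional_ms")
  X <- stats::model.matrix(~ age + sex + xan + yan + xan:sex + xan:yan,
                           data = covariates)
  if (qr(X)$rank < ncol(X)) {
    nv_abort("singular interaction design.", "nv_singular_design")
  }
  purrr::map(c("sex:xan", "xan:yan"), function(term) {
    fit <- ols_t(X, Y, term)
    tibble::tibble(region = colnames(Y),
                   term = if (term == "sex:xan") "xan:sex" else term,
                   p = unname(fit$p))
  }) |> purrr::list_rbind()
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("Change map (%s, coefficient %s, n = %d subjects)\n",
              attr(x, "model"), attr(x, "coef"), attr(x, "n_subjects")))
  NextMethod()
}

#' Tidy an edge_stats object
#'
#' @param x An `edge_stats` object.
#' @param ... Unused.
#' @return A tibble with one row per off-diagonal edge (upper triangle):
#'   `region_a`, `region_b`, `edge_t`, `control_weight`, `category`.
#' @export
tidy.edge_stats <- function(x, ...) {
  ut <- which(upper.tri(x$edge_t), arr.ind = TRUE)
  rn <- rownames(x$edge_t)
  tibble::tibble(
    region_a = rn[ut[, 1]], region_b = rn[ut[, 2]],
    edge_t = x$edge_t[ut], control_weight = x$control_mean_edge[ut],
    category = x$category[ut]
  )
}
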