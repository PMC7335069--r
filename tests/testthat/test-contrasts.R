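# Balanced two-group fixture with age and sex orthogonal to group.
balanced_covs <- function(n_per_group = 6) {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("case", "control"), each = n_per_group),
    dx = rep(c(1, 0), each = n_per_group),
    age = rep(seq(8, 18, length.out = n_per_group), 2),
    sex = rep(rep(c("M", "F"), length.out = n_per_group), 2)
  )
}

# Independent closed-form OLS oracle: explicit normal equations and the
# textbook t = beta / sqrt(sigma2 * [ (X'X)^-1 ]_jj ).
ols_oracle_t <- function(y, X, j) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  beta[j] / sqrt(sigma2 * XtX_inv[j, j])
}

test_that("regional T equals the closed-form OLS statistic on balanced fixtures", {
  covs <- balanced_covs()
  withr::with_seed(31, {
    ms <- tidyr::expand_grid(subject_id = covs$subject_id,
                             region = sprintf("r%02d", 1:7))
    ms$regional_ms <- rnorm(nrow(ms), 0, 0.2)
  })
  cm <- fit_regional_contrast(ms, covs, model = "case_control")
  X <- cbind(1, covs$age, as.numeric(factor(covs$sex)) - 1, covs$dx)
  for (r in unique(ms$region)) {
    y <- ms$regional_ms[ms$region == r]
    expect_lt(abs(cm$t[cm$region == r] - ols_oracle_t(y, X, 4)), 1e-10)
  }
})

test_that("regional T agrees with lm() under the aneuploidy model", {
  covs <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("XXY", "XYY", "XX", "XY"), each = 5),
    xan = rep(c(1, 0, 0, 0), each = 5), yan = rep(c(0, 1, 0, 0), each = 5),
    age = seq(6, 24, length.out = 20),
    sex = rep(c("M", "M", "F", "M"), each = 5)
  )
  withr::with_seed(13, {
    ms <- tidyr::expand_grid(subject_id = covs$subject_id,
                             region = c("rA", "rB"))
    ms$regional_ms <- rnorm(40)
  })
  for (coef in c("xan", "yan")) {
    cm <- fit_regional_contrast(ms, covs, model = "aneuploidy", coef = coef)
    for (r in c("rA", "rB")) {
      d <- dplyr::left_join(ms[ms$region == r, ], covs, by = "subject_id")
      d$sexn <- as.numeric(factor(d$sex)) - 1
      fit <- summary(lm(regional_ms ~ age + sexn + xan + yan, data = d))
      expect_lt(abs(cm$t[cm$region == r] - fit$coefficients[coef, "t value"]),
                1e-10)
    }
  }
})

test_that("a response identical across groups gives T = 0", {
  covs <- balanced_covs()
  ms <- tidyr::expand_grid(subject_id = covs$subject_id, region = "r1")
  ms$regional_ms <- 0.3
  cm <- fit_regional_contrast(ms, covs, model = "case_control")
  expect_equal(cm$t, 0)
})

test_that("rank-deficient designs fail with the aliased columns named", {
  covs <- balanced_covs()
  covs$sex <- "F"
  ms <- tidyr::expand_grid(subject_id = covs$subject_id, region = "r1")
  ms$regional_ms <- rnorm(12)
  expect_error(fit_regional_contrast(ms, covs, model = "case_control"),
               regexp = "sex", class = "nv_singular_design")
})

test_that("edge classification covers the sign grid, with zeros going positive", {
  expect_equal(classify_edges(0.4, 2.1), "hypercoupling")
  expect_equal(classify_edges(-0.3, -1.7), "hyperdifferentiation")
  grid <- expand.grid(w = c(1, -1), t = c(1, -1))
  got <- classify_edges(grid$w, grid$t)
  expect_setequal(got, c("hypercoupling", "dedifferentiation", "decoupling",
                         "hyperdifferentiation"))
  expect_equal(classify_edges(0, 0), "hypercoupling")
  expect_equal(classify_edges(0, -1), "decoupling")
})

test_that("edge contrasts are symmetric and reduce to the regional model per edge", {
  covs <- cohort_covariates(cohort_fix)
  msns <- compute_cohort_msns(cohort_fix)
  es <- fit_edge_contrast(msns, covs, model = "case_control")
  expect_true(all(abs(es$edge_t - t(es$edge_t)) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(es$control_mean_edge - t(es$control_mean_edge)) < 1e-12,
                  na.rm = TRUE))
  # single-edge self-consistency: edge (1,2) as a one-region response
  regions <- rownames(msns[[1]]$edges)
  one <- tibble::tibble(
    subject_id = covs$subject_id, region = "edge12",
    regional_ms = vapply(msns[covs$subject_id],
                         function(n) n$edges[1, 2], numeric(1)))
  cm <- fit_regional_contrast(one, covs, model = "case_control")
  expect_lt(abs(es$edge_t[1, 2] - cm$t), 1e-10)
})

test_that("edge annotation sums partition each region's total |T|", {
  covs <- cohort_covariates(cohort_fix)
  msns <- compute_cohort_msns(cohort_fix)
  es <- fit_edge_contrast(msns, covs, model = "case_control")
  cm <- fit_regional_contrast(compute_cohort_ms(cohort_fix), covs,
                              model = "case_control")
  summ <- edge_annotation_summary(cm, es, k = 3)
  expect_equal(nrow(summ), 2 * 3 * 4)
  for (r in unique(summ$region)) {
    tot <- sum(summ$abs_sum[summ$region == r])
    expect_equal(tot, sum(abs(es$edge_t[r, ]), na.rm = TRUE), tolerance = 1e-10)
  }
  # all-hypercoupling fixture: per-region sum counts incident edges
  nr <- 11
  regions <- sprintf("q%02d", 1:nr)
  et <- matrix(1, nr, nr, dimnames = list(regions, regions)); diag(et) <- NA
  ctrl <- matrix(0.5, nr, nr, dimnames = list(regions, regions)); diag(ctrl) <- NA
  es2 <- structure(list(edge_t = et, control_mean_edge = ctrl,
                        category = classify_edges(ctrl, et)),
                   class = "edge_stats")
  cm2 <- tibble::tibble(region = regions, t = seq_len(nr), z = 0, p = 1)
  s2 <- edge_annotation_summary(cm2, es2, k = 2)
  expect_equal(s2$abs_sum[s2$category == "hypercoupling"], rep(10, 4))
  expect_true(all(s2$abs_sum[s2$category != "hypercoupling"] == 0))
})

test_that("leave-one-feature-out produces one map per feature and flags the weakest", {
  lofo <- leave_one_feature_out_maps(cohort_fix, model = "case_control")
  expect_length(lofo$maps, 5)
  expect_equal(sum(lofo$similarity$most_contributing), 1L)
  expect_true(all(lofo$similarity$r <= 1))
  # re-running with the full set reproduces the full map exactly
  again <- fit_regional_contrast(compute_cohort_ms(cohort_fix),
                                 cohort_covariates(cohort_fix),
                                 model = "case_control")
  expect_equal(lofo$full$t, again$t)
})

test_that("single-feature contrasts reduce to the regional machinery", {
  cm_gm <- single_feature_contrast(cohort_fix, "GM", model = "case_control")
  expect_equal(nrow(cm_gm), 40)
  cohort2 <- cohort_fix
  cohort2$GM <- 42
  expect_equal(single_feature_contrast(cohort2, "GM", model = "case_control")$t,
               rep(0, 40))
})

test_that("interaction screening returns p-values for both terms", {
  covs <- withr::with_seed(8, tibble::tibble(
    subject_id = sprintf("s%02d", 1:24),
    xan = sample(rep(c(0, 1, 2), 8)), yan = sample(rep(c(0, 1), 12)),
    age = runif(24, 5, 25), sex = sample(rep(c("M", "F"), 12))
  ))
  withr::with_seed(2, {
    ms <- tidyr::expand_grid(subject_id = covs$subject_id, region = c("a", "b"))
    ms$regional_ms <- rnorm(48)
  })
  sc <- screen_interactions(ms, covs)
  expect_setequal(unique(sc$term), c("xan:sex", "xan:yan"))
  expect_true(all(sc$p >= 0 & sc$p <= 1))
})
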