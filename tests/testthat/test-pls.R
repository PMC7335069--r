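random_pls_fixture <- function(nr = 30, ng = 80, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(nr * ng), nr, ng,
                dimnames = list(sprintf("r%02d", 1:nr), sprintf("g%03d", 1:ng)))
    y <- stats::setNames(rnorm(nr), rownames(X))
    list(X = X, y = y)
  })
}

test_that("first-component weights align with the gene-wise covariance vector", {
  for (s in 1:5) {
    fx <- random_pls_fixture(seed = s)
    fit <- fit_pls_component(fx$X, fx$y)
    X0 <- scale(fx$X, scale = FALSE)
    cov_vec <- as.numeric(crossprod(X0, fx$y - mean(fx$y)))
    cosine <- sum(fit$w1 * cov_vec) / sqrt(sum(fit$w1^2) * sum(cov_vec^2))
    expect_lt(abs(abs(cosine) - 1), 1e-10)
  }
})

test_that("a change map equal to one gene's expression puts that gene on top", {
  fx <- random_pls_fixture(seed = 3)
  g <- 17L
  fit <- fit_pls_component(fx$X, stats::setNames(fx$X[, g], rownames(fx$X)))
  expect_equal(unname(which.max(abs(fit$w1))), g)
})

test_that("negating the change map negates weights and reverses ranks", {
  fx <- random_pls_fixture(seed = 4)
  f1 <- fit_pls_component(fx$X, fx$y)
  f2 <- fit_pls_component(fx$X, -fx$y)
  expect_equal(f2$w1, -f1$w1, tolerance = 1e-10)
  r1 <- rank_genes(f1); r2 <- rank_genes(f2)
  expect_equal(r2$gene, rev(r1$gene))
})

test_that("the ranked list is invariant to positive rescaling of the change map", {
  fx <- random_pls_fixture(seed = 5)
  r1 <- rank_genes(fit_pls_component(fx$X, fx$y))
  r2 <- rank_genes(fit_pls_component(fx$X, 3.7 * fx$y))
  expect_equal(r1$gene, r2$gene)
})

test_that("polarity is fixed so scores track the change map non-negatively", {
  for (s in 6:9) {
    fx <- random_pls_fixture(seed = s)
    fit <- fit_pls_component(fx$X, fx$y)
    expect_gte(cor(fit$T1, fx$y), 0)
  }
})

test_that("gene ranking sorts by weight with label tie-breaks and centered ranks", {
  rl <- ranked_from_weights(c(0.5, -0.2, 0.9))
  expect_equal(rl$gene, c("g003", "g001", "g002"))
  expect_equal(rl$rank[rl$gene == "g003"], 1L)
  expect_equal(match(c("g001", "g002", "g003"), rl$gene), c(2L, 3L, 1L))
  expect_equal(rl$centered_rank, c(-1, 0, 1))
  # ties broken lexicographically by gene label
  rt <- ranked_from_weights(c(0.3, 0.3, 0.1))
  expect_equal(rt$gene, c("g001", "g002", "g003"))
  # ranks are a permutation, centered ranks span +-(N-1)/2
  rl2 <- ranked_from_weights(withr::with_seed(1, rnorm(101)))
  expect_setequal(rl2$rank, 1:101)
  expect_equal(range(rl2$centered_rank), c(-50, 50))
})

test_that("explained variance is bounded, near 1 for noiseless rank-1 coupling", {
  withr::with_seed(2, {
    u <- rnorm(40)
    w <- rnorm(60)
    X <- outer(u, w) + 1e-8 * matrix(rnorm(2400), 40, 60)
    dimnames(X) <- list(sprintf("r%02d", 1:40), sprintf("g%03d", 1:60))
  })
  ev <- explained_variance_profile(X, stats::setNames(u, rownames(X)), k = 4)
  expect_gt(ev$fractions[1], 0.999)
  expect_true(all(ev$fractions >= 0 & ev$fractions <= 1))
  expect_true(ev$comp1_maximal)
  fx <- random_pls_fixture(seed = 10)
  ev2 <- explained_variance_profile(fx$X, fx$y, k = 5)
  expect_true(all(ev2$fractions >= 0 & ev2$fractions <= 1))
  expect_equal(ev2$comp1_maximal, which.max(ev2$fractions) == 1)
})

test_that("a constant change map is rejected", {
  fx <- random_pls_fixture()
  expect_error(fit_pls_component(fx$X, stats::setNames(rep(1, 30), rownames(fx$X))),
               class = "nv_degenerate_response")
})

test_that("leave-one-donor-out loadings are stable, more so with less donor noise", {
  geom <- geom_small
  run_lodo <- function(noise, seed) {
    ga <- generate_expression_atlas(geom, n_genes = 200, n_donors = 4,
                                    cnv_spec = cnv_specification(size = 12, n_ds = 6, n_dsss = 4),
                                    donor_noise_sd = noise, seed = seed)
    f1 <- ga$manifest$factors[rownames(ga$atlas$expr), 1]
    y <- stats::setNames(f1 + 0.3 * withr::with_seed(seed, rnorm(length(f1))),
                         rownames(ga$atlas$expr))
    lodo <- leave_one_donor_out_atlases(ga$atlas$donors, ga$atlas$annotations)
    lodo_loading_stability(lodo, ga$atlas, y)
  }
  lo <- mean(sapply(1:3, function(s) run_lodo(0.2, s)$mean_r))
  hi <- mean(sapply(1:3, function(s) run_lodo(2.0, s)$mean_r))
  expect_gt(lo, hi)
  # identical donors give r = 1 exactly
  donors <- atlas_fix$atlas$donors[c(1, 1, 1)]
  atl <- aggregate_donor_expression(donors, atlas_fix$atlas$annotations)
  lodo <- leave_one_donor_out_atlases(donors, atlas_fix$atlas$annotations)
  y <- stats::setNames(atlas_fix$manifest$factors[rownames(atl$expr), 1],
                       rownames(atl$expr))
  st <- lodo_loading_stability(lodo, atl, y)
  expect_length(st$r, 3)
  expect_true(all(abs(st$r - 1) < 1e-10))
})

test_that("tidy and glance summarize a PLS fit", {
  fx <- random_pls_fixture(seed = 12)
  fit <- fit_pls_component(fx$X, fx$y)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 80)
  gl <- generics::glance(fit)
  expect_equal(gl$n_regions, 30)
  expect_true(is.logical(gl$comp1_maximal))
})
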