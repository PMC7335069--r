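test_that("median centered rank matches its definition", {
  rl <- ranked_from_weights(withr::with_seed(1, rnorm(10)))
  # whole list -> centered median 0
  expect_equal(median_rank(rl, rl$gene), 0)
  # members at ranks 1 and 2 of 10: centered -4.5, -3.5 -> median -4
  top2 <- rl$gene[rl$rank %in% c(1, 2)]
  expect_equal(median_rank(rl, top2), -4)
  # brute force on a random subset
  set <- withr::with_seed(2, sample(rl$gene, 5))
  expect_equal(median_rank(rl, set),
               median(rl$centered_rank[match(set, rl$gene)]))
  expect_error(median_rank(rl, c("absent1", "absent2")),
               class = "nv_empty_intersection")
})

test_that("exhaustive P_RAND equals full enumeration on tiny lists", {
  rl <- ranked_from_weights(withr::with_seed(3, rnorm(6)))
  bottom2 <- rl$gene[rl$rank %in% c(1, 2)]   # minimum possible median, low side
  obs <- median_rank(rl, bottom2)
  pt <- p_rand_trans(rl, 2, obs, direction = "low", exhaustive = TRUE)
  expect_equal(pt$p, 1 / 15)
  # oracle: enumerate all C(6,2) subsets by hand
  combos <- combn(rl$centered_rank, 2)
  oracle_p <- mean(apply(combos, 2, median) <= obs)
  expect_equal(pt$p, oracle_p)
})

test_that("P_RAND respects its floor and requires a declared direction", {
  rl <- ranked_from_weights(withr::with_seed(4, rnorm(50)))
  top <- rl$gene[rl$rank > 45]
  obs <- median_rank(rl, top)
  pt <- p_rand_trans(rl, 5, obs, direction = "high", n_perm = 200, seed = 1)
  expect_gte(pt$p, 1 / 201)
  expect_error(p_rand_trans(rl, 5, obs, direction = NULL),
               class = "nv_bad_argument")
})

test_that("cis resampling is the harder null on a chromosome-wide gradient", {
  # all 30 chromosome genes shifted high; the CNV subset is typical OF ITS
  # CHROMOSOME but extreme genome-wide
  w <- withr::with_seed(5, c(rnorm(30, mean = 2), rnorm(170)))
  rl <- ranked_from_weights(w)
  chrom_genes <- sprintf("g%03d", 1:30)
  cnv <- sprintf("g%03d", 1:12)
  obs <- median_rank(rl, cnv)
  p_cis <- p_rand_cis(rl, chrom_genes, 12, obs, "low", n_perm = 2000, seed = 1)
  p_trans <- p_rand_trans(rl, 12, obs, "low", n_perm = 2000, seed = 1)
  expect_gt(p_cis$p, p_trans$p)
  # degenerate: set as large as its chromosome
  expect_error(p_rand_cis(rl, chrom_genes, 30, obs, "low"),
               class = "nv_bad_bound")
})

test_that("cis sampling from the whole genome reduces to trans", {
  rl <- ranked_from_weights(withr::with_seed(6, rnorm(60)))
  set <- rl$gene[1:6]
  obs <- median_rank(rl, set)
  p1 <- p_rand_cis(rl, rl$gene, 6, obs, "low", n_perm = 3000, seed = 9)
  p2 <- p_rand_trans(rl, 6, obs, "low", n_perm = 3000, seed = 9)
  expect_lt(abs(p1$p - p2$p), 0.03)
})

test_that("chromosome profiles report per-chromosome medians with bootstrap SEs", {
  rl <- ranked_from_weights(withr::with_seed(7, rnorm(40)))
  ann <- tibble::tibble(gene = rl$gene,
                        chromosome = rep(c("1", "2"), each = 20))
  prof <- chromosome_rank_profile(rl, ann, n_boot = 200, seed = 1)
  expect_setequal(prof$chromosome, c("1", "2"))
  expect_true(all(prof$se >= 0))
  for (ch in c("1", "2")) {
    expect_equal(prof$median_rank[prof$chromosome == ch],
                 median_rank(rl, ann$gene[ann$chromosome == ch]))
  }
  # single chromosome: median 0
  ann1 <- tibble::tibble(gene = rl$gene, chromosome = "1")
  expect_equal(chromosome_rank_profile(rl, ann1, n_boot = 10)$median_rank, 0)
  # chromosome with no ranked genes is omitted with a warning
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(gene = "zz", chromosome = "9"))
  expect_warning(chromosome_rank_profile(rl, ann2, n_boot = 10), "omitted")
})

test_that("the most-extreme-chromosome test recovers a planted shift", {
  w <- withr::with_seed(8, c(rnorm(25, mean = 1.5), rnorm(275)))
  rl <- ranked_from_weights(w)
  ann <- tibble::tibble(gene = sprintf("g%03d", 1:300),
                        chromosome = c(rep("21", 25),
                                       rep(as.character(1:11), each = 25)))
  pt <- p_most_extreme_chromosome(rl, ann, "21", "low", n_perm = 500, seed = 2)
  expect_true(pt$observed_most_extreme)
  expect_lt(pt$p, 0.01)
  expect_gte(pt$p, 1 / 501)
  expect_error(p_most_extreme_chromosome(rl, ann, "99", "low"),
               class = "nv_bad_argument")
})

test_that("the most-extreme margin is null-calibrated for two symmetric chromosomes", {
  ps <- vapply(1:40, function(s) {
    rl <- ranked_from_weights(withr::with_seed(100 + s, rnorm(60)))
    ann <- tibble::tibble(gene = rl$gene, chromosome = rep(c("1", "2"), 30))
    p_most_extreme_chromosome(rl, ann, "1", "high", n_perm = 99, seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("the omnibus p multiplies independent marginals and honours bounds", {
  mk <- function(obs, null) {
    structure(list(statistic = "x", observed = obs, null_sample = null,
                   p = (1 + sum(null >= obs)) / (length(null) + 1),
                   direction = "high", n_perm = length(null), seed = 1),
              class = "perm_test")
  }
  null1 <- withr::with_seed(1, runif(4000))
  null2 <- withr::with_seed(2, runif(4000))
  r1 <- mk(quantile(null1, 0.8), null1)   # marginal p ~ 0.2
  r2 <- mk(quantile(null2, 0.7), null2)   # marginal p ~ 0.3
  om <- omnibus_p(list(r1, r2))
  expect_lt(abs(om$p - r1$p * r2$p), 0.03)
  # both observed at the minimum -> joint p = 1
  rmin <- mk(min(null1) - 1, null1)
  expect_equal(omnibus_p(list(rmin, rmin))$p, 1)
  # both at the ceiling -> omnibus at its floor
  rmax1 <- mk(max(null1) + 1, null1); rmax2 <- mk(max(null2) + 1, null2)
  expect_equal(omnibus_p(list(rmax1, rmax2))$p, 1 / 4001)
})

test_that("DS vs nDS median test matches exhaustive enumeration and flags overlap", {
  rl <- ranked_from_weights(withr::with_seed(9, rnorm(12)))
  ds <- rl$gene[rl$rank %in% 1:3]
  nds <- rl$gene[rl$rank %in% 7:10]
  exact <- ds_nds_median_test(rl, ds, nds, exhaustive = TRUE)
  # oracle: enumerate all label assignments by hand
  pool <- rl$centered_rank[match(c(ds, nds), rl$gene)]
  picks <- combn(7, 3)
  null <- apply(picks, 2, function(ix) median(pool[ix]) - median(pool[-ix]))
  obs <- median(pool[1:3]) - median(pool[-(1:3)])
  expect_equal(exact$observed, obs)
  expect_equal(exact$p, mean(abs(null) >= abs(obs)))
  mc <- ds_nds_median_test(rl, ds, nds, n_perm = 4000, seed = 3)
  expect_lt(abs(mc$p - exact$p), 0.05)
  expect_error(ds_nds_median_test(rl, ds, c(ds[1], nds)),
               class = "nv_bad_argument")
})

test_that("DS occupying the top ranks attains the extreme median difference", {
  rl <- ranked_from_weights(withr::with_seed(10, rnorm(20)))
  ds <- rl$gene[rl$rank <= 5]     # most positive weights = lowest centered ranks
  nds <- rl$gene[rl$rank > 5]
  tst <- ds_nds_median_test(rl, ds, nds, n_perm = 500, seed = 1)
  expect_true(all(tst$observed <= tst$null_sample))
  expect_equal(tst$p, perm <- (1 + sum(abs(tst$null_sample) >= abs(tst$observed))) / 501)
})

test_that("decile proportions partition each set and null composition gives no signal", {
  rl <- ranked_from_weights(withr::with_seed(11, rnorm(200)))
  # interleaved sets: identical decile composition -> all differences 0
  ord <- rl$gene[order(rl$rank)]
  ds <- ord[seq(1, 200, by = 20)]
  nds <- ord[seq(2, 200, by = 20)]
  dt <- decile_enrichment(rl, ds, nds, n_perm = 300, seed = 1)
  expect_true(all(dt$difference == 0))
  expect_equal(sum(dt$proportion_ds), 1, tolerance = 1e-12)
  expect_equal(sum(dt$proportion_nds), 1, tolerance = 1e-12)
  expect_true(all(dt$p > 0.999))
})

test_that("a planted extreme DS subset lights up only its decile, and DS^SS is extracted", {
  rl <- ranked_from_weights(withr::with_seed(12, rnorm(200)))
  ord <- rl$gene[order(rl$rank)]
  dsss_true <- ord[1:8]                      # decile 1
  ds <- c(dsss_true, ord[sample(41:200, 6)]) # plus unremarkable DS genes
  nds <- setdiff(ord[seq(15, 200, by = 9)], ds)[1:18]
  dt <- decile_enrichment(rl, ds, nds, n_perm = 2000, seed = 2)
  expect_true(1 %in% dt$decile[dt$p < 0.05])
  dsss <- extract_dsss(dt, ds, rl)
  expect_true(all(dsss$members %in% ds))
  expect_true(all(dsss_true %in% dsss$members))
  # no significant decile -> empty set with a warning
  dt0 <- dt; dt0$p <- 1
  expect_warning(empty <- extract_dsss(dt0, ds, rl), "empty")
  expect_length(empty$members, 0)
})

test_that("set-size sensitivity reduces to the single-set test at full size", {
  w <- withr::with_seed(13, c(rnorm(30, 1.2), rnorm(170)))
  rl <- ranked_from_weights(w)
  donor <- sprintf("g%03d", 1:30)
  sens <- set_size_sensitivity(rl, donor, sizes = c(10, 20, 30),
                               direction = "low", n_draws = 1500, seed = 3)
  expect_equal(nrow(sens), 3)
  expect_true(all(sens$p >= 1 / 1501))
  expect_equal(sens$observed[sens$size == 30], median_rank(rl, donor))
  # monotone planted gradient: p non-increasing in size
  expect_true(all(diff(sens$p) <= 0.02))
  expect_error(set_size_sensitivity(rl, donor, sizes = 0, direction = "low"),
               class = "nv_bad_bound")
})

test_that("permutation p-values use the add-one estimator", {
  rl <- ranked_from_weights(withr::with_seed(14, rnorm(30)))
  set <- rl$gene[rl$rank <= 3]
  obs <- median_rank(rl, set)
  pt <- p_rand_trans(rl, 3, obs, "low", n_perm = 100, seed = 5)
  expect_equal(pt$p, (1 + sum(pt$null_sample <= obs)) / 101)
})

test_that("enrichment summaries apply the optional Bonferroni correction", {
  rl <- ranked_from_weights(withr::with_seed(15, rnorm(60)))
  mk <- function(k) p_rand_trans(rl, 5, median_rank(rl, rl$gene[rl$rank <= k]),
                                 "low", n_perm = 200, seed = k)
  res <- list(a = mk(5), b = mk(30))
  raw <- enrichment_summary(res)
  bon <- enrichment_summary(res, correction = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, 2 * raw$p))
  expect_equal(raw$p_adjusted, raw$p)
  expect_true(all(bon$p_adjusted >= raw$p_adjusted))
})
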