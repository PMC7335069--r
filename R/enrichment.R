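# Median-rank permutation machinery for ranked gene lists: genome-wide and
# within-chromosome set tests, chromosome profiles, the most-extreme-
# chromosome test, dosage-sensitivity tests, rank-decile analysis and
# set-size sensitivity curves.
#
# All p-values use the add-one estimator (1 + #extreme) / (n_perm + 1), so a
# permutation p can never be 0 and has floor 1 / (n_perm + 1). One-sided
# directions are declared a priori from the CNV sign: a dosage gain is
# expected to push its gene set toward HIGH ranks, a loss toward LOW ranks.

# Internal: centered ranks of a ranked_genes tibble, named by gene.
centered_ranks <- function(ranked_list) {
  stats::setNames(ranked_list$centered_rank, ranked_list$gene)
}

# Internal: members of a gene_set or plain character vector.
set_members <- function(x) if (inherits(x, "gene_set")) x$members else as.character(x)

#' Median centered rank of a gene set
#'
#' @param ranked_list A `ranked_genes` tibble from [rank_genes()].
#' @param gene_set A `gene_set` or character vector of gene labels.
#' @return The median of the members' centered ranks (midpoint for even
#'   cardinality).
#' @export
median_rank <- function(ranked_list, gene_set) {
  cr <- centered_ranks(ranked_list)
  members <- set_members(gene_set)
  hit <- members %in% names(cr)
  if (!any(hit)) {
    nv_abort(paste0("gene set has no genes in the ranked list; missing: ",
                    paste(head(members, 5), collapse = ", ")),
             "nv_empty_intersection")
  }
  median(cr[members[hit]])
}

# Internal: sample `n_perm` medians of size-m draws without replacement from
# a pool of centered ranks.
null_median_sample <- function(pool, m, n_perm) {
  vapply(seq_len(n_perm),
         function(i) median(pool[sample.int(length(pool), m)]),
         numeric(1))
}

# Internal: medians of all size-m subsets of a pool (exhaustive null).
exhaustive_median_sample <- function(pool, m) {
  utils::combn(pool, m, median)
}

#' Genome-wide random-set median rank test (P_RAND-Trans)
#'
#' Compares an observed gene-set median centered rank to medians of
#' size-matched gene sets sampled uniformly without replacement from the
#' whole ranked list.
#'
#' @param ranked_list A `ranked_genes` tibble.
#' @param set_size Size of the gene set being tested.
#' @param observed Observed median centered rank (see [median_rank()]).
#' @param direction `"high"` (dosage gain), `"low"` (loss) or
#'   `"two_sided"`. Must be declared a priori.
#' @param n_perm Number of random sets (default 10000).
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate all size-`set_size` subsets and
#'   report the exact tail probability (no add-one correction); only
#'   feasible for small lists.
#' @return A `perm_test` object.
#' @export
p_rand_trans <- function(ranked_list, set_size, observed, direction,
                         n_perm = 10000L, seed = 1L, exhaustive = FALSE) {
  if (missing(direction) || is.null(direction)) {
    nv_abort("`direction` must be declared a priori from the CNV sign.",
             "nv_bad_argument")
  }
  pool <- ranked_list$centered_rank
  if (set_size >= length(pool)) {
    nv_abort("set_size must be smaller than the ranked list.", "nv_bad_argument")
  }
  if (exhaustive) {
    null <- exhaustive_median_sample(pool, set_size)
    n_ex <- length(null)
    extreme <- switch(direction,
                      high = sum(null >= observed),
                      low = sum(null <= observed),
                      two_sided = sum(abs(null) >= abs(observed)))
    out <- new_perm_test("median centered rank (trans)", observed, null,
                         direction, n_ex, seed)
    out$p <- extreme / n_ex
    return(out)
  }
  null <- with_seed(seed, null_median_sample(pool, set_size, n_perm))
  new_perm_test("median centered rank (trans)", observed, null, direction,
                n_perm, seed)
}

#' Within-chromosome random-set median rank test (P_RAND-Cis)
#'
#' As [p_rand_trans()], but null sets are resampled only from the genes of
#' the CNV's own chromosome, a stricter null for subchromosomal CNVs.
#'
#' @inheritParams p_rand_trans
#' @param chromosome_genes Gene labels of the host chromosome.
#' @return A `perm_test` object.
#' @export
p_rand_cis <- function(ranked_list, chromosome_genes, set_size, observed,
                       direction, n_perm = 10000L, seed = 1L) {
  cr <- centered_ranks(ranked_list)
  chromosome_genes <- set_members(chromosome_genes)
  pool <- cr[intersect(chromosome_genes, names(cr))]
  if (set_size >= length(pool)) {
    nv_abort("set_size must be smaller than the chromosome gene count.",
             "nv_bad_bound")
  }
  null <- with_seed(seed, null_median_sample(unname(pool), set_size, n_perm))
  new_perm_test("median centered rank (cis)", observed, null, direction,
                n_perm, seed)
}

#' Convenience wrapper: median-rank test of a gene set
#'
#' Computes the observed median centered rank of `gene_set` and runs
#' [p_rand_trans()] (or [p_rand_cis()] when `chromosome_genes` is given).
#'
#' @inheritParams p_rand_trans
#' @param gene_set A `gene_set` or character vector.
#' @param chromosome_genes Optional chromosome gene pool for the cis variant.
#' @return A `perm_test` object.
#' @export
p_rand <- function(ranked_list, gene_set, direction, n_perm = 10000L,
                   seed = 1L, chromosome_genes = NULL, exhaustive = FALSE) {
  members <- intersect(set_members(gene_set), ranked_list$gene)
  observed <- median_rank(ranked_list, members)
  if (is.null(chromosome_genes)) {
    p_rand_trans(ranked_list, length(members), observed, direction,
                 n_perm = n_perm, seed = seed, exhaustive = exhaustive)
  } else {
    p_rand_cis(ranked_list, chromosome_genes, length(members), observed,
               direction, n_perm = n_perm, seed = seed)
  }
}

#' Median centered rank per chromosome, with bootstrap standard errors
#'
#' @param ranked_list A `ranked_genes` tibble.
#' @param annotations Per-gene annotations with `gene` and `chromosome`
#'   (the pseudoautosomal region may appear as its own `PAR` label).
#' @param n_boot Bootstrap resamples over member genes (default 1000).
#' @param seed Integer seed.
#' @return A tibble `chromosome`, `n_genes`, `median_rank`, `se`.
#' @export
chromosome_rank_profile <- function(ranked_list, annotations, n_boot = 1000L,
                                    seed = 1L) {
  cr <- centered_ranks(ranked_list)
  annotations <- tibble::as_tibble(annotations)
  ann <- annotations[annotations$gene %in% names(cr), ]
  chroms <- unique(ann$chromosome)
  empty <- setdiff(unique(annotations$chromosome), chroms)
  if (length(empty)) {
    rlang::warn(paste0("chromosomes with no ranked genes omitted: ",
                       paste(empty, collapse = ", ")))
  }
  with_seed(seed, {
    purrr::map(chroms, function(ch) {
      v <- unname(cr[ann$gene[ann$chromosome == ch]])
      boot <- vapply(seq_len(n_boot),
                     function(i) median(v[sample.int(length(v), replace = TRUE)]),
                     numeric(1))
      tibble::tibble(chromosome = ch, n_genes = length(v),
                     median_rank = median(v), se = stats::sd(boot))
    }) |> purrr::list_rbind()
  })
}

#' Most-extreme-chromosome permutation test
#'
#' Tests whether the target chromosome's gene set occupies the most extreme
#' median rank of all chromosomes, in the direction declared a priori from
#' the CNV sign. The statistic is the margin of extremeness: the target's
#' median centered rank minus the most extreme other-chromosome median
#' (sign-adjusted so that larger means more extreme in the stated
#' direction); a positive observed margin means the target is the single
#' most extreme chromosome. The null permutes gene ranks across the genome
#' and recomputes all chromosome medians.
#'
#' @inheritParams chromosome_rank_profile
#' @param target_chromosome Chromosome label of the CNV.
#' @param direction `"high"` (gain) or `"low"` (loss).
#' @param n_perm Number of rank permutations.
#' @return A `perm_test` with extra fields `chromosome` and
#'   `observed_most_extreme`.
#' @export
p_most_extreme_chromosome <- function(ranked_list, annotations,
                                      target_chromosome, direction,
                                      n_perm = 10000L, seed = 1L) {
  cr <- centered_ranks(ranked_list)
  annotations <- tibble::as_tibble(annotations)
  ann <- annotations[annotations$gene %in% names(cr), ]
  if (!target_chromosome %in% ann$chromosome) {
    nv_abort(sprintf("target chromosome '%s' absent.", target_chromosome),
             "nv_bad_argument")
  }
  if (length(unique(ann$chromosome)) < 2L) {
    nv_abort("need at least 2 chromosomes.", "nv_bad_argument")
  }
  sgn <- switch(direction, high = 1, low = -1,
                nv_abort("direction must be 'high' or 'low'.", "nv_bad_argument"))
  idx <- split(match(ann$gene, names(cr)), ann$chromosome)
  target <- which(names(idx) == target_chromosome)
  margin <- function(v) {
    med <- vapply(idx, function(ix) median(v[ix]), numeric(1))
    sgn * med[target] - max(sgn * med[-target])
  }
  v0 <- unname(cr)
  obs <- margin(v0)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) margin(sample(v0)), numeric(1)))
  new_perm_test("most-extreme-chromosome margin", obs, null, "high",
                n_perm, seed,
                extra = list(chromosome = target_chromosome,
                             direction_declared = direction,
                             observed_most_extreme = obs > 0))
}

#' Omnibus probability across independent CNV results
#'
#' Joint null by simultaneous independent permutations: the omnibus p is the
#' add-one probability that every CNV's permuted statistic is at least as
#' extreme (in its own declared direction) as its observed statistic in the
#' same joint permutation. With independent uniform marginals this
#' approaches the product of the marginal p-values.
#'
#' @param per_cnv_results A list of >= 2 `perm_test` objects with equal
#'   `n_perm` and independently drawn nulls.
#' @return A `perm_test` object for the joint event.
#' @export
omnibus_p <- function(per_cnv_results) {
  if (length(per_cnv_results) < 2L) {
    nv_abort("need at least 2 results for an omnibus test.", "nv_bad_argument")
  }
  n_perm <- unique(vapply(per_cnv_results, function(r) r$n_perm, numeric(1)))
  if (length(n_perm) != 1L) {
    nv_abort("all results must share the same n_perm.", "nv_bad_argument")
  }
  hit <- purrr::map(per_cnv_results, function(r) {
    switch(r$direction,
           high = r$null_sample >= r$observed,
           low = r$null_sample <= r$observed,
           two_sided = abs(r$null_sample) >= abs(r$observed))
  })
  joint <- Reduce(`&`, hit)
  out <- new_perm_test("omnibus joint extremeness", 1, as.numeric(joint),
                       "high", n_perm, per_cnv_results[[1]]$seed)
  out$p <- (1 + sum(joint)) / (n_perm + 1)
  out
}

#' DS vs nDS median rank difference test
#'
#' Statistic: `median(DS centered ranks) - median(nDS centered ranks)`;
#' null by permuting the DS/nDS labels over the union's rank positions.
#'
#' @inheritParams p_rand_trans
#' @param ds_set,nds_set Disjoint `gene_set`s (or character vectors) of
#'   dosage-sensitive and non-dosage-sensitive genes.
#' @param direction Default `"two_sided"`.
#' @param exhaustive If `TRUE`, enumerate all label assignments (exact p,
#'   no add-one); feasible only for small unions.
#' @return A `perm_test` object.
#' @export
ds_nds_median_test <- function(ranked_list, ds_set, nds_set,
                               direction = "two_sided", n_perm = 10000L,
                               seed = 1L, exhaustive = FALSE) {
  cr <- centered_ranks(ranked_list)
  ds <- intersect(set_members(ds_set), names(cr))
  nds <- intersect(set_members(nds_set), names(cr))
  if (!length(ds) || !length(nds)) {
    nv_abort("both gene sets must intersect the ranked list.",
             "nv_empty_intersection")
  }
  if (length(intersect(ds, nds))) {
    nv_abort("DS and nDS sets overlap.", "nv_bad_argument")
  }
  pool <- unname(cr[c(ds, nds)])
  n_ds <- length(ds)
  obs <- median(pool[seq_len(n_ds)]) - median(pool[-seq_len(n_ds)])
  if (exhaustive) {
    picks <- utils::combn(length(pool), n_ds)
    null <- apply(picks, 2, function(ix) median(pool[ix]) - median(pool[-ix]))
    out <- new_perm_test("DS - nDS median rank difference", obs, null,
                         direction, ncol(picks), seed)
    extreme <- switch(direction,
                      high = sum(null >= obs), low = sum(null <= obs),
                      two_sided = sum(abs(null) >= abs(obs)))
    out$p <- extreme / ncol(picks)
    return(out)
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sh <- sample(pool)
    median(sh[seq_len(n_ds)]) - median(sh[-seq_len(n_ds)])
  }, numeric(1)))
  new_perm_test("DS - nDS median rank difference", obs, null, direction,
                n_perm, seed)
}

#' Rank-decile enrichment of DS vs nDS genes
#'
#' Deciles are defined on the full ranked list (decile 1 = most positive PLS
#' weights). For each decile the statistic is the difference between the
#' within-set proportions of DS and nDS genes falling in it; per-decile
#' two-sided p-values come from permuting the DS/nDS labels over the union.
#'
#' @inheritParams ds_nds_median_test
#' @return A `decile_table` tibble: `decile`, `n_ds`, `n_nds`,
#'   `proportion_ds`, `proportion_nds`, `difference`, `p`.
#' @export
decile_enrichment <- function(ranked_list, ds_set, nds_set, n_perm = 10000L,
                              seed = 1L) {
  n <- nrow(ranked_list)
  decile_of <- ceiling(ranked_list$rank * 10 / n)
  names(decile_of) <- ranked_list$gene
  ds <- intersect(set_members(ds_set), ranked_list$gene)
  nds <- intersect(set_members(nds_set), ranked_list$gene)
  if (!length(ds) || !length(nds)) {
    nv_abort("both gene sets must intersect the ranked list.",
             "nv_empty_intersection")
  }
  if (length(intersect(ds, nds))) {
    nv_abort("DS and nDS sets overlap.", "nv_bad_argument")
  }
  union_dec <- unname(decile_of[c(ds, nds)])
  n_ds <- length(ds); n_nds <- length(nds)
  props <- function(dec, take_ds) {
    counts_ds <- tabulate(dec[take_ds], nbins = 10L)
    counts_nds <- tabulate(dec[!take_ds], nbins = 10L)
    counts_ds / n_ds - counts_nds / n_nds
  }
  is_ds <- seq_along(union_dec) <= n_ds
  obs_diff <- props(union_dec, is_ds)
  null_diff <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) props(union_dec, sample(is_ds)),
           numeric(10))
  })
  pvals <- vapply(1:10, function(d) {
    (1 + sum(abs(null_diff[d, ]) >= abs(obs_diff[d]))) / (n_perm + 1)
  }, numeric(1))
  counts_ds <- tabulate(union_dec[is_ds], nbins = 10L)
  counts_nds <- tabulate(union_dec[!is_ds], nbins = 10L)
  prop_ds <- counts_ds / n_ds
  prop_nds <- counts_nds / n_nds
  out <- tibble::tibble(
    decile = 1:10,
    n_ds = counts_ds,
    n_nds = counts_nds,
    proportion_ds = prop_ds,
    proportion_nds = prop_nds,
    difference = obs_diff,
    p = pvals
  )
  structure(out, class = c("decile_table", class(out)),
            n_perm = n_perm, seed = seed)
}

#' Extract the extreme-ranked dosage-sensitive subset (DS^SS)
#'
#' DS genes lying in deciles whose DS/nDS proportion difference is
#' significant at the given threshold.
#'
#' @param decile_table A `decile_table` from [decile_enrichment()].
#' @param ds_set The DS `gene_set` (or character vector).
#' @param ranked_list The `ranked_genes` tibble the deciles were defined on.
#' @param alpha Per-decile significance threshold (default 0.05).
#' @return A `gene_set` with provenance `DSSS` (empty, with a warning, when
#'   no decile is significant).
#' @export
extract_dsss <- function(decile_table, ds_set, ranked_list, alpha = 0.05) {
  sig <- decile_table$decile[decile_table$p < alpha]
  ds <- intersect(set_members(ds_set), ranked_list$gene)
  if (!length(sig)) {
    rlang::warn("no significant decile; DS^SS is empty.")
    return(structure(list(name = "DSSS", members = character(0),
                          provenance = "DSSS", description = ""),
                     class = "gene_set"))
  }
  dec <- ceiling(ranked_list$rank * 10 / nrow(ranked_list))
  names(dec) <- ranked_list$gene
  members <- ds[dec[ds] %in% sig]
  structure(list(name = "DSSS", members = members, provenance = "DSSS",
                 description = sprintf("DS genes in significant decile(s) %s",
                                       paste(sig, collapse = ","))),
            class = "gene_set")
}

#' Set-size sensitivity of the median-rank test
#'
#' For each requested size, draws subsamples from a donor gene set (e.g. the
#' X chromosome), takes the median of the subsample medians as the observed
#' statistic, and compares it to medians of size-matched random pulls from
#' the whole ranked list.
#'
#' @inheritParams p_rand_trans
#' @param donor_genes Gene labels of the donor set to subsample.
#' @param sizes Integer vector of subsample sizes (within `(0, |donor|]`).
#' @param n_draws Draws per size for both subsamples and null pulls
#'   (default 10000).
#' @return A tibble `size`, `observed`, `p`.
#' @export
set_size_sensitivity <- function(ranked_list, donor_genes, sizes,
                                 direction, n_draws = 10000L, seed = 1L) {
  cr <- centered_ranks(ranked_list)
  donor <- unname(cr[intersect(set_members(donor_genes), names(cr))])
  pool <- ranked_list$centered_rank
  if (any(sizes < 1L) || any(sizes > length(donor))) {
    nv_abort("sizes must lie within (0, |donor set|].", "nv_bad_bound")
  }
  with_seed(seed, {
    purrr::map(sizes, function(s) {
      sub_meds <- if (s == length(donor)) {
        median(donor)
      } else {
        median(vapply(seq_len(n_draws),
                      function(i) median(donor[sample.int(length(donor), s)]),
                      numeric(1)))
      }
      null <- null_median_sample(pool, s, n_draws)
      p <- switch(direction,
                  high = (1 + sum(null >= sub_meds)) / (n_draws + 1),
                  low = (1 + sum(null <= sub_meds)) / (n_draws + 1),
                  two_sided = (1 + sum(abs(null) >= abs(sub_meds))) / (n_draws + 1))
      tibble::tibble(size = s, observed = sub_meds, p = p)
    }) |> purrr::list_rbind()
  })
}

#' Summarize a batch of permutation tests, optionally Bonferroni-corrected
#'
#' Permutation p-values are reported uncorrected by default (the add-one
#' estimator already bounds them away from 0); the Bonferroni option
#' reproduces a corrected-threshold summary across a family of CNV tests.
#'
#' @param results A named list of `perm_test` objects.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param alpha Significance threshold applied to the (possibly corrected)
#'   p-values (default 0.05).
#' @return A tibble: one row per test with `p`, `p_adjusted`, `significant`.
#' @export
enrichment_summary <- function(results, correction = c("none", "bonferroni"),
                               alpha = 0.05) {
  correction <- match.arg(correction)
  p <- vapply(results, function(r) r$p, numeric(1))
  p_adj <- stats::p.adjust(p, method = if (correction == "none") "none" else "bonferroni")
  tibble::tibble(
    test = names(results) %||% paste0("test", seq_along(results)),
    statistic = vapply(results, function(r) r$statistic, character(1)),
    observed = vapply(results, function(r) r$observed, numeric(1)),
    direction = vapply(results, function(r) r$direction, character(1)),
    p = unname(p),
    p_adjusted = unname(p_adj),
    significant = unname(p_adj < alpha)
  )
}

#' Plot a rank-decile enrichment table
#'
#' @param object A `decile_table`.
#' @param alpha Significance threshold to mark (default 0.05).
#' @param ... Unused.
#' @return A ggplot bar chart of per-decile DS - nDS proportion differences,
#'   significant deciles filled.
#' @export
autoplot.decile_table <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), significant = .data$p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                   y = .data$difference,
                                   fill = .data$significant)) +
    ggplot2::geom_col(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey80",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank decile (1 = most positive PLS weights)",
                  y = "DS - nDS proportion difference")
}
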