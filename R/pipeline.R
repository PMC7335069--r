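# End-to-end pipeline orchestration on synthetic data: simulate inputs,
# build MSNs, fit the dosage contrast, rank genes by PLS, run the
# enrichment battery, derive cell-class maps, spin-validate map comparisons
# and fit the individual-coupling component. Every stage's seed derives
# deterministically from the run seed, so a rerun with the same
# configuration is numerically identical.

#' Pipeline run configuration
#'
#' @param n_per_hemisphere Regions per hemisphere (default 152).
#' @param design `"case_control"` or `"aneuploidy"`.
#' @param n_cases,n_controls Cohort sizes (defaults from
#'   [generate_cohort()]).
#' @param effect_size Planted anatomical effect (default 1).
#' @param cnv A [cnv_specification()].
#' @param n_genes,n_donors Atlas dimensions.
#' @param n_perm Permutations for enrichment tests (default 1000).
#' @param n_spins Spin rotations (default 1000).
#' @param brain_expressed_filter Restrict the cell screen to brain-expressed
#'   genes (default TRUE, as in the screen's contract).
#' @param with_cells Run the cell-class stage (default TRUE).
#' @param with_individual Run the individual-coupling stage (requires the
#'   aneuploidy design; default matches `design`).
#' @param seed Run seed; every stochastic stage derives its own stream from
#'   it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_per_hemisphere = 152L,
                       design = c("case_control", "aneuploidy"),
                       n_cases = NULL, n_controls = NULL, effect_size = 1,
                       cnv = cnv_specification(), n_genes = 2000L,
                       n_donors = 6L, n_perm = 1000L, n_spins = 1000L,
                       brain_expressed_filter = TRUE, with_cells = TRUE,
                       with_individual = NULL, seed = 1L) {
  design <- match.arg(design)
  structure(list(
    n_per_hemisphere = n_per_hemisphere, design = design,
    n_cases = n_cases %||% if (design == "aneuploidy") 55L else 30L,
    n_controls = n_controls %||% if (design == "aneuploidy") 20L else 30L,
    effect_size = effect_size, cnv = cnv, n_genes = n_genes,
    n_donors = n_donors, n_perm = n_perm, n_spins = n_spins,
    brain_expressed_filter = brain_expressed_filter, with_cells = with_cells,
    with_individual = with_individual %||% (design == "aneuploidy"),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full transcriptional-vulnerability pipeline on synthetic data
#'
#' Executes simulate -> MSN construction -> dosage contrast -> PLS gene
#' ranking -> median-rank enrichment (set, cis, chromosome profile,
#' most-extreme chromosome), DS/nDS and decile analysis with DS^SS
#' extraction -> cell-class maps and CNV screen -> spin-validated map
#' comparisons -> individual coupling (aneuploidy designs). Optionally
#' writes all tabular outputs and a JSON manifest to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A named list with every stage's result plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  res <- list(config = config)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      nv_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "nv_stage_error")
    })
  }

  res$geometry <- stage("geometry",
    generate_geometry(config$n_per_hemisphere, seed = seed))
  atl <- stage("atlas",
    generate_expression_atlas(res$geometry, n_genes = config$n_genes,
                              n_donors = config$n_donors,
                              cnv_spec = config$cnv, seed = seed))
  res$atlas <- atl$atlas
  manifest <- atl$manifest
  sigs <- NULL
  if (config$with_cells) {
    # extend the atlas with cell-signature genes before ranking, so the
    # cell screen and the CNV enrichment share one gene universe
    sigs <- stage("signatures",
      generate_cell_signatures(res$atlas, manifest,
                               seed = derive_seed(seed, "cells")))
    res$atlas <- sigs$atlas
    manifest <- sigs$manifest
  }
  res$cohort <- stage("cohort",
    generate_cohort(res$geometry, manifest, design = config$design,
                    n_cases = config$n_cases, n_controls = config$n_controls,
                    effect_size = config$effect_size, seed = seed))

  res$ms <- stage("msn", compute_cohort_ms(res$cohort))
  covs <- cohort_covariates(res$cohort)
  model <- if (config$design == "aneuploidy") "aneuploidy" else "case_control"
  res$change_map <- stage("contrast",
    fit_regional_contrast(res$ms, covs, model = model))

  res$pls <- stage("pls", fit_pls_component(res$atlas, res$change_map))
  res$ranked <- rank_genes(res$pls)

  cnv_set <- gene_set(manifest$cnv$name, manifest$cnv$genes,
                      provenance = "chromosome")
  direction <- if (manifest$cnv$type == "gain") "high" else "low"
  res$enrichment <- stage("enrich", list(
    p_rand_trans = p_rand(res$ranked, cnv_set, direction = direction,
                          n_perm = config$n_perm,
                          seed = derive_seed(seed, "trans")),
    p_rand_cis = p_rand(res$ranked, cnv_set, direction = direction,
                        n_perm = config$n_perm,
                        seed = derive_seed(seed, "cis"),
                        chromosome_genes = res$atlas$annotations$gene[
                          res$atlas$annotations$chromosome ==
                            manifest$cnv$chromosome]),
    chromosome_profile = chromosome_rank_profile(
      res$ranked, res$atlas$annotations, n_boot = 200,
      seed = derive_seed(seed, "boot")),
    most_extreme = p_most_extreme_chromosome(
      res$ranked, res$atlas$annotations, manifest$cnv$chromosome,
      direction = direction, n_perm = config$n_perm,
      seed = derive_seed(seed, "extreme"))
  ))

  ds <- gene_set("DS", manifest$ds_flags$ds, provenance = "DS")
  nds <- gene_set("nDS", manifest$ds_flags$nds, provenance = "nDS")
  res$ds_nds <- stage("ds_nds", ds_nds_median_test(
    res$ranked, ds, nds, n_perm = config$n_perm,
    seed = derive_seed(seed, "dsnds")))
  res$deciles <- stage("deciles", decile_enrichment(
    res$ranked, ds, nds, n_perm = config$n_perm,
    seed = derive_seed(seed, "decile")))
  res$dsss <- extract_dsss(res$deciles, ds, res$ranked)

  res$spins <- stage("spin",
    generate_spins(res$geometry, config$n_spins,
                   seed = derive_seed(seed, "spin")))
  if (length(res$dsss$members)) {
    de_map <- differential_expression_map(res$atlas, res$dsss, nds)
    full_map <- stats::setNames(rep(0, nrow(res$geometry)),
                                res$geometry$region)
    full_map[names(de_map)] <- de_map
    mirror <- sub("^L", "R", names(de_map))
    full_map[mirror[mirror %in% names(full_map)]] <- de_map
    res$dsss_vs_change <- p_spin(res$change_map,
                                 full_map[res$geometry$region], res$spins)
  }

  if (config$with_cells) {
    res$cell_matrix <- cell_by_region_matrix(res$atlas, sigs$signatures)
    res$cell_clusters <- stage("cluster", cluster_cell_signatures(
      res$cell_matrix, max_k = 10L, seed = derive_seed(seed, "gap")))
    res$cell_assignment <- assign_cell_classes(
      res$cell_clusters, attr(res$cell_matrix, "signatures"))
    res$cell_maps <- cell_class_maps(res$cell_matrix, res$cell_assignment)
    class_sets <- split(
      unlist(purrr::map(attr(res$cell_matrix, "signatures"), "genes")),
      rep(res$cell_assignment$class_assignment,
          lengths(purrr::map(attr(res$cell_matrix, "signatures"), "genes"))))
    class_sets <- class_sets[!is.na(names(class_sets))]
    res$cell_screen <- stage("screen", cnv_cell_screen(
      res$ranked, class_sets, cnv_set, res$atlas$annotations,
      n_perm = config$n_perm, seed = derive_seed(seed, "screen")))
  }

  if (config$with_individual) {
    ie <- stage("individual", generate_individual_expression(
      res$cohort, manifest, seed = derive_seed(seed, "indiv")))
    manifest <- ie$manifest
    ez <- scale_within_group(ie$expression, ie$groups)
    mz <- scale_within_group(ie$ms, ie$groups)
    res$individual <- list(
      significance = component_significance(
        ez, mz, groups = ie$groups, n_perm = config$n_perm,
        seed = derive_seed(seed, "indivperm")),
      coupling = loadings_vs_changemap(
        ez, mz, res$change_map, res$spins, n_boot = 200,
        seed = derive_seed(seed, "indivboot"))
    )
  }

  res$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Internal: serialize the pipeline's tabular outputs and a JSON summary.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_geometry_tsv(res$geometry, file.path(out_dir, "geometry.tsv"))
  write_cohort_tsv(res$cohort, file.path(out_dir, "cohort.tsv"))
  readr::write_tsv(res$ms, file.path(out_dir, "regional_ms.tsv"))
  readr::write_tsv(tibble::as_tibble(res$change_map),
                   file.path(out_dir, "change_map.tsv"))
  readr::write_tsv(tibble::as_tibble(res$ranked),
                   file.path(out_dir, "ranked_genes.tsv"))
  readr::write_tsv(res$enrichment$chromosome_profile,
                   file.path(out_dir, "chromosome_profile.tsv"))
  readr::write_tsv(tibble::as_tibble(res$deciles),
                   file.path(out_dir, "decile_table.tsv"))
  write_matrix_tsv(res$atlas$expr, file.path(out_dir, "atlas_z.tsv"),
                   label_header = "region")
  summary <- list(
    seed = res$config$seed,
    design = res$config$design,
    cnv = res$manifest$cnv[c("name", "chromosome", "type", "coupling_r")],
    p_rand_trans = res$enrichment$p_rand_trans$p,
    p_rand_cis = res$enrichment$p_rand_cis$p,
    p_most_extreme = res$enrichment$most_extreme$p,
    observed_most_extreme = res$enrichment$most_extreme$observed_most_extreme,
    ds_nds_p = res$ds_nds$p,
    significant_deciles = res$deciles$decile[res$deciles$p < 0.05],
    dsss = res$dsss$members,
    individual_p = if (!is.null(res$individual)) res$individual$significance$p,
    individual_r = if (!is.null(res$individual)) res$individual$coupling$r,
    cell_k = if (!is.null(res$cell_clusters)) res$cell_clusters$k
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
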