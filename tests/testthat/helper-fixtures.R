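# Shared fixtures, built once per test run. Sizes are kept small; the
# statistically heavy checks live in test-acceptance.R.

geom_small <- generate_geometry(20, seed = 1)
geom_std <- generate_geometry(152, seed = 1)

# a small planted atlas + manifest shared by atlas/pls/enrichment tests
atlas_fix <- generate_expression_atlas(
  geom_small, n_genes = 300, n_donors = 4, k_factors = 12,
  cnv_spec = cnv_specification(size = 20, n_ds = 8, n_dsss = 6), seed = 42
)

# a tiny case-control cohort on the small geometry
cohort_fix <- generate_cohort(geom_small, atlas_fix$manifest,
                              design = "case_control",
                              n_cases = 8, n_controls = 8, seed = 7)

# random region-by-feature table for one subject
random_features <- function(n_regions, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      region = sprintf("r%02d", seq_len(n_regions)),
      CT = rnorm(n_regions, 2.5, 0.3), SA = rnorm(n_regions, 500, 90),
      GM = rnorm(n_regions, 1500, 250), MC = rnorm(n_regions, 0.12, 0.02),
      IC = rnorm(n_regions, 0.05, 0.01)
    )
  })
}

# a ranked list with prescribed weights (gene labels g001..)
ranked_from_weights <- function(w) {
  names(w) <- sprintf("g%03d", seq_along(w))
  fit <- structure(list(w1 = w, genes = names(w)), class = "pls_fit")
  rank_genes(fit)
}
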