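# neurovuln

Transcriptional vulnerability mapping from morphometric similarity networks.

Gene-dosage disorders (trisomy 21, sex-chromosome aneuploidies,
subchromosomal deletions) reshape cortical anatomy in regionally specific
ways. The *transcriptional vulnerability model* predicts that the regions
whose anatomy changes most in carriers of a copy-number variant (CNV) are
the regions that most strongly express the CNV's genes in health.
`neurovuln` implements the full analytic chain for testing this prediction,
for imaging-transcriptomics researchers who want each stage as a tested,
reusable function:

- **Morphometric similarity networks (MSNs)** — per subject, z-score five
  regional features (CT, SA, GM, MC, IC) across regions and correlate
  regional feature profiles; *regional MS* of region *i* is its mean edge
  weight,
  `MS_i = mean_{j != i} cor(z_i, z_j)`.
- **Dosage-contrast change maps** — per-region OLS,
  `MS_i ~ 1 + age + sex + Xan + Yan` (aneuploidy) or
  `MS_i ~ 1 + age + sex + Dx` (case–control), keeping the dosage
  coefficient's two-sided T statistic (patient − control), plus edge-level
  models and the four-class edge-effect taxonomy (hypercoupling,
  dedifferentiation, decoupling, hyperdifferentiation).
- **SIMPLS gene ranking** — first partial-least-squares component between a
  z-scored region × gene expression atlas and the change map
  (`T1 = X0 w1`, `U1 = Y0 q1`, covariance of scores maximal), polarity fixed
  so rank 1 is the gene most over-expressed where MS increases.
- **Median-rank permutation enrichment** — `P_RAND-Trans` / `P_RAND-Cis`
  null sets drawn genome-wide or within-chromosome, chromosome profiles with
  bootstrap SEs, a most-extreme-chromosome test, omnibus p across CNVs,
  DS/nDS dosage-sensitivity tests, rank-decile analysis with DS^SS
  extraction, and set-size sensitivity curves. All p-values use the add-one
  estimator.
- **Cell-class decoding** — signature-by-region median expression matrices,
  gap-statistic hierarchical clustering, label-concordant class assignment
  with nesting checks, inverse-distance weighted class expression maps, and
  a CNV-by-cell-class screen on brain-expressed genes.
- **Spin tests** — hemisphere-preserving spherical rotation nulls for
  map-to-map correlations.
- **Individual coupling** — subject-level SIMPLS between carrier expression
  panels and regional MS, with permutation significance, spin-validated
  region loadings and a subject bootstrap.
- **Synthetic data** — generators for every input (spherical parcellation,
  donor-level expression atlas with a planted CNV coupling and DS^SS core,
  morphometry cohorts with a planted MS contrast, cell signatures with
  nested class structure, carrier expression panels), with the planted truth
  recorded in a manifest.

## Worked example

```r
library(neurovuln)

geom  <- generate_geometry(152, seed = 1)               # 304 regions
atl   <- generate_expression_atlas(geom, seed = 3)      # gain CNV, coupling 0.7
cohort <- generate_cohort(geom, atl$manifest, "case_control", seed = 5)

ms  <- compute_cohort_ms(cohort)
cmap <- fit_regional_contrast(ms, cohort_covariates(cohort), "case_control")
rl  <- rank_genes(fit_pls_component(atl$atlas, cmap))

p_rand(rl, atl$manifest$cnv$genes, direction = "high",
       n_perm = 1000, seed = 9)
#> Permutation test: median centered rank (trans)
#>   observed = 750.5, direction = high
#>   p = 0.000999 (1000 permutations, add-one estimator)
```

The CNV gene set's observed median centered rank (750.5 of a ±1000 scale)
sits far in the high tail: regions expressing the planted "gained" genes
lose morphometric similarity, so those genes end up with strongly negative
PLS weights, i.e. extreme high ranks, and no size-matched random gene set
among 1000 draws reaches that median (p at the permutation floor, 1/1001).

A single call runs the whole pipeline on synthetic data and serializes
every stage:

```r
res <- run_pipeline(run_config(design = "aneuploidy", seed = 7),
                    out_dir = "demo_run")
res$enrichment$most_extreme$p        # most-extreme-chromosome test
res$cell_clusters$k                  # gap-statistic cluster count
res$individual$coupling$r            # loadings vs change map
autoplot(res$change_map, res$geometry)
```

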