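---
title: "Transcriptional vulnerability mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional vulnerability mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

Gene-dosage disorders — aneuploidies such as trisomy 21 or a supernumerary
X chromosome, and subchromosomal deletions — change the anatomy of the
cerebral cortex in regionally specific ways. The transcriptional
vulnerability model holds that this regional specificity is not arbitrary:
cortical regions that, in health, most strongly express the genes inside a
copy-number variant (CNV) are the regions whose anatomy changes most when
the dosage of those genes changes. `neurovuln` implements the full analytic
chain needed to test this model, together with a synthetic-data generator
that plants every quantity the chain is supposed to recover.

The chain has six stages.

**1. Morphometric similarity networks (MSNs).** For each subject, five
regional morphometric features (cortical thickness CT in mm, surface area SA
in mm², gray-matter volume GM in mm³, mean curvature MC in 1/mm, intrinsic
curvature IC, dimensionless) are z-scored across regions within subject and
feature; the MSN edge between two regions is the Pearson correlation of
their five-feature profiles, and a region's *regional MS* (nodal similarity)
is its mean edge weight to all other regions. Two properties of this
construction matter for everything downstream: per-feature z-scoring removes
feature location and scale, and correlation removes profile scale — so only
the *orientation* of a region's feature profile carries signal, and the
regional-MS distribution is approximately zero-centered.

**2. Dosage-contrast change maps.** Regional MS is modelled per region by
ordinary least squares. The aneuploidy design regresses on age, sex and the
supernumerary X and Y counts (`xan`, `yan`); the case–control design on
age, sex and the binary diagnosis `dx`. The change map is the two-sided
T statistic of the dosage coefficient (patient − control polarity). Edges
can be modelled the same way, and each edge is classified by the sign pair
(control mean weight, edge T) into hypercoupling (+,+), dedifferentiation
(−,+), decoupling (+,−) or hyperdifferentiation (−,−); exact zeros go to the
positive branch — a measure-zero event on real data, fixed so tests are
deterministic.

**3. PLS gene ranking.** The change map (regions) is aligned with a
z-scored region × gene expression atlas by the first SIMPLS partial least
squares component: gene weights `w1` maximize the covariance between the
expression score `T1 = X0 w1` and the response score `U1 = Y0 q1`. Polarity
is fixed so that `T1` correlates non-negatively with the change map, making
rank 1 the gene most over-expressed where the anatomical statistic
increases. Genes are ranked by `w1`; for a univariate response the weights,
x-loadings and response-projected orderings coincide under this polarity, so
the choice of `w1` (rather than a response-side quantity, which is
region-indexed and cannot rank genes directly) is the only internally
consistent reading. Ranks are centred by subtracting (N+1)/2; ties are
broken lexicographically by gene label.

**4. Median-rank permutation enrichment.** The spatial correspondence of a
gene set with the change map is summarized by the median centred rank of its
members. Significance comes from permutation nulls with the add-one
estimator p = (1 + #extreme)/(n_perm + 1), so p is never 0 and has floor
1/(n_perm + 1): size-matched random sets drawn genome-wide (trans) or from
the CNV's own chromosome (cis). The test direction is declared a priori
from the CNV sign — a dosage gain is expected to push its genes toward high
ranks (under-expression where MS increases), a loss toward low ranks. The
most-extreme-chromosome test asks whether the CNV chromosome's median rank
is the most extreme of all chromosomes; its statistic is the *margin of
extremeness* (target median minus the most extreme other-chromosome median,
sign-adjusted), permuted over gene ranks. A literal "probability the target
is most extreme" null is data-independent (≈ 1/#chromosomes) and cannot
register the strength of an observed separation, so the margin form is used;
an `observed_most_extreme` flag reports the categorical claim itself. An
omnibus across CNVs is the joint probability, under simultaneous independent
permutations, that every CNV shows its observed direction-specific
extremeness; with independent uniform marginals this approaches the product
of the marginal p-values. Dosage-sensitivity (DS vs nDS) differences use the
median-rank difference with labels permuted over the union; the rank-decile
analysis tests per-decile differences in within-set proportions the same
way (label permutation is equivalent to rank permutation under
exchangeability and cheaper), and DS^SS is the DS subset lying in deciles
significant at 0.05. No multiple-testing correction is applied by default.

**5. Cell-class decoding.** Study-specific cell-type signature sets are
summarized as the median regional z-expression of their genes; signatures
are clustered by average-linkage agglomeration on correlation distance
(1 − Pearson between regional profiles), with the cluster count chosen by
the gap statistic (uniform-box reference, B = 50, Tibshirani's 1-SE rule).
Fine classes are then formed post hoc by cell-label concordance and checked
for nesting within the coarse clusters; labels that cannot be mapped to a
canonical class (undivided "Neuro", pericytes) are excluded. Within each
class, signature weights are proportional to the inverse distance (+1e-6)
to the class centroid in a PCA space retaining ≥ 95% of variance — the
distance-to-centroid construction leaves the distance-to-weight transform
open, and inverse distance is the simplest choice that down-weights
outlying study sets; it reduces to the plain mean when distances are equal.
The CNV-by-class screen runs on the brain-expressed subset of the ranked
list (re-ranked after filtering) and reports a (CNV, class) association when
the class set's median rank is significantly extreme (two-sided, since
classes carry no a-priori direction) *and* at least one brain-expressed CNV
gene inside the class set sits in the extreme 5% centiles.

**6. Spatial and individual-level validation.** Map-to-map correlations are
tested against the spin null: the left-hemisphere parcel sphere is rotated
by three uniform angles about x, y, z, the right hemisphere by (a, −b, −c)
to preserve mirror symmetry, and rotated parcels are matched back to
original parcels greedily, nearest-first in descending order of mean
Euclidean distance. Each spin is a hemisphere-preserving permutation, so a
spun map keeps its value multiset and spatial autocorrelation structure.
For carriers with both imaging and expression panels, expression and
regional MS are z-scored within karyotype group and coupled across subjects
by SIMPLS (the shared dimension is people); significance permutes the
expression block's subject rows — within karyotype groups, since
within-group centering leaves only within-group order exchangeable — against
the maximized score covariance, and
the component's region loadings are compared to the group change map with a
spin test and a subject bootstrap. The PLS polarity convention (score
vectors correlate non-negatively) leaves a joint sign free; it is pinned by
requiring a non-negative mean gene loading, which is the natural orientation
for a dosage-sensitive expression panel.

# The synthetic generator and what it emulates

All inputs are simulated with planted ground truth recorded in a manifest.

*Geometry.* Each hemisphere is a full unit sphere carrying a Fibonacci
lattice of parcel centroids (152 per hemisphere by default, mirroring the
bilateral parcellation scale of region-level imaging-transcriptomic work);
the right hemisphere is the exact mirror of the left. Per-hemisphere full
spheres match how spherical cortical-surface registrations are actually
parameterized and are what makes rotation-based matching meaningful.

*Smooth maps.* Regional maps are drawn from an orthonormalized polynomial
(spherical-harmonic) basis of degree ≤ 4 with coefficients shrinking by
degree, giving spatially autocorrelated maps — the regime the spin test
exists for. Orthonormalization matters: raw monomials are so ill-conditioned
that "independent" draws would collapse onto a handful of patterns.

*Atlas.* Donor-level expression follows a latent-factor model: background
genes carry independent region-wise profiles; CNV genes additionally load on
the smooth factor-1 gradient. The dosage-sensitive core (DS^SS, 12 of 14 DS
genes by default, loading 0.35) is planted extreme; the base loading of the
remaining CNV genes is solved in closed form so that the correlation between
the CNV set's mean regional expression and factor 1 equals the requested
`coupling_r` (0.7 by default) after donor-median noise attenuation
(homoscedastic Gaussian donor noise, sd 0.5, 6 donors; inter-donor variance
in real donor atlases is not well characterized, so the noise scale is an
exposed parameter). At `coupling_r = 0` every loading is zero and CNV genes
are exchangeable with the background — the property that makes the
permutation-calibration checks exact. Chromosome labels follow roughly
human-genome-shaped weights with the CNV chromosome smallest (as chromosome
21 is) and every chromosome large enough (~40+ genes) for a stable median
rank; tiny chromosomes would otherwise dominate the most-extreme test with
high-variance null medians, which is a property of the statistic, not of
the biology being emulated.

*Cohort.* Because regional MS only responds to profile orientation (stage 1
above), mean shifts on features cannot plant an MS contrast — per-feature
z-scoring and correlation's scale invariance annihilate them. The generator
therefore plants the effect through orientation: a small anchored set of
regions carries large opposite-direction profiles, pinning the
cohort-average normalized profile (the "consensus" every region's MS is
implicitly measured against) at a known positive alignment with a fixed
feature direction weighted toward GM and MC (the features that dominate MS
contrasts); the case effect then rotates each region's profile toward or
away from that consensus in proportion to
`effect_size × dose × sign × factor1(region)`, with dose = 1 for cases or
`xan + 0.6·yan` for aneuploidies, and sign negative for a gain (regions
expressing the CNV genes lose similarity). Rotation responds linearly in
this regime, so the expected regional-MS contrast follows the planted
gradient. Subjects also carry a stable smooth individual anatomy component
(`subject_anatomy_sd`, default 0.9 — individual anatomical variation is the
dominant variance source in real morphometry), which is what gives
subject-level MS deviations a smooth spatial structure — without it, the individual-coupling loadings could not
recover a smooth change map from ~50 subjects over 300 regions, a rank
ceiling, not an estimation artifact. Ages are uniform on [5, 25] years with
a small linear feature effect; sex is balanced with a small shift; both are
removed by the model covariates. Default cohort sizes are 30 + 30
(case–control) and 55 carriers + 20 controls (aneuploidy), sizes at which
the planted gradient is recovered with the margins the recovery checks
require. Zero-variance feature draws are retried with fresh noise.

*Cell signatures.* Class profiles are built from the atlas's own factor
maps: a coarse-cluster factor (3 coarse clusters by default) plus a small
class-specific component (`fine_sep = 0.04`), so 7 fine classes nest inside
3 coarse clusters. Fine classes are deliberately subordinate: study-level
signature noise (0.8 × `noise_sd`) and gene-level noise (`noise_sd`) sit at
or above the fine separation, which is exactly the regime in which the gap
statistic should return the coarse count while label concordance still
recovers the fine classes. Signature genes are appended to the atlas and
the donor stack is re-aggregated.

*Individual expression.* Each carrier's panel expression is a
karyotype-group mean plus `beta` times the subject's MS deviation score
along the planted change map plus noise (sd 0.3). The deviation score is
computed against the ridge-regularized MS covariance (λ = 20 × mean
diagonal); a raw projection would couple expression to the change map as
blurred by inter-regional MS covariance rather than to the map itself.

# What passing tests do and do not show

The generator emulates the *statistical structure* of the real inputs:
smooth expression gradients, donor noise, correlated five-feature
morphometry, group contrasts with covariates, karyotype structure, and
spatial autocorrelation. It does not emulate probe-level microarray
artifacts, sample-to-parcel assignment error, scanner/site effects,
hemispheric asymmetries of expression, non-Gaussian feature distributions,
or the positive-mean baseline alignment our anchored construction introduces
(real regional MS is zero-centered with structure arising from profile-
geometry asymmetries we only coarsely mimic). Passing recovery tests
therefore demonstrates that the *pipeline* is correct and calibrated under
a faithful null and a planted alternative — not that real MRI cohorts would
yield any particular effect size.

# Numerical choices and test design

- Sample (n−1) standard deviations everywhere z-scoring is done; the MSN
  diagonal is stored as `NA` so it can never leak into nodal means.
- Permutation p-values use the add-one estimator; exhaustive enumeration is
  available for tiny lists and used as the oracle in tests.
- The spin test's greedy parcel matching reproduces a rotated smooth map
  with fidelity ≈ 0.95 at 152 parcels per hemisphere, which makes the test
  mildly anticonservative (empirically ≈ 0.06–0.07 at α = 0.05) — an
  inherent property of parcel-level rotation nulls at this resolution, shared
  by the published procedure. Calibration is assessed against independently
  *oriented* copies of a smooth template: a rotation null cannot
  re-randomize harmonic coefficients within a degree subspace, so
  independent-coefficient harmonic maps are the wrong calibration ensemble
  for it.
- The gap statistic uses the uniform-box reference (`spaceH0 = "original"`,
  B = 50) and the 1-SE rule; linkage is average on correlation distance
  (the clustering criterion is stated in the field's work, the linkage is
  not — both are configurable).
- Heavy acceptance checks run at fixed problem sizes chosen once: 100 seeds
  for planted-signal recovery on the 152-per-hemisphere geometry with a
  2000-gene atlas, 50 seeds for cell-class recovery, 200 pairs and 1000
  spins for spatial calibration, 200 lean-cohort seeds for the
  individual-coupling null and 40 full-size seeds for its power. The P_RAND
  calibration (5000 replicates at 1000 permutations) draws its null ranked
  lists directly as uniform permutations: under `coupling_r = 0` the
  generator makes CNV genes exchangeable with the background by
  construction (asserted on the generator in the same test), so the
  reduction is exact rather than approximate.

# Known limitations

- The anchored-consensus cohort mechanism produces a positively shifted
  baseline MS distribution at the anchor regions and a mildly positive mean
  elsewhere; contrasts are unaffected but absolute MS levels should not be
  over-interpreted.
- The most-extreme-chromosome statistic is one defensible formalization of
  "most extreme of all chromosomes"; alternatives (e.g. rank-of-target
  among chromosomes) are less sensitive and not implemented.
- The omnibus joint-permutation p assumes the per-CNV ranked lists are
  independent, which holds for separate cohorts sharing no subjects but only
  approximately when CNVs share the expression atlas.
- Individual-coupling loadings can only recover the component of a change
  map lying in the span of the subjects' MS variation; with ~50 subjects
  this caps the attainable loading-map correlation well below 1 even at
  strong coupling.
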