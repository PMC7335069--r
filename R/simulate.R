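# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with planted, configurable ground truth recorded in a manifest:
# a smooth latent regional gradient (factor 1), a CNV gene set whose mean
# regional expression tracks that gradient at a requested correlation, a
# dosage-sensitive subset with an extreme-loading core (DS^SS), cell-class
# signature genes, a cohort whose regional-MS contrast follows the gradient
# with sign set by gain/loss, and subject-level expression coupled to
# individual MS deviation.

#' CNV specification for the synthetic atlas
#'
#' @param chromosome Host chromosome label (default `"21"`).
#' @param size Number of CNV genes (default 40).
#' @param type `"gain"` or `"loss"`; fixes the a-priori enrichment direction
#'   (gain pushes the set toward high ranks).
#' @param coupling_r Target correlation between the CNV set's mean regional
#'   expression and the latent gradient (factor 1), in `[-1, 1]`.
#' @param n_ds,n_dsss Sizes of the dosage-sensitive subset and of its
#'   extreme-loading core (DS^SS within DS). The remaining CNV genes are
#'   non-dosage-sensitive (nDS).
#' @param dsss_loading Factor-1 loading of DS^SS genes (default 0.35); the
#'   base loading of the other CNV genes is solved so the set-level
#'   `coupling_r` is realized in expectation.
#' @return A list of class `cnv_spec`.
#' @export
cnv_specification <- function(chromosome = "21", size = 40L,
                              type = c("gain", "loss"), coupling_r = 0.7,
                              n_ds = 14L, n_dsss = 12L, dsss_loading = 0.35) {
  type <- match.arg(type)
  if (abs(coupling_r) > 1) nv_abort("coupling_r must lie in [-1, 1].",
                                    "nv_config_error")
  if (n_ds > size || n_dsss > n_ds) {
    nv_abort("need n_dsss <= n_ds <= size.", "nv_config_error")
  }
  structure(list(chromosome = as.character(chromosome), size = as.integer(size),
                 type = type, coupling_r = coupling_r, n_ds = as.integer(n_ds),
                 n_dsss = as.integer(n_dsss), dsss_loading = dsss_loading),
            class = "cnv_spec")
}

# Internal: expected correlation between the mean of m unit-variance gene
# profiles with factor-1 loadings `l` and the factor itself, accounting for
# donor-median noise of variance v per gene.
expected_coupling <- function(l, v) {
  m <- length(l)
  lbar <- mean(l)
  msq <- mean(l^2)
  lbar / sqrt(lbar^2 + (1 - msq + v) / m)
}

# Internal: solve the base loading of non-DS^SS CNV genes so the set-level
# coupling matches `target`. When the DS^SS core alone already over-supplies
# the coupling, the core loading is scaled down instead.
solve_cnv_loadings <- function(spec, v) {
  m <- spec$size
  n_ss <- spec$n_dsss
  target <- abs(spec$coupling_r)
  if (target == 0) return(rep(0, m))
  make <- function(a, lss) c(rep(lss, n_ss), rep(a, m - n_ss))
  at_zero <- expected_coupling(make(0, spec$dsss_loading), v)
  if (at_zero >= target) {
    f <- function(s) expected_coupling(make(0, s), v) - target
    lss <- stats::uniroot(f, c(1e-6, spec$dsss_loading))$root
    return(make(0, lss))
  }
  f <- function(a) expected_coupling(make(a, spec$dsss_loading), v) - target
  if (f(0.99) < 0) nv_abort("coupling_r target unattainable.", "nv_config_error")
  a <- stats::uniroot(f, c(0, 0.99))$root
  make(a, spec$dsss_loading)
}

# Internal: left-hemisphere (or whole, if single-hemisphere) region subset.
lh_regions <- function(geometry) {
  if ("L" %in% geometry$hemi) geometry[geometry$hemi == "L", ] else geometry
}

#' Generate a donor-level regional expression atlas with planted structure
#'
#' Gene profiles follow a latent-factor model: smooth orthogonal factor maps
#' are built from a low-order spherical-harmonic (polynomial) basis of the
#' left-hemisphere parcel coordinates; CNV genes load on factor 1 so that
#' the set's mean regional expression correlates with the factor at the
#' requested strength (with the DS^SS core loading most strongly), while
#' background genes carry independent region-wise profiles. Donor matrices
#' add homoscedastic Gaussian noise; the analysis-ready atlas is the
#' median-then-z aggregation of the donors.
#'
#' @param geometry Parcellation from [generate_geometry()] (the atlas uses
#'   the left hemisphere, as regional expression resources are typically
#'   left-lateralized).
#' @param n_genes Number of genes (>= 10 * k_factors).
#' @param n_donors Number of donors (default 6).
#' @param k_factors Number of latent factor maps (default 12).
#' @param cnv_spec A [cnv_specification()].
#' @param donor_noise_sd Donor noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return A list: `atlas` (an `expression_atlas`) and `manifest` (a
#'   `nv_manifest` recording every planted quantity).
#' @export
generate_expression_atlas <- function(geometry, n_genes = 2000L,
                                      n_donors = 6L, k_factors = 12L,
                                      cnv_spec = cnv_specification(),
                                      donor_noise_sd = 0.5, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  if (n_genes < 10L * k_factors) {
    nv_abort("need n_genes >= 10 * k_factors.", "nv_config_error")
  }
  lh <- lh_regions(geometry)
  regions <- lh$region
  nr <- length(regions)
  genes <- sprintf("G%05d", seq_len(n_genes))
  m <- cnv_spec$size

  with_seed(derive_seed(seed, "atlas"), {
    # latent smooth factor maps over the full geometry (mirror-symmetric)
    Fall <- smooth_factor_maps(geometry_coords(geometry), k_factors)
    rownames(Fall) <- geometry$region
    F_lh <- Fall[regions, , drop = FALSE]

    # chromosome assignment: CNV genes form a contiguous block on the host
    # chromosome; the rest are spread over 1..22, X, Y
    # chromosome gene-count weights shaped like the human genome, with the
    # CNV host chromosome smallest (as chromosome 21 is) and every
    # chromosome large enough for a stable median rank
    chroms <- c(as.character(1:22), "X", "Y")
    chrom_w <- c(2000, 1300, 1100, 800, 900, 1000, 950, 700, 800, 750,
                 1300, 1050, 450, 650, 600, 850, 1200, 420, 1400, 550,
                 100, 450, 850, 420)
    names(chrom_w) <- chroms
    chrom_w[cnv_spec$chromosome] <- 100
    chromosome <- sample(chroms, n_genes, replace = TRUE,
                         prob = chrom_w / sum(chrom_w))
    cnv_idx <- seq_len(m)
    chromosome[cnv_idx] <- cnv_spec$chromosome
    # the host chromosome must extend beyond the CNV: top up with a few
    # background genes if the sampling left it bare
    extras <- setdiff(which(chromosome == cnv_spec$chromosome), cnv_idx)
    if (length(extras) < 5L) {
      if (n_genes < m + 5L) {
        nv_abort("CNV set would cover its whole chromosome; increase n_genes.",
                 "nv_config_error")
      }
      pool <- setdiff(seq_len(n_genes), c(cnv_idx, extras))
      chromosome[sample(pool, 5L - length(extras))] <- cnv_spec$chromosome
    }
    # positions: sequential per chromosome, CNV block first on its chromosome
    start <- integer(n_genes); end <- integer(n_genes)
    for (ch in unique(chromosome)) {
      ix <- which(chromosome == ch)
      if (ch == cnv_spec$chromosome) ix <- c(cnv_idx, setdiff(ix, cnv_idx))
      start[ix] <- 1000L * seq_along(ix)
      end[ix] <- start[ix] + 500L
    }
    brain <- runif(n_genes) < 0.6
    brain[cnv_idx] <- TRUE
    annotations <- tibble::tibble(gene = genes, chromosome = chromosome,
                                  start = start, end = end,
                                  brain_expressed = brain)

    # factor-1 loadings: zero for background genes; CNV genes solved so the
    # set mean tracks factor 1 at the target coupling after donor-median
    # noise attenuation
    v_med <- donor_noise_sd^2 * pi / (2 * n_donors)
    loadings <- rep(0, n_genes)
    cnv_l <- solve_cnv_loadings(cnv_spec, v_med) * sign(cnv_spec$coupling_r)
    loadings[cnv_idx] <- cnv_l

    idio <- matrix(rnorm(nr * n_genes), nr, n_genes)
    signal <- sweep(idio, 2, sqrt(1 - loadings^2), `*`) +
      F_lh[, 1] %*% t(loadings)
    dimnames(signal) <- list(regions, genes)
    donors <- purrr::map(seq_len(n_donors), function(d) {
      signal + donor_noise_sd * matrix(rnorm(nr * n_genes), nr, n_genes)
    })
    names(donors) <- paste0("donor", seq_len(n_donors))

    cnv_genes <- genes[cnv_idx]
    dsss <- cnv_genes[seq_len(cnv_spec$n_dsss)]
    ds <- cnv_genes[seq_len(cnv_spec$n_ds)]
    nds <- setdiff(cnv_genes, ds)
    manifest <- structure(list(
      seed = seed,
      regions = geometry$region,
      lh_regions = regions,
      factors = Fall,
      gene_loadings = stats::setNames(loadings, genes),
      cnv = list(name = paste0("cnv_chr", cnv_spec$chromosome),
                 chromosome = cnv_spec$chromosome,
                 type = cnv_spec$type,
                 genes = cnv_genes,
                 interval = c(start = 999, end = 1000 * m + 501),
                 coupling_r = cnv_spec$coupling_r,
                 # effect sign of the anatomical change along factor 1:
                 # a gain decreases MS where CNV genes are expressed
                 effect_sign = if (cnv_spec$type == "gain") -1 else 1),
      ds_flags = list(ds = ds, dsss = dsss, nds = nds),
      planted_classes = NULL,
      individual_beta = NULL
    ), class = "nv_manifest")
    list(atlas = aggregate_donor_expression(donors, annotations),
         manifest = manifest)
  })
}

#' @export
print.nv_manifest <- function(x, ...) {
  cat(sprintf("Synthetic ground-truth manifest (seed %d)\n", x$seed))
  cat(sprintf("  %d regions (%d LH), %d factors, CNV '%s' (%s, coupling %.2f)\n",
              length(x$regions), length(x$lh_regions), ncol(x$factors),
              x$cnv$name, x$cnv$type, x$cnv$coupling_r))
  invisible(x)
}

# Feature-level constants for the cohort generator: plausible means and
# scales per morphometric feature, and the injection direction weighted
# toward gray matter volume and mean curvature (the features that dominate
# MS contrasts).
FEATURE_MEANS <- c(CT = 2.5, SA = 500, GM = 1500, MC = 0.12, IC = 0.05)
FEATURE_SDS <- c(CT = 0.25, SA = 90, GM = 280, MC = 0.02, IC = 0.012)
feature_direction <- function(weights = c(CT = 0.3, SA = 0.3, GM = 1,
                                          MC = 1, IC = 0.45)) {
  g <- weights - mean(weights)
  g / sqrt(sum(g^2))
}

#' Generate a synthetic morphometry cohort with a planted MS contrast
#'
#' Regional MS is invariant to per-feature location and scale, so the
#' planted group effect is injected through profile orientation: baseline
#' region profiles have a right-skewed alignment with a fixed feature
#' direction (weighted toward GM and MC), which makes the cohort-average
#' normalized profile robustly nonzero along that direction; the case effect
#' then rotates each region's profile toward (or away from) it in proportion
#' to `effect_size * dose * sign * factor1(region)`. A region pushed toward
#' the consensus direction becomes more similar to all others, so the
#' expected case-control regional-MS contrast follows factor 1 with the
#' planted sign (negative for a gain: regions expressing the CNV genes lose
#' similarity). `dose` is 1 for cases in the case-control design, and
#' `xan + 0.6 * yan` in the aneuploidy design.
#'
#' @param geometry Parcellation tibble.
#' @param manifest Manifest from [generate_expression_atlas()].
#' @param design `"case_control"` or `"aneuploidy"`.
#' @param n_cases,n_controls Group sizes (>= 5).
#' @param effect_size Planted effect amplitude (0 = null; default 1).
#' @param noise_sd Subject feature noise (default 1, on the standardized
#'   construction scale).
#' @param subject_anatomy_sd Amplitude of each subject's stable smooth
#'   anatomy component (default 0.9); this is what gives individual MS
#'   deviations their spatial structure.
#' @param seed Integer seed.
#' @return A `cohort_table` tibble: one row per subject x region with
#'   covariates (`group`, `age`, `sex`, and `dx` or `xan`/`yan`) and the
#'   five feature columns.
#' @export
generate_cohort <- function(geometry, manifest,
                            design = c("case_control", "aneuploidy"),
                            n_cases = 30L, n_controls = 30L, effect_size = 1,
                            noise_sd = 1, subject_anatomy_sd = 0.9,
                            seed = 1L) {
  design <- match.arg(design)
  n_cases <- assert_count(n_cases, "n_cases", min = 5L)
  n_controls <- assert_count(n_controls, "n_controls", min = 5L)
  if (effect_size < 0) nv_abort("effect_size must be >= 0.", "nv_bad_argument")
  regions <- geometry$region
  nr <- length(regions)
  f1 <- manifest$factors[regions, 1]
  sgn <- manifest$cnv$effect_sign

  # fixed spatial structure shared across subjects: per-feature smooth maps
  # plus a right-skewed alignment map along the injection direction
  struct_parts <- with_seed(derive_seed(seed, "cohort-structure"), {
    maps <- random_smooth_maps(geometry_coords(geometry), 6L, symmetric = FALSE)
    list(feat = maps[, 1:5, drop = FALSE], skew_src = maps[, 6])
  })
  struct <- struct_parts$feat
  colnames(struct) <- MS_FEATURES
  # anchor construction: a small spatially clustered set of regions carries
  # large opposite-direction profiles, so the cohort-average normalized
  # profile (the consensus the effect rotates against) is pinned at a known
  # positive alignment; all other regions sit at a moderate alignment where
  # rotation responds linearly. The anchor magnitude balances the column
  # means exactly, so per-feature centering cannot remove the component.
  n_anchor <- max(8L, round(0.05 * nr))
  anchor <- rank(struct_parts$skew_src) <= n_anchor
  a_base <- rep(0.45, nr)
  a_base[anchor] <- -0.45 * (nr - n_anchor) / n_anchor
  g <- feature_direction()
  # keep the feature structure maps orthogonal to the injection direction so
  # the rotation gain is uniform across regions
  struct <- struct - tcrossprod(struct %*% g, g)

  if (design == "case_control") {
    subjects <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_cases + n_controls)),
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      dx = rep(c(1, 0), c(n_cases, n_controls))
    )
    dose <- subjects$dx
  } else {
    # supernumerary karyotypes for cases; XX/XY controls
    karyos <- data.frame(group = c("XXX", "XXY", "XYY", "XXYY"),
                         xan = c(1, 1, 0, 1), yan = c(0, 0, 1, 1),
                         sex = c("F", "M", "M", "M"))
    pick <- rep(seq_len(4), length.out = n_cases)
    ctrl <- data.frame(group = rep(c("XX", "XY"), length.out = n_controls),
                       xan = 0, yan = 0,
                       sex = rep(c("F", "M"), length.out = n_controls))
    subjects <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_cases + n_controls)),
      group = c(karyos$group[pick], ctrl$group),
      xan = c(karyos$xan[pick], ctrl$xan),
      yan = c(karyos$yan[pick], ctrl$yan)
    )
    dose <- subjects$xan + 0.6 * subjects$yan
  }

  with_seed(derive_seed(seed, "cohort"), {
    subjects$age <- runif(nrow(subjects), 5, 25)
    if (design == "case_control") {
      subjects$sex <- sample(rep(c("M", "F"), length.out = nrow(subjects)))
    } else {
      subjects$sex <- c(karyos$sex[pick], ctrl$sex)
    }
    sex_num <- as.numeric(subjects$sex == "M")

    subj_smooth <- random_smooth_maps(geometry_coords(geometry),
                                      nrow(subjects), symmetric = FALSE)
    rows <- purrr::map(seq_len(nrow(subjects)), function(i) {
      # alignment magnitude per region: anchored baseline, the planted
      # dose-dependent rotation along factor 1, and a stable smooth
      # individual anatomy component
      a_r <- a_base + effect_size * 0.42 * dose[i] * sgn * f1 +
        subject_anatomy_sd * subj_smooth[, i]
      for (attempt in 1:5) {
        Z <- tcrossprod(a_r, g) + 0.6 * struct +
          noise_sd * matrix(rnorm(nr * 5), nr, 5)
        # small covariate effects, removed downstream by the linear model
        Z <- Z + 0.02 * (subjects$age[i] - 15) + 0.05 * sex_num[i]
        X <- sweep(sweep(Z, 2, FEATURE_SDS[MS_FEATURES], `*`), 2,
                   FEATURE_MEANS[MS_FEATURES], `+`)
        if (all(apply(X, 2, sd) > 0)) break
        rlang::inform("zero-variance feature draw; retrying with new noise.")
      }
      colnames(X) <- MS_FEATURES
      dplyr::bind_cols(subjects[i, ], tibble::tibble(region = regions),
                       tibble::as_tibble(X))
    })
    out <- purrr::list_rbind(rows)
    structure(out, class = c("cohort_table", class(out)), design = design,
              effect_size = effect_size)
  })
}

#' Generate cell-type signature sets with planted class structure
#'
#' Adds signature genes to the atlas: each of `n_classes` fine classes gets
#' a regional profile built from a coarse-cluster factor map plus a smaller
#' class-specific factor component, so fine classes nest inside
#' `n_coarse` coarse clusters; each signature's genes share their class
#' profile plus independent gene-level noise. Several studies contribute one
#' signature per class, with study-specific labels.
#'
#' @param atlas An `expression_atlas` from [generate_expression_atlas()].
#' @param manifest The matching manifest (updated in the return value).
#' @param n_classes Number of fine cell classes (default 7; must not exceed
#'   the number of factor maps).
#' @param sets_per_class Signatures (studies) per class (default 3).
#' @param genes_per_set Genes per signature (default 12).
#' @param noise_sd Profile noise level (default 0.2): genes deviate from
#'   their signature profile by `noise_sd`, and each signature (study)
#'   deviates from its class profile by `0.8 * noise_sd`.
#' @param n_coarse Number of coarse clusters the classes nest into
#'   (default 3).
#' @param fine_sep Relative weight of the class-specific component; kept
#'   small (default 0.04) so fine classes are real but subordinate to the
#'   coarse split, as study-level cell-type sets are in practice.
#' @param seed Integer seed.
#' @return A list: `signatures` (list of `cell_signature`), `atlas` (with
#'   the signature genes appended and re-aggregated), `manifest` (with
#'   `planted_classes` filled in).
#' @export
generate_cell_signatures <- function(atlas, manifest, n_classes = 7L,
                                     sets_per_class = 3L, genes_per_set = 12L,
                                     noise_sd = 0.2, n_coarse = 3L,
                                     fine_sep = 0.04, seed = 1L) {
  k_factors <- ncol(manifest$factors)
  if (n_classes > k_factors) {
    nv_abort("n_classes exceeds the number of latent factors.",
             "nv_config_error")
  }
  if (n_coarse + n_classes + 1L > k_factors) {
    nv_abort("need k_factors >= n_coarse + n_classes + 1 for nested class profiles.",
             "nv_config_error")
  }
  class_labels <- c("Astro", "Endo", "Micro", "Neuro-Ex", "Neuro-In",
                    "Oligo", "OPC", paste0("Class", seq_len(max(0, n_classes - 7))))
  class_labels <- class_labels[seq_len(n_classes)]
  regions <- rownames(atlas$expr)
  Flh <- manifest$factors[regions, , drop = FALSE]
  # coarse profiles use factors 2..(n_coarse+1); fine offsets the next ones
  coarse_of <- rep(seq_len(n_coarse), length.out = n_classes)
  profiles <- vapply(seq_len(n_classes), function(c_) {
    sqrt(1 - fine_sep^2) * Flh[, 1L + coarse_of[c_]] +
      fine_sep * Flh[, 1L + n_coarse + c_]
  }, numeric(length(regions)))
  colnames(profiles) <- class_labels

  n_new <- n_classes * sets_per_class * genes_per_set
  new_genes <- sprintf("CSG%04d", seq_len(n_new))
  gene_class <- rep(rep(class_labels, each = genes_per_set), sets_per_class)
  n_sig <- n_classes * sets_per_class
  sig_of_gene <- rep(seq_len(n_sig), each = genes_per_set)
  with_seed(derive_seed(seed, "signatures"), {
    sig_noise <- matrix(rnorm(length(regions) * n_sig), length(regions), n_sig)
    noise <- matrix(rnorm(length(regions) * n_new), length(regions), n_new)
    expr_new <- profiles[, gene_class, drop = FALSE] +
      0.8 * noise_sd * sig_noise[, sig_of_gene, drop = FALSE] +
      noise_sd * noise
    colnames(expr_new) <- new_genes
    donor_sd <- if (length(atlas$donors) > 1L) {
      sd(atlas$donors[[1]] - atlas$donors[[2]]) / sqrt(2)
    } else {
      0.5
    }
    donors <- purrr::map(atlas$donors, function(d) {
      cbind(d, expr_new + donor_sd *
              matrix(rnorm(length(expr_new)), nrow(expr_new)))
    })
    annotations <- dplyr::bind_rows(
      atlas$annotations,
      tibble::tibble(gene = new_genes,
                     chromosome = sample(as.character(1:22), n_new,
                                         replace = TRUE),
                     start = NA_real_, end = NA_real_, brain_expressed = TRUE)
    )
    sig_idx <- split(seq_len(n_new),
                     rep(seq_len(n_classes * sets_per_class),
                         each = genes_per_set))
    sig_class <- rep(class_labels, times = sets_per_class)
    sig_study <- rep(paste0("study", seq_len(sets_per_class)),
                     each = n_classes)
    signatures <- purrr::map(seq_along(sig_idx), function(s) {
      cell_signature(sig_study[s], sig_class[s], new_genes[sig_idx[[s]]])
    })
    manifest$planted_classes <- tibble::tibble(
      signature = vapply(signatures, function(s) s$name, character(1)),
      class = sig_class,
      coarse_cluster = coarse_of[match(sig_class, class_labels)]
    )
    manifest$class_profiles <- profiles
    list(signatures = signatures,
         atlas = aggregate_donor_expression(donors, annotations),
         manifest = manifest)
  })
}

#' Generate subject-level carrier expression coupled to MS deviation
#'
#' Emulates a qPCR-style panel of dosage-sensitive genes measured in CNV
#' carriers: each subject's expression is a karyotype-group mean plus
#' `beta` times the subject's MS deviation score (the projection of their
#' regional MS, standardized within karyotype group, onto the planted
#' change-map direction) plus noise.
#'
#' @param cohort A `cohort_table` from [generate_cohort()] (aneuploidy
#'   design; carriers are subjects with `xan > 0` or `yan > 0`).
#' @param manifest The matching manifest.
#' @param n_ds_genes Number of panel genes (default 11).
#' @param beta Coupling coefficient (0 = null).
#' @param noise_sd Residual expression noise (default 0.3).
#' @param seed Integer seed.
#' @return A list: `expression` (carriers x genes matrix), `groups` (named
#'   karyotype labels), `ms` (carriers x regions regional-MS matrix),
#'   `score` (the planted deviation scores), `manifest` (with
#'   `individual_beta` recorded).
#' @export
generate_individual_expression <- function(cohort, manifest, n_ds_genes = 11L,
                                           beta = 0.8, noise_sd = 0.3,
                                           seed = 1L) {
  covs <- cohort_covariates(cohort)
  if (!all(c("xan", "yan") %in% names(covs))) {
    nv_abort("individual expression requires an aneuploidy cohort.",
             "nv_config_error")
  }
  carriers <- covs$subject_id[covs$xan > 0 | covs$yan > 0]
  groups <- covs$group[match(carriers, covs$subject_id)]
  if (length(unique(groups)) < 2L) {
    nv_abort("need >= 2 karyotype groups of carriers.", "nv_config_error")
  }
  ms_long <- compute_cohort_ms(cohort[cohort$subject_id %in% carriers, ])
  ms <- response_matrix(ms_long, tibble::tibble(subject_id = carriers),
                        "regional_ms")
  map <- manifest$cnv$effect_sign * manifest$factors[colnames(ms), 1]
  ms_z <- scale_within_group(ms, groups)
  # deviation score along the planted change map, computed against the
  # ridge-regularized MS covariance so the planted coupling lies along the
  # map itself rather than the map blurred by inter-regional MS covariance
  S <- crossprod(ms_z) / (nrow(ms_z) - 1)
  lam <- 20 * mean(diag(S))
  w_map <- solve(S + lam * diag(ncol(S)), map - mean(map))
  score <- as.numeric(scale(ms_z %*% w_map))
  dosage <- covs$xan[match(carriers, covs$subject_id)]
  genes <- paste0("DSG", seq_len(n_ds_genes))
  expr <- with_seed(derive_seed(seed, "individual"), {
    gm <- outer(0.5 * dosage, runif(n_ds_genes, 0.8, 1.2))
    gm + beta * score + noise_sd * matrix(rnorm(length(carriers) * n_ds_genes),
                                          length(carriers), n_ds_genes)
  })
  dimnames(expr) <- list(carriers, genes)
  manifest$individual_beta <- beta
  list(expression = expr, groups = stats::setNames(groups, carriers), ms = ms,
       score = stats::setNames(score, carriers), manifest = manifest)
}
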