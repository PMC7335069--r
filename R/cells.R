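# Cell-class decoding: signature-by-region expression matrix, gap-statistic
# hierarchical clustering, post hoc class assignment, distance-weighted
# class expression maps, and the CNV-by-cell-class screen.

#' Cell-type signature constructor
#'
#' @param study_id Label of the source single-cell study.
#' @param cell_label The study's cell-type label (e.g. `"Astro"`,
#'   `"Neuro-Ex"`).
#' @param genes Character vector of marker genes.
#' @return A `cell_signature` object; its display name is
#'   `study_id.cell_label`.
#' @export
cell_signature <- function(study_id, cell_label, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) nv_abort("signature has no genes.", "nv_empty_gene_set")
  structure(list(study_id = study_id, cell_label = cell_label, genes = genes,
                 name = paste(study_id, cell_label, sep = ".")),
            class = "cell_signature")
}

#' Signature-by-region median expression matrix
#'
#' Entry (s, r) is the median z-scored expression in region r over the atlas
#' genes of signature s. Signatures with no atlas genes are dropped with a
#' warning.
#'
#' @param atlas An `expression_atlas`.
#' @param signatures A list of `cell_signature` objects.
#' @return A signatures x regions numeric matrix with signature names as row
#'   names and an attached `signatures` attribute (the retained list).
#' @export
cell_by_region_matrix <- function(atlas, signatures) {
  stopifnot(inherits(atlas, "expression_atlas"))
  rows <- purrr::map(signatures, function(sig) {
    genes <- intersect(sig$genes, colnames(atlas$expr))
    if (!length(genes)) return(NULL)
    apply(atlas$expr[, genes, drop = FALSE], 1, median)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) {
    rlang::warn(sprintf("%d signature(s) with no atlas genes dropped.",
                        sum(!keep)))
  }
  if (!any(keep)) nv_abort("no signature overlaps the atlas.",
                           "nv_empty_gene_set")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- vapply(signatures[keep], function(s) s$name, character(1))
  attr(m, "signatures") <- signatures[keep]
  m
}

# Internal: correlation-distance hierarchical clustering of matrix rows.
profile_hclust <- function(m, linkage = "average") {
  hclust(as.dist(1 - stats::cor(t(m))), method = linkage)
}

#' Cluster cell-type signatures by their regional expression profiles
#'
#' Agglomerative clustering on correlation distance (1 - Pearson between
#' signature regional profiles); the number of clusters is chosen by the gap
#' statistic with Tibshirani's uniform-box reference and the 1-SE rule.
#'
#' @param matrix A signatures x regions matrix from
#'   [cell_by_region_matrix()].
#' @param max_k Largest cluster count to evaluate (must be smaller than the
#'   number of signatures).
#' @param B_ref Reference draws for the gap statistic (default 50).
#' @param seed Integer seed for the reference draws.
#' @param linkage Agglomeration method (default `"average"`).
#' @return A list: `tree` (hclust), `k` (chosen cluster count), `clusters`
#'   (named integer vector), `gap` (the `clusGap` table).
#' @export
cluster_cell_signatures <- function(matrix, max_k, B_ref = 50L, seed = 1L,
                                    linkage = "average") {
  if (nrow(matrix) < 3L) nv_abort("need at least 3 signatures.",
                                  "nv_bad_argument")
  if (max_k >= nrow(matrix)) {
    nv_abort("`max_k` must be smaller than the number of signatures.",
             "nv_bad_bound")
  }
  tree <- profile_hclust(matrix, linkage)
  fun <- function(x, k) list(cluster = cutree(profile_hclust(x, linkage), k))
  gap <- with_seed(seed, cluster::clusGap(matrix, FUNcluster = fun,
                                          K.max = max_k, B = B_ref,
                                          spaceH0 = "original",
                                          verbose = FALSE))
  k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                      method = "Tibs2001SEmax")
  list(tree = tree, k = k, clusters = cutree(tree, k), gap = gap$Tab)
}

#' Assign signatures to canonical cell classes
#'
#' Fine classes are formed by cell-label concordance (signatures sharing a
#' label form one class); labels in `exclude_labels` (by default undivided
#' neurons and pericytes, which cannot be mapped to a canonical class) are
#' excluded. Each retained class is checked for nesting within the coarse
#' clustering solution; violations are flagged with a warning, not fatal.
#'
#' @param clustering Result of [cluster_cell_signatures()].
#' @param signatures The corresponding list of `cell_signature`s (in matrix
#'   row order).
#' @param exclude_labels Cell labels to exclude (default
#'   `c("Neuro", "Per")`).
#' @return A tibble `signature`, `study_id`, `cell_label`, `coarse_cluster`,
#'   `class_assignment` (`NA` for excluded signatures), `nested`.
#' @export
assign_cell_classes <- function(clustering, signatures,
                                exclude_labels = c("Neuro", "Per")) {
  df <- tibble::tibble(
    signature = vapply(signatures, function(s) s$name, character(1)),
    study_id = vapply(signatures, function(s) s$study_id, character(1)),
    cell_label = vapply(signatures, function(s) s$cell_label, character(1)),
    coarse_cluster = unname(clustering$clusters)
  )
  df$class_assignment <- ifelse(df$cell_label %in% exclude_labels,
                                NA_character_, df$cell_label)
  nested_by_class <- df |>
    dplyr::filter(!is.na(.data$class_assignment)) |>
    dplyr::group_by(.data$class_assignment) |>
    dplyr::summarise(nested = dplyr::n_distinct(.data$coarse_cluster) == 1L)
  df <- dplyr::left_join(df, nested_by_class, by = "class_assignment")
  if (any(!df$nested, na.rm = TRUE)) {
    bad <- unique(df$class_assignment[!is.na(df$nested) & !df$nested])
    rlang::warn(paste0("cell classes not nested within coarse clusters: ",
                       paste(bad, collapse = ", ")))
  }
  df
}

#' Inverse-distance weights of signatures within a class
#'
#' Signature profiles are projected into principal-component space (retaining
#' components that explain >= 95% of variance); each signature's weight is
#' proportional to the inverse of its Euclidean distance to the class
#' centroid (plus a small epsilon), normalized to sum to one. Signatures far
#' from the class consensus are thus down-weighted.
#'
#' @param profiles A signatures x regions matrix (the class's rows of the
#'   cell-by-region matrix).
#' @param epsilon Stabilizer added to distances (default 1e-6).
#' @return Named non-negative weights summing to 1.
#' @export
derive_class_weights <- function(profiles, epsilon = 1e-6) {
  profiles <- rbind(profiles)
  if (nrow(profiles) == 1L) {
    return(stats::setNames(1, rownames(profiles)))
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  keep <- seq_len(max(1L, which(cum >= 0.95)[1]))
  scores <- pc$x[, keep, drop = FALSE]
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  w <- 1 / (d + epsilon)
  stats::setNames(w / sum(w), rownames(profiles))
}

#' Weighted cell-class expression map
#'
#' @param profiles A signatures x regions matrix for one class.
#' @param weights Weights from [derive_class_weights()] (same order).
#' @return A named region vector: the weighted mean of the signature
#'   profiles.
#' @export
class_expression_map <- function(profiles, weights) {
  profiles <- rbind(profiles)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    nv_abort("weights must be non-negative and sum to 1.", "nv_bad_argument")
  }
  colSums(profiles * weights)
}

#' All cell-class expression maps for an assignment
#'
#' Convenience wrapper: for every assigned class, derives signature weights
#' and the weighted class expression map.
#'
#' @param matrix A signatures x regions matrix.
#' @param assignment Output of [assign_cell_classes()].
#' @return A list: `maps` (classes x regions matrix) and `weights` (tibble
#'   `class`, `signature`, `weight`).
#' @export
cell_class_maps <- function(matrix, assignment) {
  classes <- sort(unique(stats::na.omit(assignment$class_assignment)))
  weights <- list(); maps <- list()
  for (cl in classes) {
    rows <- assignment$signature[!is.na(assignment$class_assignment) &
                                   assignment$class_assignment == cl]
    prof <- matrix[rows, , drop = FALSE]
    w <- derive_class_weights(prof)
    maps[[cl]] <- class_expression_map(prof, w)
    weights[[cl]] <- tibble::tibble(class = cl, signature = rows,
                                    weight = unname(w))
  }
  list(maps = do.call(rbind, maps), weights = purrr::list_rbind(weights))
}

# Internal: re-rank a ranked list after subsetting to a gene universe.
rerank <- function(ranked_list, genes_keep) {
  sub <- ranked_list[ranked_list$gene %in% genes_keep, , drop = FALSE]
  n <- nrow(sub)
  sub$rank <- seq_len(n)
  sub$centered_rank <- seq_len(n) - (n + 1) / 2
  structure(sub, class = class(ranked_list))
}

#' Screen CNV ranked lists for cell-class associations
#'
#' Works on the brain-expressed subset of the ranked list (re-ranked after
#' filtering). A (CNV, class) association is reported when (i) the class
#' gene set occupies a significantly extreme median rank (two-sided
#' permutation test at `alpha`), and (ii) at least one brain-expressed CNV
#' gene inside the class set lies in the extreme rank centiles
#' (`< centile` or `> 1 - centile`).
#'
#' @param ranked_list A `ranked_genes` tibble (full genome).
#' @param class_sets Named list of class gene sets (`gene_set` or character).
#' @param cnv_set The CNV `gene_set`.
#' @param annotations Gene annotations with `brain_expressed` flags.
#' @param centile Extreme-rank centile (default 0.05).
#' @param alpha Class-level significance threshold (default 0.05).
#' @param n_perm Random sets for the median-rank test.
#' @param seed Integer seed.
#' @return A tibble `class`, `n_class_genes`, `median_rank`, `p`,
#'   `side` (`high`/`low`), `genes` (list column of qualifying CNV genes),
#'   `association`.
#' @export
cnv_cell_screen <- function(ranked_list, class_sets, cnv_set, annotations,
                            centile = 0.05, alpha = 0.05, n_perm = 10000L,
                            seed = 1L) {
  annotations <- tibble::as_tibble(annotations)
  brain <- annotations$gene[annotations$brain_expressed]
  rl <- rerank(ranked_list, brain)
  n <- nrow(rl)
  cent <- rl$rank / n
  names(cent) <- rl$gene
  cnv <- intersect(set_members(cnv_set), rl$gene)
  out <- purrr::imap(class_sets, function(cs, nm) {
    members <- intersect(set_members(cs), rl$gene)
    if (!length(members)) {
      rlang::warn(sprintf("class set '%s' has no ranked genes; skipped.", nm))
      return(NULL)
    }
    obs <- median_rank(rl, members)
    pt <- p_rand_trans(rl, length(members), obs, direction = "two_sided",
                       n_perm = n_perm, seed = derive_seed(seed, nm))
    extreme_genes <- intersect(cnv, members)
    extreme_genes <- extreme_genes[cent[extreme_genes] < centile |
                                     cent[extreme_genes] > 1 - centile]
    tibble::tibble(class = nm, n_class_genes = length(members),
                   median_rank = obs, p = pt$p,
                   side = if (obs >= 0) "high" else "low",
                   genes = list(extreme_genes),
                   association = pt$p < alpha && length(extreme_genes) > 0)
  })
  purrr::list_rbind(purrr::compact(out))
}

#' Regional differential expression between two gene sets
#'
#' @param atlas An `expression_atlas`.
#' @param setA,setB Gene sets (e.g. DS^SS and nDS).
#' @return Named region vector: mean z expression of `setA` minus that of
#'   `setB`.
#' @export
differential_expression_map <- function(atlas, setA, setB) {
  a <- intersect(set_members(setA), colnames(atlas$expr))
  b <- intersect(set_members(setB), colnames(atlas$expr))
  if (!length(a) || !length(b)) {
    nv_abort("both sets must be nonempty in the atlas.", "nv_empty_gene_set")
  }
  rowMeans(atlas$expr[, a, drop = FALSE]) -
    rowMeans(atlas$expr[, b, drop = FALSE])
}
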