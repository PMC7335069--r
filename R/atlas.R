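# Regional expression atlas assembly: donor aggregation, z-scoring, gene
# annotation, CNV gene-set derivation and brain-expressed filtering.

# Internal: elementwise median across a list of equally-shaped matrices,
# via a vectorized compare-exchange (bubble) sorting network over the list
# dimension -- fast for the small donor counts in play.
elementwise_median <- function(mats) {
  k <- length(mats)
  if (k == 1L) return(mats[[1]])
  cols <- lapply(mats, as.numeric)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
      cols[[j + 1L]] <- hi
    }
  }
  mid <- (k + 1L) / 2
  out <- if (k %% 2L == 1L) {
    cols[[mid]]
  } else {
    (cols[[k / 2L]] + cols[[k / 2L + 1L]]) / 2
  }
  matrix(out, nrow(mats[[1]]), ncol(mats[[1]]))
}

# Internal: expression_atlas constructor.
new_expression_atlas <- function(expr, donors, annotations) {
  structure(list(expr = expr, donors = donors, annotations = annotations),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("Expression atlas: %d regions x %d genes (%d donors)\n",
              nrow(x$expr), ncol(x$expr), length(x$donors)))
  invisible(x)
}

#' @export
dim.expression_atlas <- function(x) dim(x$expr)

#' Gene set constructor
#'
#' @param name Set label.
#' @param members Character vector of gene labels (must be nonempty).
#' @param provenance One of `chromosome`, `interval`, `cell_type`, `DS`,
#'   `nDS`, `DSSS`, `custom`.
#' @param description Optional free-text description (kept through GMT
#'   round trips).
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members,
                     provenance = c("custom", "chromosome", "interval",
                                    "cell_type", "DS", "nDS", "DSSS"),
                     description = "") {
  provenance <- match.arg(provenance)
  members <- as.character(members)
  if (!length(members)) {
    nv_abort(sprintf("gene set '%s' is empty.", name), "nv_empty_gene_set")
  }
  if (anyDuplicated(members)) {
    rlang::warn(sprintf("gene set '%s': duplicate members removed.", name))
    members <- unique(members)
  }
  structure(list(name = name, members = members, provenance = provenance,
                 description = description), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s' (%s): %d genes\n", x$name, x$provenance,
              length(x$members)))
  invisible(x)
}

#' Aggregate donor-level expression into an analysis-ready atlas
#'
#' Takes the elementwise median across donor region-by-gene matrices, then
#' z-scores each gene across regions (sample sd). This is the standard
#' donor-consensus construction for projecting a multi-donor expression
#' resource onto a parcellation.
#'
#' @param donors A list of region x gene matrices with identical dimnames.
#' @param annotations Optional per-gene annotation tibble with columns
#'   `gene`, `chromosome`, `start`, `end`, `brain_expressed`.
#' @return An `expression_atlas`: `expr` (z-scored region x gene matrix),
#'   `donors` (the input list), `annotations`.
#' @export
aggregate_donor_expression <- function(donors, annotations = NULL) {
  if (!length(donors)) nv_abort("at least one donor is required.",
                                "nv_bad_argument")
  ref <- donors[[1]]
  for (d in donors) {
    if (!identical(dim(d), dim(ref)) ||
        !identical(dimnames(d), dimnames(ref))) {
      nv_abort("donor matrices have misaligned region/gene axes.",
               "nv_alignment_error")
    }
  }
  med <- elementwise_median(donors)
  dimnames(med) <- dimnames(ref)
  sds <- apply(med, 2, sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("%d constant gene(s) dropped before z-scoring.",
                        sum(sds == 0)))
    med <- med[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  expr <- scale(med)
  attr(expr, "scaled:center") <- NULL
  attr(expr, "scaled:scale") <- NULL
  if (is.null(annotations)) {
    annotations <- tibble::tibble(gene = colnames(expr),
                                  chromosome = NA_character_,
                                  start = NA_real_, end = NA_real_,
                                  brain_expressed = TRUE)
  } else {
    annotations <- tibble::as_tibble(annotations)
    miss <- setdiff(colnames(expr), annotations$gene)
    if (length(miss)) {
      nv_abort(paste0("annotations missing for genes: ",
                      paste(head(miss, 5), collapse = ", ")),
               "nv_bad_argument")
    }
    annotations <- annotations[match(colnames(expr), annotations$gene), ]
  }
  new_expression_atlas(expr, donors, annotations)
}

#' Restrict an atlas to brain-expressed genes
#'
#' Column subset by the `brain_expressed` annotation flag. Gene z-scores are
#' deliberately not recomputed: genome-wide PLS ranking runs on the full
#' atlas, and this filter applies only to downstream exports and cell-class
#' screens.
#'
#' @param atlas An `expression_atlas`.
#' @return The filtered `expression_atlas`.
#' @export
filter_brain_expressed <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  keep <- atlas$annotations$brain_expressed
  if (!any(keep)) nv_abort("no brain-expressed genes in atlas.",
                           "nv_empty_gene_set")
  new_expression_atlas(atlas$expr[, keep, drop = FALSE],
                       purrr::map(atlas$donors,
                                  function(d) d[, keep, drop = FALSE]),
                       atlas$annotations[keep, ])
}

#' Derive a CNV gene set from annotations
#'
#' Three specifications are supported: a whole chromosome (all genes
#' annotated to it, with the pseudoautosomal region `PAR` carried as its own
#' label), an explicit interval on a chromosome, or per-patient breakpoint
#' lists, in which case the representative interval is
#' `[median(proximal), median(distal)]`. A gene belongs to an interval iff
#' both its annotated start and end lie within the closed interval.
#'
#' @param annotations Per-gene tibble with `gene`, `chromosome`, `start`,
#'   `end`.
#' @param chromosome Chromosome label (`"1"`..`"22"`, `"X"`, `"Y"`, `"PAR"`).
#' @param start,end Optional interval bounds (base pairs).
#' @param proximal,distal Optional numeric breakpoint vectors across
#'   patients; medians define the interval.
#' @param name Optional set label.
#' @return A `gene_set` with provenance `chromosome` or `interval`.
#' @export
derive_cnv_gene_set <- function(annotations, chromosome, start = NULL,
                                end = NULL, proximal = NULL, distal = NULL,
                                name = NULL) {
  annotations <- tibble::as_tibble(annotations)
  on_chr <- annotations[annotations$chromosome == chromosome, , drop = FALSE]
  if (!is.null(proximal) || !is.null(distal)) {
    if (!length(proximal) || !length(distal)) {
      nv_abort("both proximal and distal breakpoint lists must be nonempty.",
               "nv_bad_argument")
    }
    start <- median(proximal)
    end <- median(distal)
  }
  if (is.null(start) != is.null(end)) {
    nv_abort("provide both `start` and `end`, or neither.", "nv_bad_argument")
  }
  if (is.null(start)) {
    members <- on_chr$gene
    prov <- "chromosome"
    name <- name %||% paste0("chr", chromosome)
  } else {
    members <- on_chr$gene[on_chr$start >= start & on_chr$end <= end]
    prov <- "interval"
    name <- name %||% sprintf("chr%s:%g-%g", chromosome, start, end)
  }
  if (!length(members)) {
    nv_abort(sprintf("CNV specification selects zero atlas genes (%s).", name),
             "nv_empty_gene_set")
  }
  gene_set(name, members, provenance = prov)
}

#' Leave-one-donor-out atlas variants
#'
#' @param donors A list of >= 2 aligned donor matrices.
#' @param annotations Optional annotations passed through to each atlas.
#' @return A named list of `expression_atlas` objects, one per excluded
#'   donor.
#' @export
leave_one_donor_out_atlases <- function(donors, annotations = NULL) {
  if (length(donors) < 2L) {
    nv_abort("at least 2 donors are required for leave-one-out atlases.",
             "nv_bad_argument")
  }
  nms <- names(donors) %||% paste0("donor", seq_along(donors))
  out <- purrr::map(seq_along(donors), function(i) {
    aggregate_donor_expression(donors[-i], annotations)
  })
  stats::setNames(out, paste0("without_", nms))
}
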