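# File formats: labeled TSV matrices, GMT gene sets, cohort/geometry tables
# and JSON manifests. All tabular exchange is TSV with explicit headers;
# gene sets use the GMT convention (set name, description, then members,
# tab-separated, one set per line).

#' Read a labeled numeric matrix from TSV
#'
#' Expects a header row; the first column holds row labels. Parsing is
#' strict: any non-numeric cell is an error naming the offending line.
#'
#' @param path File path.
#' @param orientation `"as_is"` or `"transpose"`.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, orientation = c("as_is", "transpose")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(lines))) {
    nv_abort(sprintf("empty input file: %s", path), "nv_empty_input")
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  ncol_expected <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != ncol_expected)
  if (length(bad)) {
    nv_abort(sprintf("ragged row at line %d of %s.", bad[1] + 1L, path),
             "nv_parse_error")
  }
  labels <- vapply(cells, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(cells, function(x) as.numeric(x[-1]), numeric(ncol_expected - 1L))
  )
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expected - 1L)
  if (anyNA(vals)) {
    row <- which(apply(vals, 1, anyNA))[1]
    nv_abort(sprintf("non-numeric cell at line %d of %s.", row + 1L, path),
             "nv_parse_error")
  }
  dimnames(vals) <- list(labels, header[-1])
  if (orientation == "transpose") t(vals) else vals
}

#' Write a labeled numeric matrix to TSV
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @param label_header Name of the label column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, label_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- label_header
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members (tab-separated).
#' Member order is preserved; duplicates are removed with a warning.
#'
#' @param path File path.
#' @return A named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) nv_abort(sprintf("empty GMT file: %s", path),
                               "nv_empty_input")
  sets <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      nv_abort("GMT line needs >= 3 tab-separated fields.", "nv_parse_error")
    }
    gene_set(f[1], f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of `gene_set` objects (or character vectors, in which
#'   case list names become set names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(s, nm) {
    if (inherits(s, "gene_set")) {
      paste(c(s$name, if (nzchar(s$description)) s$description else s$provenance,
              s$members), collapse = "\t")
    } else {
      paste(c(nm, "custom", as.character(s)), collapse = "\t")
    }
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a cohort table to TSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' Read a cohort table from TSV
#'
#' @param path File path.
#' @return A `cohort_table` tibble.
#' @export
read_cohort_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("cohort_table", class(out)))
}

#' Write parcellation geometry to TSV
#'
#' @param geometry Geometry tibble (`region`, `hemi`, `x`, `y`, `z`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry_tsv <- function(geometry, path) {
  readr::write_tsv(geometry, path)
  invisible(path)
}

#' Read parcellation geometry from TSV
#'
#' @param path File path.
#' @return A geometry tibble.
#' @export
read_geometry_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
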