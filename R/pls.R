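# SIMPLS partial least squares: rank atlas genes by first-component
# alignment between regional expression and an anatomical change map.
#
# SIMPLS (de Jong 1993) extracts components maximizing the covariance
# between score vectors of the two centered blocks, deflating the
# cross-product matrix (not the data) by an orthonormal basis of the
# X-loading space, so scores remain weighted sums of the original centered
# matrices: T = X0 W, U = Y0 Q.

# Internal: SIMPLS on centered blocks X0 (n x p), Y0 (n x q).
# Returns weights W (p x k), scores TT (n x k, orthonormal columns),
# y-weights Q (q x k), y-scores U (n x k), x-loadings P (p x k).
simpls <- function(X0, Y0, k) {
  n <- nrow(X0); p <- ncol(X0); q <- ncol(Y0)
  k <- min(k, p, n - 1L)
  S <- crossprod(X0, Y0)
  W <- matrix(0, p, k); TT <- matrix(0, n, k); P <- matrix(0, p, k)
  Q <- matrix(0, q, k); U <- matrix(0, n, k); V <- matrix(0, p, k)
  for (a in seq_len(k)) {
    r <- if (q == 1L) S[, 1] else svd(S, nu = 1L, nv = 0L)$u[, 1]
    t_ <- X0 %*% r
    nt <- sqrt(sum(t_^2))
    if (nt < .Machine$double.eps^0.5) break
    t_ <- t_ / nt; r <- r / nt
    p_ <- crossprod(X0, t_)
    q_ <- crossprod(Y0, t_)
    u_ <- Y0 %*% q_
    v <- p_
    if (a > 1L) {
      Vprev <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vprev %*% crossprod(Vprev, p_)
      Tprev <- TT[, seq_len(a - 1L), drop = FALSE]
      u_ <- u_ - Tprev %*% crossprod(Tprev, u_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    W[, a] <- r; TT[, a] <- t_; P[, a] <- p_; Q[, a] <- q_; U[, a] <- u_
    V[, a] <- v
  }
  # per-component fraction of response variance explained (T orthonormal)
  ssy <- sum(Y0^2)
  var_explained <- pmin(1, pmax(0, colSums(Q^2) / ssy))
  list(W = W, T = TT, P = P, Q = Q, U = U, var_explained = var_explained,
       k = k)
}

#' Fit the first SIMPLS component of expression against a change map
#'
#' The predictor block is the region x gene atlas matrix (already z-scored
#' per gene; centered per gene here) and the response is the regional change
#' map. The first-component gene weights `w1` maximize the covariance
#' between the expression score `T1 = X0 w1` and the response score
#' `U1 = Y0 q1`. Polarity is fixed so that `T1` correlates non-negatively
#' with the change map: genes with positive weights are then over-expressed
#' where the anatomical statistic is increased.
#'
#' @param atlas An `expression_atlas` or a region x gene matrix.
#' @param change_map A `change_map` tibble (or named numeric vector) giving
#'   one statistic per atlas region.
#' @param k Number of components for the explained-variance profile
#'   (default 5).
#' @return A `pls_fit` object: `w1`, `q1`, `T1`, `U1`, `E1`, `E2` (first
#'   component residual blocks), `var_explained` (components 1..k),
#'   `comp1_maximal` flag, `genes`, `regions`, `covariance` (cov(T1, U1)).
#' @export
fit_pls_component <- function(atlas, change_map, k = 5L) {
  X <- if (inherits(atlas, "expression_atlas")) atlas$expr else as.matrix(atlas)
  y <- change_map_vector(change_map, rownames(X))
  if (nrow(X) < 3L) nv_abort("need at least 3 regions.", "nv_bad_argument")
  if (sd(y) == 0) nv_abort("change map is constant: degenerate response.",
                           "nv_degenerate_response")
  X0 <- scale(X, center = TRUE, scale = FALSE)
  Y0 <- matrix(y - mean(y), ncol = 1)
  fit <- simpls(X0, Y0, k)
  w1 <- fit$W[, 1]; q1 <- fit$Q[1, 1]; t1 <- fit$T[, 1]; u1 <- fit$U[, 1]
  if (stats::cor(t1, y) < 0) {
    w1 <- -w1; q1 <- -q1; t1 <- -t1; u1 <- -u1
  }
  names(w1) <- colnames(X)
  structure(list(
    w1 = w1, q1 = q1, T1 = t1, U1 = u1,
    E1 = X0 - tcrossprod(t1, fit$P[, 1]),
    E2 = Y0 - t1 * q1,
    var_explained = fit$var_explained,
    comp1_maximal = which.max(fit$var_explained) == 1L,
    genes = colnames(X), regions = rownames(X),
    covariance = sum(t1 * u1) / (length(t1) - 1),
    k = fit$k
  ), class = "pls_fit")
}

# Internal: extract an aligned response vector from a change_map tibble or a
# named vector.
change_map_vector <- function(change_map, regions) {
  if (is.data.frame(change_map)) {
    v <- stats::setNames(change_map$t, change_map$region)
  } else {
    v <- change_map
  }
  if (!is.null(regions) && !is.null(names(v))) {
    miss <- setdiff(regions, names(v))
    if (length(miss)) {
      nv_abort(paste0("change map missing regions: ",
                      paste(head(miss, 5), collapse = ", ")),
               "nv_alignment_error")
    }
    v <- v[regions]
  }
  if (anyNA(v) || any(!is.finite(v))) {
    nv_abort("change map contains non-finite values.", "nv_bad_argument")
  }
  unname(v)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("SIMPLS fit: %d regions x %d genes\n",
              length(x$regions), length(x$genes)))
  cat(sprintf("  component 1 explains %.1f%% of response variance%s\n",
              100 * x$var_explained[1],
              if (x$comp1_maximal) "" else " (NOT maximal - flagged)"))
  invisible(x)
}

#' Tidy a SIMPLS fit
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A tibble `gene`, `weight` sorted as in the atlas.
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(gene = x$genes, weight = unname(x$w1))
}

#' One-line summary of a SIMPLS fit
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, first-component explained variance,
#'   maximality flag and score covariance.
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(
    n_regions = length(x$regions), n_genes = length(x$genes),
    var_explained_1 = x$var_explained[1], comp1_maximal = x$comp1_maximal,
    covariance = x$covariance
  )
}

#' Rank genes by first-component PLS weight
#'
#' Rank 1 is the gene with the largest positive weight (most over-expressed
#' where the anatomical statistic increases); the last rank is the most
#' negative weight. Centered ranks subtract `(N + 1) / 2` so the list spans
#' approximately `-(N-1)/2 .. +(N-1)/2`. Ties are broken lexicographically
#' by gene label.
#'
#' @param pls_model A `pls_fit` from [fit_pls_component()].
#' @return A `ranked_genes` tibble: `gene`, `weight`, `rank`,
#'   `centered_rank`, ordered by rank.
#' @export
rank_genes <- function(pls_model) {
  stopifnot(inherits(pls_model, "pls_fit"))
  w <- pls_model$w1
  ord <- order(-w, names(w))
  n <- length(w)
  out <- tibble::tibble(
    gene = names(w)[ord],
    weight = unname(w[ord]),
    rank = seq_len(n),
    centered_rank = seq_len(n) - (n + 1) / 2
  )
  structure(out, class = c("ranked_genes", class(out)))
}

#' Explained-variance profile over PLS components
#'
#' @inheritParams fit_pls_component
#' @param k Number of components (>= 2).
#' @return A list: `fractions` (length-k numeric in `[0, 1]`) and
#'   `comp1_maximal` (flag raised when a later component explains more
#'   response variance than the first).
#' @export
explained_variance_profile <- function(atlas, change_map, k = 5L) {
  k <- assert_count(k, "k", min = 2L)
  fit <- fit_pls_component(atlas, change_map, k = k)
  list(fractions = fit$var_explained, comp1_maximal = fit$comp1_maximal)
}

#' Leave-one-donor-out stability of PLS gene weights
#'
#' Refits the first PLS component on each leave-one-donor-out atlas and
#' correlates its gene weights with the full-atlas weights (polarity is
#' already aligned to the change map by the fitting convention).
#'
#' @param lodo_atlases A list of `expression_atlas` objects from
#'   [leave_one_donor_out_atlases()].
#' @param full_atlas The all-donor `expression_atlas`.
#' @param change_map The change map used for both fits.
#' @return A list: `r` (named vector, one correlation per excluded donor)
#'   and `mean_r`.
#' @export
lodo_loading_stability <- function(lodo_atlases, full_atlas, change_map) {
  if (length(lodo_atlases) < 2L) {
    nv_abort("need at least 2 leave-one-out atlases.", "nv_bad_argument")
  }
  full <- fit_pls_component(full_atlas, change_map)
  r <- vapply(lodo_atlases, function(a) {
    if (!identical(colnames(a$expr), full$genes)) {
      nv_abort("gene sets differ across atlases.", "nv_alignment_error")
    }
    fit <- fit_pls_component(a, change_map)
    stats::cor(fit$w1, full$w1)
  }, numeric(1))
  list(r = r, mean_r = mean(r))
}

#' Plot a ranked gene list
#'
#' @param object A `ranked_genes` tibble.
#' @param highlight Optional `gene_set` (or character vector) to mark.
#' @param ... Unused.
#' @return A ggplot of PLS weight against centered rank, with highlighted
#'   genes as rug marks.
#' @export
autoplot.ranked_genes <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$centered_rank, y = .data$weight)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "centered rank", y = "PLS weight (component 1)")
  if (!is.null(highlight)) {
    members <- if (inherits(highlight, "gene_set")) highlight$members else highlight
    sub <- object[object$gene %in% members, , drop = FALSE]
    p <- p + ggplot2::geom_rug(data = sub, sides = "b", colour = "firebrick")
  }
  p
}
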