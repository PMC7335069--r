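#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor median sd quantile rnorm runif var pt prcomp cutree hclust as.dist setNames
#' @importFrom utils combn head
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise left_join bind_rows n
#' @importFrom tibble tibble as_tibble
NULL

# Internal: stop with a classed condition so tests can assert on error class.
nv_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "neurovuln_error"))
}

# Internal: validate a single positive integer-ish scalar.
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    nv_abort(sprintf("`%s` must be a single integer >= %d.", name, min),
             "nv_bad_argument")
  }
  as.integer(x)
}

# Internal: derive a child RNG seed from a base seed and a stream label.
# Keeps every derived seed strictly below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 2039L + (h %% 2039L)
}

# Internal: run code with a local RNG state so generators never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Internal: permutation p-value with the add-one estimator.
perm_pvalue <- function(observed, null_sample, direction) {
  n <- length(null_sample)
  extreme <- switch(direction,
    high      = sum(null_sample >= observed),
    low       = sum(null_sample <= observed),
    two_sided = sum(abs(null_sample) >= abs(observed)),
    nv_abort(sprintf("unknown direction '%s'", direction), "nv_bad_argument")
  )
  (1 + extreme) / (n + 1)
}

# Internal: construct a PermutationResult.
new_perm_test <- function(statistic, observed, null_sample, direction,
                          n_perm, seed, extra = list()) {
  out <- c(list(
    statistic = statistic,
    observed = observed,
    null_sample = null_sample,
    p = perm_pvalue(observed, null_sample, direction),
    direction = direction,
    n_perm = n_perm,
    seed = seed
  ), extra)
  structure(out, class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic))
  cat(sprintf("  observed = %.4g, direction = %s\n", x$observed, x$direction))
  cat(sprintf("  p = %.4g (%d permutations, add-one estimator)\n",
              x$p, x$n_perm))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Tidy a permutation test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic label, observed value,
#'   direction, permutation count and p-value.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    direction = x$direction,
    n_perm = x$n_perm,
    p.value = x$p
  )
}

#' Plot a permutation null with its observed statistic
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot: histogram of the permutation null with the observed
#'   statistic as a vertical line.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = object$statistic,
      y = "permutations",
      title = sprintf("%s: p = %.4g (%s, %d perms)",
                      object$statistic, object$p, object$direction,
                      object$n_perm)
    )
}
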