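#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tracking result
#'
#' Already tidy by construction; returns a plain tibble copy.
#'
#' @param x a `ctt_tracking`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy ctt_tracking
#' @export
tidy.ctt_tracking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a tracking result
#'
#' @param x a `ctt_tracking`.
#' @param ... unused.
#' @return A tibble with metric, polarity, counts and (for classifier
#'   results) accuracy.
#' @method glance ctt_tracking
#' @export
glance.ctt_tracking <- function(x, ...) {
  tibble::tibble(metric = attr(x, "metric"),
                 polarity = attr(x, "polarity"),
                 n_observations = length(unique(x$obs)),
                 n_templates = length(unique(x$template %||% x$contrast)),
                 accuracy = attr(x, "accuracy") %||% NA_real_)
}

#' Tidy a permutation-test result
#'
#' @param x a `ctt_permutation`.
#' @param ... unused.
#' @return A tibble with one row per unit: observed statistic and p-value.
#' @method tidy ctt_permutation
#' @export
tidy.ctt_permutation <- function(x, ...) {
  tibble::tibble(unit = seq_along(x$observed), observed = x$observed,
                 p_value = x$p_values)
}

#' One-row summary of a permutation-test result
#'
#' @param x a `ctt_permutation`.
#' @param ... unused.
#' @return A tibble with scheme, permutation count, exactness and the
#'   smallest p-value.
#' @method glance ctt_permutation
#' @export
glance.ctt_permutation <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_perm = x$n_perm, exact = x$exact,
                 alternative = x$alternative, min_p = min(x$p_values))
}

#' Tidy a cluster-correction result
#'
#' @param x a `ctt_clusters`.
#' @param ... unused.
#' @return The cluster table (id, size, member units, FWE p).
#' @method tidy ctt_clusters
#' @export
tidy.ctt_clusters <- function(x, ...) {
  x$clusters
}

#' One-row summary of a cluster-correction result
#'
#' @param x a `ctt_clusters`.
#' @param alpha significance level for the significant-cluster count.
#' @param ... unused.
#' @return A tibble with cluster counts and the null max-size quantiles.
#' @method glance ctt_clusters
#' @export
glance.ctt_clusters <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p_fwe <= alpha),
                 largest = if (nrow(x$clusters)) max(x$clusters$size) else 0L,
                 null_max_median = stats::median(x$null_max_sizes),
                 n_perm = x$n_perm)
}
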