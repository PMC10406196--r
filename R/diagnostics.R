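#' Signal-to-noise ratio of an activation-index distribution
#'
#' Mean of the per-observation activation indexes for one template divided
#' by their sample standard deviation (n - 1). Scale-invariant; used to
#' check that competing templates/localizers are equally reliable before
#' comparing their tracking results.
#'
#' @param indexes numeric vector of per-observation indexes (>= 2 values,
#'   nonzero variance).
#' @return A scalar SNR.
#' @export
compute_snr <- function(indexes) {
  if (length(indexes) < 2L) abort_ctt("SNR needs at least 2 observations")
  s <- stats::sd(indexes)
  if (s == 0) abort_ctt("zero variance: SNR undefined")
  mean(indexes) / s
}

#' Shannon entropy of a template's value distribution
#'
#' Informational content of a canonical template: equal-width histogram over
#' the template's observed range, entropy `-sum p log2 p` over nonempty
#' bins, in bits. A constant template carries 0 bits (returned with a
#' warning, not an error).
#'
#' @param template numeric vector (length >= n_bins).
#' @param n_bins number of histogram bins (default 16).
#' @return Entropy in bits.
#' @export
compute_entropy <- function(template, n_bins = 16L) {
  if (!is_count(n_bins) || n_bins < 2L) abort_ctt("n_bins must be >= 2")
  if (length(template) < n_bins) {
    abort_ctt("template must have at least n_bins values")
  }
  rng <- range(template)
  if (rng[1] == rng[2]) {
    rlang::warn("constant template: entropy is 0 bits")
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(template, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins)
  p <- p[p > 0] / length(template)
  -sum(p * log2(p))
}

#' Correlationability of run-wise template estimates
#'
#' Reliability of each canonical template: the mean Pearson correlation over
#' all pairs of its run-wise estimates (Fisher-z averaged, back-transformed).
#' Templates compared in an analysis should exhibit similar
#' correlationability, otherwise activation differences may just reflect
#' reliability differences.
#'
#' @param ts a template set built with `keep_runwise = TRUE` (>= 2 runs).
#' @return A tibble with `condition` and `correlationability`.
#' @export
compute_correlationability <- function(ts) {
  rw <- ts$runwise_estimates
  if (is.null(rw) || length(rw) < 2L) {
    abort_ctt("correlationability requires run-wise estimates from >= 2 runs")
  }
  n_runs <- length(rw)
  out <- vapply(seq_along(ts$conditions), function(k) {
    zs <- c()
    for (a in seq_len(n_runs - 1L)) {
      for (b in (a + 1L):n_runs) {
        zs <- c(zs, fisher_z(stats::cor(rw[[a]][k, ], rw[[b]][k, ])))
      }
    }
    tanh(mean(zs))
  }, numeric(1))
  tibble::tibble(condition = ts$conditions, correlationability = out)
}

#' Audit of the noise bias in naive vs cross-validated distances
#'
#' Seeded simulation in which a main-task condition's true pattern equals
#' its canonical template, so every distance should be zero. Three
#' estimators are reported, each with its Monte-Carlo standard error:
#'
#' * `naive_pattern_sqdist`: mean squared Euclidean distance between
#'   same-condition chunk patterns from different chunks -- the naive
#'   estimate a template comparison makes when the template itself is
#'   estimated from equally noisy data. Its analytic expectation is the
#'   noise-difference norm `2 * sum_v Var_v`.
#' * `naive_template_sqdist`: mean squared Euclidean distance between the
#'   fixed canonical template and the chunk patterns; biased by
#'   `sum_v Var_v`.
#' * `cv_sqdist`: the cross-validated chunk-pair estimator with the
#'   template fixed; unbiased, centered on 0.
#'
#' @param spec a [sim_spec()]; condition 1 with its one-hot weights is used.
#' @param n_reps number of simulation repetitions (default 1000).
#' @return A tibble with `estimator`, `mean`, `se`, plus the analytic
#'   expectations as attributes `analytic_naive` (2 sum Var) and
#'   `analytic_template` (sum Var).
#' @export
bias_audit <- function(spec, n_reps = 1000L) {
  if (!inherits(spec, "sim_spec")) abort_ctt("`spec` must be a sim_spec")
  truth <- generate_truth(spec)
  Tm <- truth$true_templates[1L, ]
  V <- length(Tm)
  C <- spec$n_chunks_main
  sum_var <- V * spec$noise_sd^2
  naive_pat <- naive_tmp <- cv <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    Y <- with_seed(derive_seed(spec$seed, "bias_audit", rep), {
      draw_noise(truth, C, V)
    })
    Y <- sweep(Y, 2L, Tm, `+`)  # one pattern per chunk, truth = template
    D <- sweep(Y, 2L, Tm)       # chunk-minus-template differences
    Gp <- tcrossprod(Y)
    # naive pattern-pair squared distances
    sq <- outer(diag(Gp), diag(Gp), `+`) - 2 * Gp
    off <- upper.tri(sq) | lower.tri(sq)
    naive_pat[rep] <- mean(sq[off])
    naive_tmp[rep] <- mean(rowSums(D^2))
    Gd <- tcrossprod(D)
    cv[rep] <- mean(Gd[off])
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- tibble::tibble(
    estimator = c("naive_pattern_sqdist", "naive_template_sqdist",
                  "cv_sqdist"),
    mean = c(mean(naive_pat), mean(naive_tmp), mean(cv)),
    se = c(se(naive_pat), se(naive_tmp), se(cv)))
  attr(out, "analytic_naive") <- 2 * sum_var
  attr(out, "analytic_template") <- sum_var
  attr(out, "n_reps") <- n_reps
  out
}
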