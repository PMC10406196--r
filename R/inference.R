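#' Wilcoxon signed-rank test with exact sign enumeration
#'
#' One-sample (against `mu`) or paired signed-rank test. Zero differences
#' are dropped (classic convention; their count is reported). For n <= 25
#' the null distribution of the positive-rank sum is computed exactly by
#' enumerating all 2^n sign assignments via its generating function (exact
#' for tied midranks too); above that, a normal approximation with
#' continuity and tie correction is used.
#'
#' The one-sample form should only be used on activation indexes whose zero
#' is meaningful (cross-validated estimators or relative indexes); naive
#' correlations and distances are positively biased and call for the paired
#' form against a baseline template.
#'
#' @param values numeric sample (or first member of the pair).
#' @param mu null location (default 0).
#' @param paired_with optional second sample of equal length; the test is on
#'   `values - paired_with`.
#' @param alternative `"greater"` (default: directional relative-activation
#'   hypothesis), `"less"` or `"two.sided"`.
#' @return A one-row tibble: `statistic` (V = positive-rank sum), `p_value`,
#'   `n` (after zero removal), `n_zero`, `method`, `alternative`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0, paired_with = NULL,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(paired_with)) values - mu else {
    if (length(paired_with) != length(values)) {
      abort_ctt("paired samples must have equal length")
    }
    values - paired_with
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort_ctt("all differences are zero")
  if (n < 5L) abort_ctt("need at least 5 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of V over all 2^n sign patterns, via the
    # generating function prod_k (1 + z^(2 r_k)) / 2 on doubled (integer)
    # midranks
    r2 <- as.integer(round(2 * r))
    dist <- c(1)
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist)
      dist <- c(dist, rep(0, rk)) + shifted
    }
    dist <- dist / sum(dist)
    v2 <- as.integer(round(2 * V))
    cdf_ge <- sum(dist[(v2 + 1L):length(dist)])
    cdf_le <- sum(dist[1:(v2 + 1L)])
    p <- switch(alternative,
                greater = cdf_ge,
                less = cdf_le,
                two.sided = min(1, 2 * min(cdf_ge, cdf_le)))
    method <- "exact sign enumeration"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    var_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- switch(alternative,
                greater = (V - mu_v - 0.5) / sqrt(var_v),
                less = (V - mu_v + 0.5) / sqrt(var_v),
                two.sided = (V - mu_v - sign(V - mu_v) * 0.5) / sqrt(var_v))
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal approximation with continuity correction"
  }
  tibble::tibble(statistic = V, p_value = p, n = n, n_zero = n_zero,
                 method = method, alternative = alternative)
}

#' Permutation test on activation indexes
#'
#' Estimates the null distribution of a statistic by random relabeling.
#' Two schemes:
#'
#' * `group_sign_flip`: `x` holds per-subject (relative) indexes -- a vector
#'   or a subjects x units matrix for maps. Under the null the indexes are
#'   symmetric around zero, so subject signs are flipped. For n <= 12
#'   subjects all 2^n sign patterns are enumerated (deterministic, exact);
#'   otherwise `n_perm` random flips are drawn and
#'   `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#' * `trial_label_shuffle`: `x` holds per-trial indexes and `labels` their
#'   condition labels; labels are shuffled and the difference of condition
#'   means (first level minus second) is recomputed.
#'
#' @param x numeric vector or matrix (see schemes).
#' @param scheme `"group_sign_flip"` or `"trial_label_shuffle"`.
#' @param n_perm number of permutations (>= 100); ignored when full
#'   enumeration applies.
#' @param seed RNG seed for sampled permutations.
#' @param statistic `"mean"` or `"t"` (sign-flip scheme).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param labels factor/character trial labels (shuffle scheme; exactly 2
#'   levels used).
#' @return A list of class `ctt_permutation`: `observed`, `p_values`,
#'   `null` (permutations x units matrix), `n_perm`, `scheme`, `exact`,
#'   `seed`, `alternative`.
#' @export
permutation_test <- function(x, scheme = c("group_sign_flip",
                                           "trial_label_shuffle"),
                             n_perm = 1000L, seed = 1L,
                             statistic = c("mean", "t"),
                             alternative = c("greater", "less", "two.sided"),
                             labels = NULL) {
  scheme <- match.arg(scheme)
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (n_perm < 100L) abort_ctt("n_perm must be at least 100")
  if (scheme == "group_sign_flip") {
    X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
    n <- nrow(X)
    stat_fun <- if (statistic == "mean") {
      function(M) colMeans(M)
    } else {
      function(M) colMeans(M) / (apply(M, 2L, stats::sd) / sqrt(nrow(M)))
    }
    observed <- stat_fun(X)
    exact <- n <= 12L
    if (exact) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    } else {
      signs <- with_seed(derive_seed(seed, "signflip"), {
        matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
      })
    }
    null <- t(apply(signs, 1L, function(s) stat_fun(X * s)))
    if (ncol(X) == 1L) null <- matrix(null, ncol = 1L)
  } else {
    if (is.null(labels)) abort_ctt("trial_label_shuffle requires `labels`")
    labels <- as.factor(labels)
    lv <- levels(labels)
    if (length(lv) < 2L) abort_ctt("trial labels need two levels")
    stat_fun <- function(lab) {
      mean(x[lab == lv[1]]) - mean(x[lab == lv[2]])
    }
    observed <- stat_fun(labels)
    exact <- FALSE
    null <- with_seed(derive_seed(seed, "shuffle"), {
      matrix(vapply(seq_len(n_perm),
                    function(i) stat_fun(sample(labels)), numeric(1)),
             ncol = 1L)
    })
  }
  side <- function(null_col, obs) {
    switch(alternative,
           greater = null_col >= obs,
           less = null_col <= obs,
           two.sided = abs(null_col) >= abs(obs))
  }
  n_eff <- nrow(null)
  p_values <- vapply(seq_along(observed), function(j) {
    hits <- sum(side(null[, j], observed[j]))
    if (exact) hits / n_eff else (1 + hits) / (1 + n_eff)
  }, numeric(1))
  structure(list(observed = observed, p_values = p_values, null = null,
                 n_perm = n_eff, scheme = scheme, exact = exact,
                 seed = seed, alternative = alternative),
            class = "ctt_permutation")
}

#' @export
print.ctt_permutation <- function(x, ...) {
  cat(sprintf("<ctt_permutation> scheme %s, %d permutations%s, %d unit(s)\n",
              x$scheme, x$n_perm, if (x$exact) " (full enumeration)" else "",
              length(x$observed)))
  invisible(x)
}

# connected-component labeling of a logical mask
# 1D: run adjacency; 3D: flood fill with 6- or 26-connectivity
label_components <- function(mask, connectivity = 6L) {
  if (is.null(dim(mask)) || length(dim(mask)) == 1L) {
    lab <- integer(length(mask))
    cur <- 0L
    for (i in seq_along(mask)) {
      if (!mask[i]) next
      if (i > 1L && mask[i - 1L]) lab[i] <- cur else {
        cur <- cur + 1L; lab[i] <- cur
      }
    }
    return(lab)
  }
  dims <- dim(mask)
  if (length(dims) != 3L) abort_ctt("cluster labeling supports 1D and 3D maps")
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else abort_ctt("connectivity must be 6 or 26")
  lab <- array(0L, dims)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      ci <- v0 %% dims[1] + 1L
      cj <- (v0 %/% dims[1]) %% dims[2] + 1L
      ck <- v0 %/% (dims[1] * dims[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        ni <- ci + offs[o, 1]; nj <- cj + offs[o, 2]; nk <- ck + offs[o, 3]
        if (ni < 1 || ni > dims[1] || nj < 1 || nj > dims[2] ||
            nk < 1 || nk > dims[3]) next
        nl <- (nk - 1L) * dims[1] * dims[2] + (nj - 1L) * dims[1] + ni
        if (mask[nl] && lab[nl] == 0L) {
          lab[nl] <- cur
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

#' Cluster-based family-wise-error correction
#'
#' Thresholds the observed statistic map and each permutation null map,
#' labels connected suprathreshold components (run adjacency in 1D time,
#' 6-connectivity by default in 3D volumes), records the maximal cluster
#' size of every null map, and assigns each observed cluster the FWE p-value
#' `(1 + #\{null max size >= cluster size\}) / (1 + n_perm)`.
#'
#' @param observed numeric vector (time) or 3D array (volume) of statistics,
#'   or a `ctt_statmap`.
#' @param null_maps matrix with one permutation per row (columns matching
#'   the flattened observed map).
#' @param forming_threshold either a numeric statistic cutoff, or
#'   `list(p = alpha)` to derive a per-unit cutoff from the null maps'
#'   pointwise `1 - alpha` quantile.
#' @param connectivity 6 or 26 (3D only).
#' @return A list of class `ctt_clusters`: `clusters` tibble (`id`, `size`,
#'   `units`, `p_fwe`), `threshold`, `null_max_sizes`, `n_perm`,
#'   `connectivity`.
#' @export
cluster_correct <- function(observed, null_maps, forming_threshold,
                            connectivity = 6L) {
  geometry <- NULL
  if (inherits(observed, "ctt_statmap")) {
    geometry <- observed$geometry
    observed <- observed$values
  }
  dims <- dim(observed)
  flat_obs <- as.vector(observed)
  null_maps <- as.matrix(null_maps)
  if (ncol(null_maps) != length(flat_obs)) {
    abort_ctt("observed and null maps have mismatched geometry")
  }
  thr <- if (is.list(forming_threshold)) {
    alpha <- forming_threshold$p %||%
      abort_ctt("forming_threshold list must carry `p`")
    apply(null_maps, 2L, stats::quantile, probs = 1 - alpha, names = FALSE,
          na.rm = TRUE)
  } else rep(forming_threshold, length(flat_obs))
  supra <- !is.na(flat_obs) & flat_obs > thr
  shape <- function(v) if (is.null(dims) || length(dims) < 2L) v else
    array(v, dims)
  lab <- label_components(shape(supra), connectivity)
  lab_flat <- as.vector(lab)
  n_perm <- nrow(null_maps)
  null_max <- vapply(seq_len(n_perm), function(i) {
    s <- !is.na(null_maps[i, ]) & null_maps[i, ] > thr
    l <- label_components(shape(s), connectivity)
    if (any(s)) max(tabulate(as.vector(l))) else 0L
  }, numeric(1))
  ids <- setdiff(unique(lab_flat), 0L)
  clusters <- if (length(ids)) {
    dplyr::bind_rows(lapply(sort(ids), function(id) {
      members <- which(lab_flat == id)
      size <- length(members)
      tibble::tibble(id = id, size = size, units = list(members),
                     p_fwe = (1 + sum(null_max >= size)) / (1 + n_perm))
    }))
  } else {
    tibble::tibble(id = integer(), size = integer(), units = list(),
                   p_fwe = numeric())
  }
  structure(list(clusters = clusters, threshold = thr,
                 null_max_sizes = null_max, n_perm = n_perm,
                 connectivity = connectivity, labels = lab_flat,
                 geometry = geometry),
            class = "ctt_clusters")
}

#' @export
print.ctt_clusters <- function(x, ...) {
  cat(sprintf("<ctt_clusters> %d cluster(s), %d permutations, connectivity %d\n",
              nrow(x$clusters), x$n_perm, x$connectivity))
  if (nrow(x$clusters)) print(x$clusters[c("id", "size", "p_fwe")])
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values p-values in (0, 1].
#' @return Adjusted p-values (step-up), same order as the input.
#' @export
fdr_correct <- function(p_values) {
  if (!length(p_values)) abort_ctt("empty p-value input")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    abort_ctt("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
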