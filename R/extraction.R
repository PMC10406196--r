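#' Run-wise or trial-wise least-squares pattern estimation
#'
#' Fits ordinary least squares `B = (X'X)^-1 X'Y` of a timepoints x V data
#' matrix on a timepoints x p design, returning beta maps, their t values
#' (beta divided by its standard error from the residual variance and the
#' diagonal of `(X'X)^-1`) and the residuals needed for noise modeling.
#' Run-wise extraction uses one regressor per condition; trial-wise
#' extraction uses one regressor per trial on the same shared design.
#'
#' @param data numeric matrix, timepoints x units.
#' @param design numeric matrix, timepoints x regressors; must have full
#'   column rank and fewer columns than rows.
#' @return A list of class `glm_result` with `betas` (p x V), `t_values`
#'   (p x V), `residuals` (timepoints x V) and `dof`.
#' @export
fit_run_glm <- function(data, design) {
  data <- as.matrix(data); design <- as.matrix(design)
  n <- nrow(data); p <- ncol(design)
  if (nrow(design) != n) abort_ctt("data and design must have equal timepoints")
  if (n <= p) abort_ctt("timepoints must exceed the number of regressors")
  qrX <- qr(design)
  if (qrX$rank < p) {
    dep <- colnames(design)[qrX$pivot[(qrX$rank + 1L):p]] %||%
      qrX$pivot[(qrX$rank + 1L):p]
    abort_ctt(paste0("rank-deficient design; dependent columns: ",
                     paste(dep, collapse = ", ")))
  }
  fit <- stats::lm.fit(design, data)
  betas <- matrix(fit$coefficients, p, ncol(data))
  resid <- matrix(fit$residuals, n, ncol(data))
  dof <- n - p
  sigma2 <- colSums(resid^2) / dof
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  rownames(betas) <- colnames(design)
  structure(
    list(betas = betas, t_values = betas / se, residuals = resid, dof = dof,
         design = design),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d regressors x %d units, dof = %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Shrinkage-regularized residual noise model
#'
#' Estimates the spatial noise covariance from GLM residuals, shrinks it
#' toward its diagonal with the analytic optimal intensity (the
#' Schafer-Strimmer estimator for a diagonal target: the summed sampling
#' variance of the off-diagonal entries over their summed squares), and
#' computes the symmetric whitener `W = S*^{-1/2}` used by multivariate
#' noise normalization and the cross-validated Mahalanobis distance.
#'
#' @param residuals numeric matrix (timepoints x V) or a `glm_result`.
#' @param shrinkage optional fixed gamma in [0, 1] overriding the analytic
#'   value; `gamma = 1` shrinks fully to the diagonal, making multivariate
#'   normalization coincide with univariate scaling.
#' @param min_samples minimum residual rows required (default 10).
#' @return A list of class `noise_model` with `covariance`, `shrinkage` and
#'   `whitener` (with `W S* W' ~ I`).
#' @export
noise_model <- function(residuals, shrinkage = NULL, min_samples = 10L) {
  if (inherits(residuals, "glm_result")) residuals <- residuals$residuals
  X <- as.matrix(residuals)
  n <- nrow(X); V <- ncol(X)
  if (n < min_samples) {
    abort_ctt(sprintf("noise_model needs at least %d residual samples", min_samples))
  }
  S <- crossprod(X) / (n - 1)
  if (is.null(shrinkage)) {
    X2 <- X^2
    varS <- (n / (n - 1)^3) * (crossprod(X2) - crossprod(X)^2 / n)
    off <- !diag(V)
    denom <- sum(S[off]^2)
    shrinkage <- if (denom <= 0) 1 else min(1, max(0, sum(varS[off]) / denom))
  }
  if (shrinkage < 0 || shrinkage > 1) {
    abort_ctt("shrinkage must lie in [0, 1]")
  }
  Sstar <- (1 - shrinkage) * S + shrinkage * diag(diag(S), V)
  eg <- eigen(Sstar, symmetric = TRUE)
  if (any(eg$values <= 1e-12 * max(eg$values))) {
    abort_ctt("covariance not positive-definite after shrinkage; increase shrinkage")
  }
  W <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  structure(list(covariance = Sstar, shrinkage = shrinkage, whitener = W),
            class = "noise_model")
}

#' Univariate or multivariate noise normalization
#'
#' Univariate normalization divides every unit by its residual standard
#' deviation (turning betas into t-like values); multivariate normalization
#' right-multiplies the patterns by the symmetric whitener of the
#' shrinkage-regularized residual covariance. Inputs are never mutated.
#'
#' @param ps a [pattern_set()] (or a `glm_result`, whose betas become the
#'   patterns with one observation per regressor).
#' @param noise a [noise_model()]; required for multivariate mode and usable
#'   for univariate mode (its covariance diagonal supplies the per-unit SDs).
#'   For univariate mode a `glm_result` may be given instead.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param condition,run labels to attach when `ps` is a `glm_result`.
#' @return A new [pattern_set()].
#' @export
noise_normalize <- function(ps, noise = NULL,
                            mode = c("univariate", "multivariate"),
                            condition = NULL, run = 1L) {
  mode <- match.arg(mode)
  if (inherits(ps, "glm_result")) {
    glm <- ps
    noise <- noise %||% noise_model(glm$residuals)
    condition <- condition %||% rownames(glm$betas) %||%
      paste0("reg", seq_len(nrow(glm$betas)))
    ps <- pattern_set(glm$betas, condition = condition, run = run)
  }
  stopifnot_pattern_set(ps)
  if (inherits(noise, "glm_result")) noise <- noise_model(noise$residuals)
  if (is.null(noise)) abort_ctt("a noise_model (or glm_result) is required")
  if (ncol(noise$covariance) != n_units(ps)) {
    abort_ctt("noise model dimension does not match the unit count")
  }
  if (mode == "univariate") {
    sds <- sqrt(diag(noise$covariance))
    bad <- which(sds == 0)
    if (length(bad)) {
      abort_ctt(paste0("zero residual SD at units: ",
                       paste(ps$unit_ids[bad], collapse = ", ")))
    }
    ps$patterns <- sweep(ps$patterns, 2L, sds, `/`)
  } else {
    ps$patterns <- ps$patterns %*% noise$whitener
  }
  ps_note(ps, "noise_normalize", list(mode = mode, shrinkage = noise$shrinkage))
}

#' Supertrial averaging
#'
#' Within each condition x run cell, trials are partitioned into seeded
#' random groups of `group_size` and averaged; a leftover smaller than the
#' group size is discarded. Averaging small sets of same-condition trials is
#' a standard signal-to-noise booster for time-resolved pattern analyses.
#' For epoch data the partition is over trials and the average is taken per
#' time bin across the grouped trials.
#'
#' @param ps a [pattern_set()].
#' @param group_size trials per supertrial (k >= 1; `k = 1` returns the
#'   input unchanged).
#' @param seed integer seed for the random partition.
#' @return A new [pattern_set()] of supertrials.
#' @export
make_supertrials <- function(ps, group_size, seed = 1L) {
  stopifnot_pattern_set(ps)
  if (!is_count(group_size)) abort_ctt("group_size must be a count >= 1")
  k <- as.integer(group_size)
  if (k == 1L) return(ps_note(ps, "make_supertrials", list(k = 1L)))
  has_bins <- !is.null(ps$obs[["time_bin"]])
  cell_key <- paste(ps$obs$condition, ps$obs$run, sep = "\r")
  trial_tab <- unique(ps$obs[c("condition", "run", "trial")])
  cells <- split(trial_tab$trial,
                 paste(trial_tab$condition, trial_tab$run, sep = "\r"))
  short <- names(cells)[vapply(cells, length, 1L) < k]
  if (length(short)) {
    abort_ctt(paste0("condition x run cells with fewer than ", k, " trials: ",
                     paste(gsub("\r", " / run ", short), collapse = "; ")))
  }
  rows <- list(); labs <- list()
  new_trial <- 0L
  for (cell in names(cells)) {
    trials <- cells[[cell]]
    perm <- with_seed(derive_seed(seed, "supertrials", cell), sample(trials))
    n_groups <- length(perm) %/% k
    for (g in seq_len(n_groups)) {
      members <- perm[((g - 1L) * k + 1L):(g * k)]
      sel <- ps$obs$trial %in% members & cell_key == cell
      new_trial <- new_trial + 1L
      if (has_bins) {
        for (b in sort(unique(ps$obs[["time_bin"]][sel]))) {
          sb <- sel & ps$obs[["time_bin"]] == b
          rows[[length(rows) + 1L]] <- colMeans(ps$patterns[sb, , drop = FALSE])
          labs[[length(labs) + 1L]] <- list(
            condition = ps$obs$condition[which(sel)[1]],
            run = ps$obs$run[which(sel)[1]],
            trial = new_trial, time_bin = b)
        }
      } else {
        rows[[length(rows) + 1L]] <- colMeans(ps$patterns[sel, , drop = FALSE])
        labs[[length(labs) + 1L]] <- list(
          condition = ps$obs$condition[which(sel)[1]],
          run = ps$obs$run[which(sel)[1]],
          trial = new_trial, time_bin = NA_integer_)
      }
    }
  }
  lab <- dplyr::bind_rows(lapply(labs, tibble::as_tibble))
  out <- pattern_set(do.call(rbind, rows), condition = lab$condition,
                     run = lab$run,
                     time_bin = if (has_bins) lab$time_bin,
                     trial = lab$trial,
                     unit_ids = ps$unit_ids, space = ps$space,
                     geometry = ps$geometry)
  out$provenance <- ps$provenance
  ps_note(out, "make_supertrials", list(k = k, seed = seed))
}

#' Temporal smoothing of epoch patterns
#'
#' Centered moving average over time bins within each trial; windows are
#' truncated at the epoch edges (no padding), so a constant-in-time trial is
#' a fixed point of the operation.
#'
#' @param ps an epoch [pattern_set()] (with `time_bin` labels).
#' @param window odd window width in bins (`1` is the identity).
#' @return A new [pattern_set()].
#' @export
smooth_temporal <- function(ps, window) {
  stopifnot_pattern_set(ps)
  if (is.null(ps$obs[["time_bin"]])) abort_ctt("smooth_temporal requires epoch data")
  if (!is_count(window) || window %% 2 == 0) {
    abort_ctt("window must be an odd count >= 1")
  }
  w <- as.integer(window)
  n_bins <- length(unique(ps$obs[["time_bin"]]))
  if (w > n_bins) abort_ctt("window exceeds the number of time bins")
  if (w == 1L) return(ps_note(ps, "smooth_temporal", list(window = 1L)))
  half <- (w - 1L) %/% 2L
  out <- ps$patterns
  for (tr in unique(ps$obs$trial)) {
    sel <- which(ps$obs$trial == tr)
    sel <- sel[order(ps$obs[["time_bin"]][sel])]
    bins <- ps$obs[["time_bin"]][sel]
    for (i in seq_along(sel)) {
      keep <- sel[abs(bins - bins[i]) <= half]
      out[sel[i], ] <- colMeans(ps$patterns[keep, , drop = FALSE])
    }
  }
  ps$patterns <- out
  ps_note(ps, "smooth_temporal", list(window = w))
}

#' Principal-component reduction fitted on localizer data
#'
#' Fits principal components on the training pattern set only (localizer
#' data by default, so no main-task information leaks into the projection),
#' retains the minimal number of components whose cumulative explained
#' variance reaches `variance_fraction`, and applies the same projection to
#' every pattern set in `apply_to`.
#'
#' @param train the [pattern_set()] the projection is fitted on.
#' @param apply_to a list of pattern sets to project with the fitted basis.
#' @param variance_fraction f in (0, 1]; `f = 1` keeps every
#'   nonzero-variance component.
#' @return A list with `train` and `applied` (projected pattern sets, space
#'   `"component"`), and `projection` (`center`, `rotation`, `n_components`,
#'   `explained`).
#' @export
reduce_dimensions <- function(train, apply_to = list(),
                              variance_fraction = 0.99) {
  stopifnot_pattern_set(train, "train")
  f <- variance_fraction
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
    abort_ctt("variance_fraction must lie in (0, 1]")
  }
  if (n_obs(train) < 2L) abort_ctt("PCA needs at least 2 training observations")
  pc <- stats::prcomp(train$patterns, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nonzero <- ev > max(ev) * 1e-12
  ev <- ev[nonzero]
  ratio <- cumsum(ev) / sum(ev)
  d <- which(ratio >= f - 1e-12)[1]
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  project <- function(ps) {
    stopifnot_pattern_set(ps)
    proj <- sweep(ps$patterns, 2L, pc$center) %*% rot
    out <- pattern_set(proj, condition = ps$obs$condition, run = ps$obs$run,
                       time_bin = ps$obs[["time_bin"]], trial = ps$obs$trial,
                       unit_ids = paste0("PC", seq_len(d)),
                       space = "component")
    out$provenance <- ps$provenance
    ps_note(out, "reduce_dimensions", list(f = f, n_components = d))
  }
  list(train = project(train),
       applied = lapply(apply_to, project),
       projection = list(center = pc$center, rotation = rot,
                         n_components = d, explained = ratio[d]))
}
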