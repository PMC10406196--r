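tracking_result <- function(df, metric, polarity, extra = list()) {
  out <- tibble::new_tibble(df, class = "ctt_tracking")
  attr(out, "metric") <- metric
  attr(out, "polarity") <- polarity
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

metric_polarity <- function(metric) {
  if (metric %in% c("euclidean", "sq_euclidean", "cv_sq_euclidean",
                    "mahalanobis_cv")) "lower_is_more_active"
  else "higher_is_more_active"
}

check_support <- function(main, ts) {
  if (!identical(main$unit_ids, ts$unit_ids)) {
    abort_ctt("main data and templates must share identical unit support")
  }
}

obs_label_cols <- function(ps) {
  df <- tibble::tibble(obs = seq_len(n_obs(ps)),
                       condition = ps$obs$condition,
                       chunk = ps$obs$run)
  if (!is.null(ps$obs[["time_bin"]])) df$time_bin <- ps$obs[["time_bin"]]
  df
}

#' Similarity-based activation indexes
#'
#' Computes, for every main-task observation and every canonical template,
#' the Pearson correlation (optionally Fisher-z transformed) or the
#' (squared) Euclidean distance between the observation's pattern and the
#' template. Correlations are read as "higher = more active"; distances as
#' "lower = more active" (the polarity is recorded on the result).
#'
#' @param main a main-task [pattern_set()].
#' @param ts a [estimate_templates()] result on the same unit support.
#' @param metric one of `"pearson"`, `"fisher_z"`, `"euclidean"`,
#'   `"sq_euclidean"`.
#' @return A `ctt_tracking` tibble with columns `obs`, `condition`, `chunk`
#'   (and `time_bin` for epoch data), `template`, `value`.
#' @export
similarity_index <- function(main, ts,
                             metric = c("pearson", "fisher_z", "euclidean",
                                        "sq_euclidean")) {
  metric <- match.arg(metric)
  stopifnot_pattern_set(main, "main")
  check_support(main, ts)
  X <- main$patterns
  Tm <- ts$templates
  if (metric %in% c("pearson", "fisher_z")) {
    sx <- apply(X, 1L, stats::sd)
    st <- apply(Tm, 1L, stats::sd)
    if (any(sx == 0)) {
      abort_ctt(paste0("zero-variance observation(s): ",
                       paste(which(sx == 0), collapse = ", ")))
    }
    if (any(st == 0)) {
      abort_ctt(paste0("zero-variance template(s): ",
                       paste(ts$conditions[st == 0], collapse = ", ")))
    }
    vals <- stats::cor(t(X), t(Tm))
    if (metric == "fisher_z") vals <- fisher_z(vals)
  } else {
    sq <- outer(rowSums(X^2), rowSums(Tm^2), `+`) - 2 * tcrossprod(X, Tm)
    sq[sq < 0] <- 0  # numerical guard
    vals <- if (metric == "euclidean") sqrt(sq) else sq
  }
  colnames(vals) <- ts$conditions
  df <- obs_label_cols(main)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(df, tibble::as_tibble(vals)),
    dplyr::all_of(ts$conditions), names_to = "template", values_to = "value")
  tracking_result(long, metric, metric_polarity(metric))
}

#' Cross-validated distance and correlation indexes
#'
#' Estimators that remove the positive noise bias of naive pattern distances
#' by combining independent main-task chunks, with the localizer templates
#' held fixed. For each main condition cell and template `T`:
#'
#' * `cv_sq_euclidean`: mean over ordered chunk pairs (c != c') of
#'   `(T - ybar_c)' (T - ybar_c')`, where `ybar_c` is the condition mean in
#'   chunk c. Unbiased around the true squared distance; in particular its
#'   expectation is 0 when the condition's true pattern equals the template.
#' * `mahalanobis_cv`: the same estimator after applying the noise model's
#'   whitener to templates and chunk means (a cross-validated Mahalanobis
#'   distance; requires `noise`).
#' * `cv_correlation`: a reliability-adjusted correlation: the mean over
#'   chunks of `cov(ybar_c, T)` divided by
#'   `sqrt(var(T) * mean over ordered pairs of cov(ybar_c, ybar_c'))`. The
#'   cross-chunk covariance in the denominator removes the noise inflation
#'   of the usual denominator; when it is non-positive (noise-dominated
#'   data) the index is `NA` with a warning.
#'
#' Negative values are genuine outcomes of these estimators and are
#' reported, never clipped; the result carries
#' `attr(, "may_be_negative") = TRUE`.
#'
#' @param ts a template set.
#' @param main a main-task [pattern_set()] with at least 2 chunks (in
#'   `run`).
#' @param metric `"cv_sq_euclidean"`, `"mahalanobis_cv"` or
#'   `"cv_correlation"`.
#' @param noise a [noise_model()] (required for `mahalanobis_cv`).
#' @return A `ctt_tracking` tibble with one row per main condition x
#'   template (`obs` and `chunk` are `NA`: the estimator pools chunks).
#' @export
crossvalidated_index <- function(ts, main,
                                 metric = c("cv_sq_euclidean",
                                            "mahalanobis_cv",
                                            "cv_correlation"),
                                 noise = NULL) {
  metric <- match.arg(metric)
  stopifnot_pattern_set(main, "main")
  check_support(main, ts)
  chunks <- sort(unique(main$obs$run))
  if (length(chunks) < 2L) {
    abort_ctt(paste0("cross-validated indexes need >= 2 independent main-task",
                     " chunks; split the main paradigm into separate,",
                     " equivalent runs"))
  }
  Tm <- ts$templates
  if (metric == "mahalanobis_cv") {
    if (is.null(noise)) abort_ctt("mahalanobis_cv requires a noise_model")
    W <- noise$whitener
    Tm <- Tm %*% W
  }
  conds <- unique(main$obs$condition)
  rows <- list()
  for (cond in conds) {
    Ybar <- t(vapply(chunks, function(ch) {
      sel <- main$obs$condition == cond & main$obs$run == ch
      colMeans(main$patterns[sel, , drop = FALSE])
    }, numeric(n_units(main))))
    if (metric == "mahalanobis_cv") Ybar <- Ybar %*% W
    C <- length(chunks)
    for (k in seq_len(nrow(Tm))) {
      if (metric == "cv_correlation") {
        tc <- Tm[k, ] - mean(Tm[k, ])
        Yc <- Ybar - rowMeans(Ybar)
        V1 <- ncol(Ybar) - 1
        num <- mean(Yc %*% tc) / V1
        G <- tcrossprod(Yc) / V1
        cross <- mean(G[upper.tri(G) | lower.tri(G)])
        var_t <- sum(tc^2) / V1
        val <- if (cross <= 0) {
          rlang::warn("non-positive cross-chunk covariance; cv_correlation is NA")
          NA_real_
        } else num / sqrt(var_t * cross)
      } else {
        D <- sweep(Ybar, 2L, Tm[k, ])  # rows: ybar_c - T
        G <- tcrossprod(D)
        val <- mean(G[upper.tri(G) | lower.tri(G)])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        obs = NA_integer_, condition = cond, chunk = NA_integer_,
        template = ts$conditions[k], value = val)
    }
  }
  pol <- if (metric == "cv_correlation") "higher_is_more_active" else
    "lower_is_more_active"
  tracking_result(dplyr::bind_rows(rows), metric, pol,
                  extra = list(may_be_negative = TRUE))
}

#' Variance partitioning across templates by multiple regression
#'
#' Regresses each (unit-centered) main-task pattern on the K (unit-centered)
#' template vectors simultaneously, so that templates sharing variance do
#' not double-count it. Centering across units removes the global-mean
#' component, which can reflect general task processing rather than
#' content-specific activation, and no intercept is fitted thereafter.
#' Returns per-template beta weights, the full-model R-squared, and signed
#' semi-partial correlations `sr_k = sign(beta_k) sqrt(R2_full -
#' R2_without_k)` -- each template's unique contribution.
#'
#' @param main a main-task [pattern_set()].
#' @param ts a template set on the same support; templates must not be
#'   collinear (condition number below `kappa_max`).
#' @param standardize scale patterns and templates to unit variance across
#'   units before fitting (betas become standardized; R-squared and
#'   semi-partials are unaffected).
#' @param value which quantity fills the `value` column: `"beta"` or
#'   `"semipartial"` (both are always returned as columns).
#' @param kappa_max collinearity threshold on the design condition number.
#' @return A `ctt_tracking` tibble with columns `beta`, `semipartial`,
#'   `r_squared` and `value`.
#' @export
regression_partition <- function(main, ts, standardize = FALSE,
                                 value = c("beta", "semipartial"),
                                 kappa_max = 1e8) {
  value <- match.arg(value)
  stopifnot_pattern_set(main, "main")
  check_support(main, ts)
  K <- nrow(ts$templates)
  Tm <- ts$templates - rowMeans(ts$templates)
  Y <- main$patterns - rowMeans(main$patterns)
  if (standardize) {
    Tm <- Tm / apply(Tm, 1L, stats::sd)
    Y <- Y / apply(Y, 1L, stats::sd)
  }
  X <- t(Tm)  # units x K
  sv <- svd(X, nu = 0, nv = 0)$d
  kappa <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (kappa > kappa_max) {
    abort_ctt(sprintf("collinear templates: condition number %.3g", kappa))
  }
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  B <- XtX_inv %*% crossprod(X, t(Y))           # K x n_obs
  tss <- rowSums(Y^2)
  rss <- tss - colSums(B * crossprod(X, t(Y)))  # B'X'y per obs
  r2_full <- 1 - rss / tss
  # R2 without template k, for every k, via rank-one downdating of each fit
  r2_wo <- matrix(0, K, n_obs(main))
  if (K > 1L) {
    for (k in seq_len(K)) {
      Xk <- X[, -k, drop = FALSE]
      Bk <- solve(crossprod(Xk), crossprod(Xk, t(Y)))
      rss_k <- tss - colSums(Bk * crossprod(Xk, t(Y)))
      r2_wo[k, ] <- 1 - rss_k / tss
    }
  }
  sr <- sign(B) * sqrt(pmax(sweep(-r2_wo, 2L, r2_full, `+`), 0))
  df <- obs_label_cols(main)
  long <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    dplyr::mutate(df, template = ts$conditions[k], beta = unname(B[k, ]),
                  semipartial = unname(sr[k, ]),
                  r_squared = unname(r2_full))
  }))
  long <- dplyr::arrange(long, .data$obs)
  long$value <- if (value == "beta") long$beta else long$semipartial
  tracking_result(long,
                  if (value == "beta") "regression_beta" else "semipartial_r",
                  "higher_is_more_active")
}

#' Classifier-based template tracking
#'
#' Trains a linear discriminant with a shrinkage-regularized pooled
#' within-class covariance on the localizer exemplars and applies it to the
#' main-task patterns. For each observation it returns the predicted
#' template label and, per template, the signed distance `d` to the
#' one-vs-rest hyperplane (positive = template side; the magnitude is the
#' classifier's confidence). Overall accuracy is computed over main
#' observations whose condition matches a template name.
#'
#' @param ts a template set built with `keep_exemplars = TRUE` (at least 2
#'   exemplars per condition, K >= 2).
#' @param main a main-task [pattern_set()].
#' @param shrinkage covariance shrinkage intensity toward the diagonal
#'   (default 0.1); 0 requires a nonsingular pooled covariance.
#' @return A `ctt_tracking` tibble (metric `"classifier_d"`) with a
#'   `predicted` column; `attr(, "accuracy")` holds the overall accuracy
#'   (NA when no main label matches a template).
#' @export
classifier_tracking <- function(ts, main, shrinkage = 0.1) {
  stopifnot_pattern_set(main, "main")
  if (is.null(ts$exemplars)) {
    abort_ctt("classifier tracking requires templates with exemplars")
  }
  check_support(main, ts)
  ex <- ts$exemplars
  K <- length(ts$conditions)
  if (K < 2L) abort_ctt("classifier tracking requires K >= 2 conditions")
  counts <- table(ex$obs$condition)
  short <- ts$conditions[counts[ts$conditions] < 2L]
  if (length(short)) {
    abort_ctt(paste0("conditions with < 2 exemplars: ",
                     paste(short, collapse = ", ")))
  }
  V <- n_units(ex)
  mus <- t(vapply(ts$conditions, function(k) {
    colMeans(ex$patterns[ex$obs$condition == k, , drop = FALSE])
  }, numeric(V)))
  centered <- ex$patterns -
    mus[match(ex$obs$condition, ts$conditions), , drop = FALSE]
  Sw <- crossprod(centered) / (n_obs(ex) - K)
  Sw_shrunk <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), V)
  eg <- eigen(Sw_shrunk, symmetric = TRUE)
  if (any(eg$values <= 1e-12 * max(eg$values, 1e-300))) {
    abort_ctt("degenerate pooled covariance; increase `shrinkage`")
  }
  Sinv <- eg$vectors %*% (t(eg$vectors) / eg$values)
  # multi-class discriminant scores (equal priors)
  A <- mus %*% Sinv                      # K x V
  const <- -0.5 * rowSums(A * mus)
  scores <- main$patterns %*% t(A) + rep(const, each = n_obs(main))
  pred_idx <- apply(scores, 1L, which.max)  # ties -> lowest condition index
  predicted <- ts$conditions[pred_idx]
  # one-vs-rest signed hyperplane distances
  dvals <- matrix(0, n_obs(main), K)
  for (k in seq_len(K)) {
    mu_rest <- colMeans(mus[-k, , drop = FALSE])
    w <- drop(Sinv %*% (mus[k, ] - mu_rest))
    m <- (mus[k, ] + mu_rest) / 2
    dvals[, k] <- (main$patterns %*% w - sum(m * w)) / sqrt(sum(w^2))
  }
  colnames(dvals) <- ts$conditions
  df <- obs_label_cols(main)
  df$predicted <- predicted
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(df, tibble::as_tibble(dvals)),
    dplyr::all_of(ts$conditions), names_to = "template", values_to = "value")
  labeled <- main$obs$condition %in% ts$conditions
  acc <- if (any(labeled)) {
    mean(predicted[labeled] == main$obs$condition[labeled])
  } else NA_real_
  tracking_result(long, "classifier_d", "higher_is_more_active",
                  extra = list(accuracy = acc))
}

#' Relative activation index: target template vs baseline template
#'
#' The interpretable quantity in canonical template tracking: the target
#' template's activation index minus a baseline (control) template's index,
#' oriented so that positive always means "target more active" (the
#' subtraction is flipped for distance metrics). Pearson correlations are
#' Fisher-z transformed before subtraction (variance stabilization);
#' `fisher_z` inputs are subtracted as-is.
#'
#' @param tr a `ctt_tracking` result.
#' @param target,baseline template names to contrast (must differ).
#' @return A `ctt_tracking` tibble with a `contrast` column instead of
#'   `template`; metric gains a `"relative_"` prefix.
#' @export
relative_activation <- function(tr, target, baseline) {
  if (!inherits(tr, "ctt_tracking")) abort_ctt("`tr` must be a ctt_tracking")
  if (identical(target, baseline)) abort_ctt("target and baseline must differ")
  metric <- attr(tr, "metric")
  polarity <- attr(tr, "polarity")
  have <- unique(tr$template)
  missing <- setdiff(c(target, baseline), have)
  if (length(missing)) {
    abort_ctt(paste0("template(s) not present: ", paste(missing, collapse = ", ")))
  }
  transf <- if (metric == "pearson") fisher_z else identity
  id_cols <- intersect(c("obs", "condition", "chunk", "time_bin"), names(tr))
  wide <- tidyr::pivot_wider(
    tr[c(id_cols, "template", "value")],
    names_from = "template", values_from = "value")
  delta <- transf(wide[[target]]) - transf(wide[[baseline]])
  if (polarity == "lower_is_more_active") delta <- -delta
  out <- dplyr::mutate(wide[id_cols],
                       contrast = paste0(target, "_vs_", baseline),
                       value = delta)
  tracking_result(out, paste0("relative_", metric), "higher_is_more_active",
                  extra = list(target = target, baseline = baseline))
}
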