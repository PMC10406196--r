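#' Estimate canonical templates from a localizer pattern set
#'
#' The canonical template of each localizer condition is the arithmetic mean
#' of that condition's activity patterns. With `keep_runwise` the mean is
#' taken per run first and the template is the grand mean of the run-wise
#' estimates (these are retained for reliability diagnostics); with
#' `keep_exemplars` the individual localizer patterns are retained for
#' classifier-based tracking and cross-validated estimators.
#'
#' @param loc a localizer [pattern_set()]; every condition must have at
#'   least one observation.
#' @param keep_exemplars keep the localizer observations inside the result.
#' @param keep_runwise also store per-run template estimates (requires at
#'   least 2 runs).
#' @return A list of class `template_set` with `templates` (K x V),
#'   `conditions`, `unit_ids`, `space`, optional `exemplars` and
#'   `runwise_estimates` (list of K x V matrices, one per run).
#' @export
estimate_templates <- function(loc, keep_exemplars = FALSE,
                               keep_runwise = FALSE) {
  stopifnot_pattern_set(loc, "loc")
  conds <- unique(loc$obs$condition)
  counts <- table(loc$obs$condition)
  empty <- setdiff(conds, names(counts)[counts > 0])
  if (length(empty)) {
    abort_ctt(paste0("empty condition(s): ", paste(empty, collapse = ", ")))
  }
  runs <- sort(unique(loc$obs$run))
  if (keep_runwise && length(runs) < 2L) {
    abort_ctt("keep_runwise requires at least 2 localizer runs")
  }
  cond_mean <- function(sel) colMeans(loc$patterns[sel, , drop = FALSE])
  runwise <- NULL
  if (keep_runwise) {
    runwise <- lapply(runs, function(r) {
      m <- t(vapply(conds, function(k) {
        sel <- loc$obs$condition == k & loc$obs$run == r
        if (!any(sel)) abort_ctt(sprintf(
          "empty condition(s) in run %d: %s", r, k))
        cond_mean(sel)
      }, numeric(n_units(loc))))
      rownames(m) <- conds
      m
    })
    templates <- Reduce(`+`, runwise) / length(runwise)
  } else {
    templates <- t(vapply(conds, function(k) {
      cond_mean(loc$obs$condition == k)
    }, numeric(n_units(loc))))
  }
  rownames(templates) <- conds
  structure(
    list(templates = templates, conditions = conds,
         unit_ids = loc$unit_ids, space = loc$space,
         geometry = loc$geometry,
         exemplars = if (keep_exemplars) loc,
         runwise_estimates = runwise),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d conditions x %d units (%s)\n",
              nrow(x$templates), ncol(x$templates), x$space))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  if (!is.null(x$exemplars)) cat("  exemplars retained\n")
  if (!is.null(x$runwise_estimates)) {
    cat("  run-wise estimates:", length(x$runwise_estimates), "runs\n")
  }
  invisible(x)
}

#' Restrict a pattern or template set to an ROI mask
#'
#' Keeps only the in-mask voxels of a volumetric pattern set (or template
#' set); unit ids are preserved so statistic maps can later be written back
#' into the source geometry.
#'
#' @param ps a volumetric [pattern_set()] or `template_set`.
#' @param mask a 3D logical/0-1 array matching the source geometry, or an
#'   `RNifti` image.
#' @return The input restricted to in-mask units.
#' @export
select_roi <- function(ps, mask) {
  mask <- as.array(mask)
  geom <- ps$geometry
  if (is.null(geom) || !identical(ps$space, "volume")) {
    abort_ctt("select_roi requires volumetric data (space = \"volume\")")
  }
  if (!identical(as.integer(dim(mask)), as.integer(geom$dim))) {
    abort_ctt("mask geometry does not match the pattern-set volume")
  }
  keep_ids <- sort(vox_to_id(which(mask != 0, arr.ind = TRUE), geom$dim))
  if (!length(keep_ids)) abort_ctt("mask is empty")
  if (inherits(ps, "template_set")) {
    idx <- match(as.character(keep_ids), ps$unit_ids)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) abort_ctt("mask does not overlap the template support")
    ps$templates <- ps$templates[, idx, drop = FALSE]
    ps$unit_ids <- ps$unit_ids[idx]
    return(ps)
  }
  stopifnot_pattern_set(ps)
  idx <- match(as.character(keep_ids), ps$unit_ids)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) abort_ctt("mask does not overlap the available units")
  ps_note(ps_subset_units(ps, idx), "select_roi",
          list(n_voxels = length(idx)))
}

#' Select (and optionally collapse) a time window
#'
#' Keeps the epoch bins inside the half-open window `[start, end)` (0-based
#' bin ids). With `collapse = TRUE` the retained bins are averaged within
#' each trial, yielding one pattern per trial.
#'
#' @param ps an epoch [pattern_set()].
#' @param window integer vector `c(start, end)`, half-open.
#' @param collapse average the in-window bins per trial.
#' @return A new [pattern_set()].
#' @export
select_time_window <- function(ps, window, collapse = FALSE) {
  stopifnot_pattern_set(ps)
  if (is.null(ps$obs[["time_bin"]])) {
    abort_ctt("select_time_window requires epoch data")
  }
  sel <- ps$obs[["time_bin"]] >= window[1] & ps$obs[["time_bin"]] < window[2]
  if (!any(sel)) abort_ctt("empty time window")
  out <- ps_subset_obs(ps, which(sel))
  if (collapse) {
    trials <- unique(out$obs[c("condition", "run", "trial")])
    m <- t(vapply(seq_len(nrow(trials)), function(i) {
      s <- out$obs$trial == trials$trial[i]
      colMeans(out$patterns[s, , drop = FALSE])
    }, numeric(n_units(out))))
    out <- pattern_set(m, condition = trials$condition, run = trials$run,
                       trial = trials$trial, unit_ids = ps$unit_ids,
                       space = ps$space, geometry = ps$geometry)
    out$provenance <- ps$provenance
  }
  ps_note(out, "select_time_window",
          list(window = as.integer(window), collapse = collapse))
}
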