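#' Integer voxel offsets of a searchlight sphere
#'
#' All integer `(dx, dy, dz)` with `dx^2 + dy^2 + dz^2 <= radius^2`, in
#' deterministic lexicographic order.
#'
#' @param radius sphere radius in voxels (>= 0).
#' @return An integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    abort_ctt("radius must be a nonnegative number")
  }
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, c("dx", "dy", "dz")]
  g <- g[order(g$dx, g$dy, g$dz), ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

#' Tracking configuration for mapping drivers
#'
#' Bundles the metric and the target/baseline contrast that [run_searchlight()]
#' and [run_temporal()] reduce to a per-center (or per-bin) scalar: the mean
#' relative activation index over target-condition observations.
#'
#' @param metric a [similarity_index()] metric (default `"pearson"`).
#' @param target,baseline template conditions for the relative index. With
#'   both omitted the scalar is instead the mean own-condition index (each
#'   observation against its own condition's template, Fisher-z for
#'   correlation metrics) -- an absolute index that is symmetric in the two
#'   datasets and useful for diagnostics, but not baseline-controlled.
#' @param reducer `"mean"` or `"median"` across observations.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(metric = "pearson", target = NULL,
                           baseline = NULL,
                           reducer = c("mean", "median")) {
  reducer <- match.arg(reducer)
  if (is.null(target) != is.null(baseline)) {
    abort_ctt("supply both target and baseline, or neither")
  }
  structure(list(metric = metric, target = target, baseline = baseline,
                 reducer = reducer),
            class = "tracker_config")
}

# scalar tracking outcome for one localizer/main pair on a shared support;
# lean matrix path (no container round-trips) for the correlation metrics
# the mapping drivers loop over many times
track_scalar <- function(loc, main, tracker) {
  if (is.null(tracker$target)) {
    if (!tracker$metric %in% c("pearson", "fisher_z")) {
      abort_ctt("the absolute own-condition tracker supports correlation metrics")
    }
    conds <- unique(loc$obs$condition)
    Tm <- t(vapply(conds, function(k) {
      colMeans(loc$patterns[loc$obs$condition == k, , drop = FALSE])
    }, numeric(n_units(loc))))
    r <- stats::cor(t(main$patterns), t(Tm))
    own <- r[cbind(seq_len(n_obs(main)),
                   match(main$obs$condition, conds))]
    vals <- fisher_z(own)
    return(if (tracker$reducer == "median") stats::median(vals)
           else mean(vals))
  }
  if (tracker$metric %in% c("pearson", "fisher_z")) {
    Tt <- colMeans(loc$patterns[loc$obs$condition == tracker$target, ,
                                drop = FALSE])
    Tb <- colMeans(loc$patterns[loc$obs$condition == tracker$baseline, ,
                                drop = FALSE])
    sel <- main$obs$condition == tracker$target
    X <- main$patterns[if (any(sel)) sel else TRUE, , drop = FALSE]
    r <- stats::cor(t(X), cbind(Tt, Tb))
    vals <- fisher_z(r[, 1]) - fisher_z(r[, 2])
  } else {
    ts <- estimate_templates(loc)
    tr <- similarity_index(main, ts, metric = tracker$metric)
    rel <- relative_activation(tr, tracker$target, tracker$baseline)
    vals <- rel$value[rel$condition == tracker$target]
    if (!length(vals)) vals <- rel$value
  }
  if (tracker$reducer == "median") stats::median(vals) else mean(vals)
}

new_stat_map <- function(values, geometry, statistic) {
  structure(list(values = values, geometry = geometry, statistic = statistic),
            class = "ctt_statmap")
}

#' @export
print.ctt_statmap <- function(x, ...) {
  kind <- x$geometry$type
  cat(sprintf("<ctt_statmap> %s map of '%s'; %d values (%d missing)\n",
              kind, x$statistic, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Searchlight template tracking
#'
#' Iterates a sphere over every in-mask voxel of a volumetric dataset. At
#' each center, both the localizer and the main-task patterns are restricted
#' to the in-mask voxels inside the sphere, canonical templates are
#' estimated locally, the tracking metric is computed, and the mean relative
#' activation index across target-condition observations is assigned to the
#' center voxel. Spheres truncated below `min_voxels` in-mask voxels are
#' skipped (NA in the map).
#'
#' @param loc,main volumetric [pattern_set()]s in the same geometry and on
#'   the same unit support.
#' @param tracker a [tracker_config()].
#' @param radius sphere radius in voxels.
#' @param mask optional 3D logical array; defaults to the voxels present in
#'   the data.
#' @param min_voxels minimum in-mask sphere size (default 12).
#' @return A `ctt_statmap` whose `values` is a 3D array (NA outside valid
#'   centers).
#' @export
run_searchlight <- function(loc, main, tracker, radius, mask = NULL,
                            min_voxels = 12L) {
  stopifnot_pattern_set(loc, "loc"); stopifnot_pattern_set(main, "main")
  if (!identical(loc$geometry$dim, main$geometry$dim)) {
    abort_ctt("localizer and main-task volumes have mismatched geometry")
  }
  check_support(main, estimate_templates(loc))
  dims <- loc$geometry$dim
  avail_ids <- as.integer(loc$unit_ids)
  if (is.null(mask)) {
    mask <- array(FALSE, dims)
    mask[id_to_vox(avail_ids, dims)] <- TRUE
  }
  if (!identical(as.integer(dim(mask)), as.integer(dims))) {
    abort_ctt("mask geometry does not match the data volume")
  }
  offs <- sphere_offsets(radius)
  if (tracker$metric %in% c("pearson", "fisher_z") && nrow(offs) == 1L) {
    abort_ctt("radius 0 yields single-voxel spheres: correlation metrics are undefined")
  }
  centers <- which(mask, arr.ind = TRUE)
  if (!nrow(centers)) abort_ctt("no valid searchlight centers in mask")
  col_of_id <- rep(NA_integer_, prod(dims))
  col_of_id[avail_ids + 1L] <- seq_along(avail_ids)
  in_mask_lin <- as.vector(mask)
  # precompute localizer condition means once; per-sphere templates are
  # column subsets of this matrix
  conds <- unique(loc$obs$condition)
  loc_means <- t(vapply(conds, function(k) {
    colMeans(loc$patterns[loc$obs$condition == k, , drop = FALSE])
  }, numeric(n_units(loc))))
  main_target <- main$patterns[main$obs$condition == tracker$target, ,
                               drop = FALSE]
  if (!nrow(main_target)) main_target <- main$patterns
  ti <- match(tracker$target, conds)
  bi <- match(tracker$baseline, conds)
  if (is.na(ti) || is.na(bi)) {
    abort_ctt("tracker target/baseline must be localizer conditions")
  }
  vals <- array(NA_real_, dims)
  n_centers <- nrow(centers)
  for (ci in seq_len(n_centers)) {
    cc <- centers[ci, ]
    vx <- sweep(offs, 2L, as.integer(cc), `+`)
    ok <- vx[, 1] >= 1 & vx[, 1] <= dims[1] &
      vx[, 2] >= 1 & vx[, 2] <= dims[2] &
      vx[, 3] >= 1 & vx[, 3] <= dims[3]
    vx <- vx[ok, , drop = FALSE]
    lin <- (vx[, 3] - 1L) * dims[1] * dims[2] + (vx[, 2] - 1L) * dims[1] + vx[, 1]
    lin <- lin[in_mask_lin[lin]]
    cols <- col_of_id[vox_to_id(id_to_vox_from_lin(lin, dims), dims) + 1L]
    cols <- cols[!is.na(cols)]
    if (length(cols) < min_voxels) next
    Tm <- loc_means[c(ti, bi), cols, drop = FALSE]
    X <- main_target[, cols, drop = FALSE]
    sx <- matrixStats_rowSds(X); st <- matrixStats_rowSds(Tm)
    if (any(st == 0) || any(sx == 0)) next
    r <- stats::cor(t(X), t(Tm))
    rel <- fisher_z(pmin(pmax(r[, 1], -1), 1)) -
      fisher_z(pmin(pmax(r[, 2], -1), 1))
    vals[cc[1], cc[2], cc[3]] <- if (tracker$reducer == "median") {
      stats::median(rel)
    } else mean(rel)
  }
  new_stat_map(vals,
               geometry = list(type = "volume", dim = dims,
                               affine = loc$geometry$affine, mask = mask),
               statistic = paste0("mean_relative_", tracker$metric))
}

# R (Fortran-order) linear index -> 1-based voxel coordinates
id_to_vox_from_lin <- function(lin, dims) {
  l0 <- lin - 1L
  i <- l0 %% dims[1]
  j <- (l0 %/% dims[1]) %% dims[2]
  k <- l0 %/% (dims[1] * dims[2])
  cbind(i, j, k) + 1L
}

matrixStats_rowSds <- function(m) {
  apply(m, 1L, stats::sd)
}

#' Time-resolved tracking and temporal generalization
#'
#' With `generalize = FALSE`, tracks templates estimated at each time bin on
#' main-task patterns from the same bin, producing a time-course statistic
#' map. With `generalize = TRUE`, templates from every localizer bin t are
#' tracked on main-task patterns from every bin t', producing the full
#' T_localizer x T_main generalization matrix; its diagonal (where both axes
#' share bins) equals the time-resolved output exactly, by construction.
#'
#' @param loc,main epoch [pattern_set()]s sharing channel support.
#' @param tracker a [tracker_config()].
#' @param generalize compute the full generalization matrix.
#' @return A `ctt_statmap` (time) or a `ctt_tgm` (list with `values`
#'   matrix, `loc_bins`, `main_bins`).
#' @export
run_temporal <- function(loc, main, tracker, generalize = FALSE) {
  stopifnot_pattern_set(loc, "loc"); stopifnot_pattern_set(main, "main")
  if (is.null(loc$obs[["time_bin"]]) || is.null(main$obs[["time_bin"]])) {
    abort_ctt("run_temporal requires epoch data on both inputs")
  }
  if (!identical(loc$unit_ids, main$unit_ids)) {
    abort_ctt("localizer and main data must share channel support")
  }
  loc_bins <- sort(unique(loc$obs[["time_bin"]]))
  main_bins <- sort(unique(main$obs[["time_bin"]]))
  cell <- function(tl, tm) {
    lb <- ps_subset_obs(loc, which(loc$obs[["time_bin"]] == tl))
    mb <- ps_subset_obs(main, which(main$obs[["time_bin"]] == tm))
    track_scalar(lb, mb, tracker)
  }
  if (generalize) {
    vals <- matrix(NA_real_, length(loc_bins), length(main_bins),
                   dimnames = list(loc_bins, main_bins))
    for (i in seq_along(loc_bins)) {
      for (j in seq_along(main_bins)) {
        vals[i, j] <- cell(loc_bins[i], main_bins[j])
      }
    }
    return(structure(list(values = vals, loc_bins = loc_bins,
                          main_bins = main_bins,
                          statistic = paste0("mean_relative_", tracker$metric)),
                     class = "ctt_tgm"))
  }
  shared <- intersect(loc_bins, main_bins)
  if (!length(shared)) abort_ctt("no shared time bins between datasets")
  vals <- vapply(shared, function(b) cell(b, b), numeric(1))
  names(vals) <- shared
  new_stat_map(vals, geometry = list(type = "time", bins = shared),
               statistic = paste0("mean_relative_", tracker$metric))
}

#' @export
print.ctt_tgm <- function(x, ...) {
  cat(sprintf("<ctt_tgm> %d localizer bins x %d main-task bins ('%s')\n",
              nrow(x$values), ncol(x$values), x$statistic))
  invisible(x)
}
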