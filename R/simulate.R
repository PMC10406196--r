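#' Simulation specification for template-tracking validation data
#'
#' Defines a seeded synthetic experiment: a localizer phase whose trials are
#' condition templates plus spatially correlated Gaussian noise, and a main
#' task whose trials are weighted mixtures of those templates plus noise,
#' with optional per-chunk baseline shifts, a temporal (epoch) layout, or a
#' 3D volumetric embedding inside an ROI box. The defaults describe the
#' reference validation setting used throughout the package tests: two
#' template conditions, 200 units, noise SD 0.5, four localizer runs and
#' five main-task chunks.
#'
#' @param n_units number of spatial units V (ignored in volume mode, where
#'   V = prod(volume_shape)).
#' @param n_conditions number of template conditions K.
#' @param n_localizer_trials_per_condition localizer trials per condition
#'   (must be divisible by `n_runs_localizer`).
#' @param n_main_trials_per_condition main-task trials per condition (must be
#'   divisible by `n_chunks_main`).
#' @param n_runs_localizer,n_chunks_main numbers of localizer runs and of
#'   independent main-task chunks.
#' @param noise_sd per-unit noise standard deviation sigma (>= 0).
#' @param spatial_corr rho in [0, 1): mixing weight of the smooth spatial
#'   noise component. The noise covariance is
#'   sigma^2 * ((1 - rho) I + rho S), S a squared-exponential kernel with
#'   length-scale 2 over unit index (1D) or voxel coordinates (3D).
#' @param template_corr target pairwise correlation of the true templates;
#'   must satisfy |r| < 1 and r > -1/(K-1) so the template correlation
#'   matrix is positive definite.
#' @param activation_weights named list mapping each main-task condition to a
#'   length-K weight vector (ground truth). Default: one-hot on the
#'   condition's own template.
#' @param baseline_shift_sd SD of the per-chunk additive offset applied to
#'   every unit of main-task trials (0 disables it).
#' @param mode `"pattern"` (plain matrix), `"volume"` (3D embedding) or
#'   `"epoch"` (time-resolved).
#' @param volume_shape,roi_box volume mode only: 3D grid dimensions, and the
#'   ROI as `list(start, end)` of 1-based inclusive voxel coordinates.
#'   Templates occupy only ROI voxels; everything else is pure noise.
#' @param n_time_bins,active_window epoch mode only: number of time bins and
#'   the half-open 0-based bin window `[start, end)` in which templates are
#'   active (boxcar); outside it trials are pure noise.
#' @param seed integer RNG seed; all datasets are bit-reproducible under it.
#'
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_units = 200L, n_conditions = 2L,
                     n_localizer_trials_per_condition = 40L,
                     n_main_trials_per_condition = 40L,
                     n_runs_localizer = 4L, n_chunks_main = 5L,
                     noise_sd = 0.5, spatial_corr = 0,
                     template_corr = 0, activation_weights = NULL,
                     baseline_shift_sd = 0,
                     mode = c("pattern", "volume", "epoch"),
                     volume_shape = NULL, roi_box = NULL,
                     n_time_bins = NULL, active_window = NULL,
                     seed = 1L) {
  mode <- match.arg(mode)
  counts <- list(n_units = n_units, n_conditions = n_conditions,
                 n_localizer_trials_per_condition = n_localizer_trials_per_condition,
                 n_main_trials_per_condition = n_main_trials_per_condition,
                 n_runs_localizer = n_runs_localizer,
                 n_chunks_main = n_chunks_main)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]])) {
      abort_ctt(sprintf("invalid sim_spec field `%s`: must be a count >= 1", nm))
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort_ctt("invalid sim_spec field `noise_sd`: must be >= 0")
  }
  if (spatial_corr < 0 || spatial_corr >= 1) {
    abort_ctt("invalid sim_spec field `spatial_corr`: must be in [0, 1)")
  }
  K <- as.integer(n_conditions)
  if (K > 1L &&
      (abs(template_corr) >= 1 || template_corr <= -1 / (K - 1))) {
    abort_ctt(paste0("invalid sim_spec field `template_corr`: needs |r| < 1",
                     " and r > -1/(K-1) for a positive-definite construction"))
  }
  if (baseline_shift_sd < 0) {
    abort_ctt("invalid sim_spec field `baseline_shift_sd`: must be >= 0")
  }
  if (n_localizer_trials_per_condition %% n_runs_localizer != 0) {
    abort_ctt(paste0("invalid sim_spec: n_localizer_trials_per_condition must",
                     " be divisible by n_runs_localizer (balanced runs)"))
  }
  if (n_main_trials_per_condition %% n_chunks_main != 0) {
    abort_ctt(paste0("invalid sim_spec: n_main_trials_per_condition must be",
                     " divisible by n_chunks_main (balanced chunks)"))
  }
  if (mode == "volume") {
    if (is.null(volume_shape) || length(volume_shape) != 3L) {
      abort_ctt("invalid sim_spec field `volume_shape`: 3 integers required")
    }
    if (is.null(roi_box) || length(roi_box) != 2L) {
      abort_ctt("invalid sim_spec field `roi_box`: list(start, end) required")
    }
    if (any(roi_box[[1]] < 1) || any(roi_box[[2]] > volume_shape) ||
        any(roi_box[[2]] < roi_box[[1]])) {
      abort_ctt("invalid sim_spec field `roi_box`: box must lie inside volume_shape")
    }
    n_units <- prod(volume_shape)
  }
  if (mode == "epoch") {
    if (!is_count(n_time_bins)) {
      abort_ctt("invalid sim_spec field `n_time_bins`: count required in epoch mode")
    }
    active_window <- active_window %||% c(0L, n_time_bins)
    if (length(active_window) != 2L || active_window[1] < 0 ||
        active_window[2] > n_time_bins || active_window[2] <= active_window[1]) {
      abort_ctt("invalid sim_spec field `active_window`: need 0 <= start < end <= n_time_bins")
    }
  }
  conds <- paste0("cond", seq_len(K))
  if (is.null(activation_weights)) {
    activation_weights <- stats::setNames(
      lapply(seq_len(K), function(k) as.numeric(seq_len(K) == k)), conds)
  }
  if (!all(vapply(activation_weights, length, 1L) == K)) {
    abort_ctt("invalid sim_spec field `activation_weights`: weight vectors must have length K")
  }
  structure(
    list(n_units = as.integer(n_units), n_conditions = K,
         n_localizer_trials_per_condition = as.integer(n_localizer_trials_per_condition),
         n_main_trials_per_condition = as.integer(n_main_trials_per_condition),
         n_runs_localizer = as.integer(n_runs_localizer),
         n_chunks_main = as.integer(n_chunks_main),
         noise_sd = noise_sd, spatial_corr = spatial_corr,
         template_corr = template_corr,
         activation_weights = activation_weights,
         baseline_shift_sd = baseline_shift_sd, mode = mode,
         volume_shape = if (mode == "volume") as.integer(volume_shape),
         roi_box = if (mode == "volume") lapply(roi_box, as.integer),
         n_time_bins = if (mode == "epoch") as.integer(n_time_bins),
         active_window = if (mode == "epoch") as.integer(active_window),
         conditions = conds, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# squared-exponential spatial kernel, length-scale fixed at 2 units
se_kernel <- function(coords, length_scale = 2) {
  d2 <- as.matrix(stats::dist(coords))^2
  exp(-d2 / (2 * length_scale^2))
}

roi_linear_ids <- function(spec) {
  b <- spec$roi_box
  g <- expand.grid(i = b[[1]][1]:b[[2]][1],
                   j = b[[1]][2]:b[[2]][2],
                   k = b[[1]][3]:b[[2]][3])
  sort(vox_to_id(as.matrix(g), spec$volume_shape))
}

#' Ground truth for a simulated template-tracking experiment
#'
#' Constructs the latent quantities a recovery test compares against: K true
#' templates with exactly controlled population pairwise correlation
#' (common-factor mixing via the Cholesky factor of the K x K correlation
#' matrix, rows standardized to zero mean and unit variance -- Pearson
#' correlations are unaffected by the per-row standardization), and the
#' stationary noise covariance sigma^2 ((1 - rho) I + rho S).
#'
#' The full V x V covariance matrix is materialized only for V <= 4096; for
#' larger grids the sampling factors (per-axis Cholesky factors of the
#' separable squared-exponential kernel) are stored instead and draws remain
#' exact.
#'
#' @param spec a [sim_spec()].
#' @return A list of class `ground_truth` with `true_templates` (K x V, in
#'   volume mode zero outside the ROI box), `activation_weights`,
#'   `noise_covariance` (V x V or NULL for large V), `roi_ids` (volume mode)
#'   and `seed`.
#' @export
generate_truth <- function(spec) {
  if (!inherits(spec, "sim_spec")) abort_ctt("`spec` must be a sim_spec")
  K <- spec$n_conditions
  V <- spec$n_units
  sig_units <- seq_len(V)
  roi_ids <- NULL
  if (spec$mode == "volume") {
    roi_ids <- roi_linear_ids(spec)
    sig_units <- roi_ids + 1L  # templates live on ROI voxels (ids are 0-based)
  }
  Vs <- length(sig_units)
  R <- matrix(spec$template_corr, K, K); diag(R) <- 1
  A <- chol(R)
  templates_roi <- with_seed(derive_seed(spec$seed, "templates"), {
    Z <- matrix(stats::rnorm(K * Vs), K, Vs)
    M <- t(A) %*% Z
    t(apply(M, 1L, function(r) (r - mean(r)) / stats::sd(r)))
  })
  if (K == 1L) templates_roi <- matrix(templates_roi, 1L, Vs)
  true_templates <- matrix(0, K, V)
  true_templates[, sig_units] <- templates_roi

  # sampling machinery for the smooth noise component
  rho <- spec$spatial_corr
  chol_axes <- NULL
  chol_S <- NULL
  if (rho > 0) {
    if (spec$mode == "volume") {
      chol_axes <- lapply(spec$volume_shape,
                          function(n) chol(se_kernel(matrix(seq_len(n)))))
    } else {
      if (V > 4096) {
        abort_ctt("spatial_corr > 0 requires n_units <= 4096 outside volume mode")
      }
      chol_S <- chol(se_kernel(matrix(seq_len(V))))
    }
  }
  noise_cov <- NULL
  if (V <= 4096) {
    S <- if (rho > 0) {
      if (spec$mode == "volume") {
        coords <- id_to_vox(0:(V - 1L), spec$volume_shape)
        se_kernel(coords)
      } else se_kernel(matrix(seq_len(V)))
    } else diag(V)
    noise_cov <- spec$noise_sd^2 * ((1 - rho) * diag(V) + rho * S)
  }
  structure(
    list(true_templates = true_templates,
         activation_weights = spec$activation_weights,
         noise_covariance = noise_cov,
         roi_ids = roi_ids,
         noise_sd = spec$noise_sd, spatial_corr = rho,
         chol_axes = chol_axes, chol_S = chol_S,
         mode = spec$mode, volume_shape = spec$volume_shape,
         seed = spec$seed),
    class = "ground_truth"
  )
}

# exact draw of n rows from N(0, sigma^2((1-rho)I + rho S))
draw_noise <- function(truth, n, V) {
  rho <- truth$spatial_corr
  sigma <- truth$noise_sd
  white <- matrix(stats::rnorm(n * V), n, V)
  if (rho == 0 || sigma == 0) return(sigma * white)
  smooth <- if (!is.null(truth$chol_axes)) {
    d <- truth$volume_shape
    out <- matrix(0, n, V)
    for (r in seq_len(n)) {
      z <- array(stats::rnorm(V), dim = rev(d))  # C-order ids: k fastest
      # axes of z are (k, j, i); kernel factors indexed accordingly
      z <- apply_chol_axis(z, truth$chol_axes[[3]], 1L)
      z <- apply_chol_axis(z, truth$chol_axes[[2]], 2L)
      z <- apply_chol_axis(z, truth$chol_axes[[1]], 3L)
      out[r, ] <- as.vector(z)
    }
    out
  } else {
    matrix(stats::rnorm(n * V), n, V) %*% truth$chol_S
  }
  sigma * (sqrt(1 - rho) * white + sqrt(rho) * smooth)
}

# multiply t(U) along one axis of a 3D array (U upper Cholesky, t(U) %*% U = K)
apply_chol_axis <- function(z, U, axis) {
  d <- dim(z)
  perm <- c(axis, setdiff(1:3, axis))
  zp <- aperm(z, perm)
  m <- matrix(zp, nrow = d[axis])
  m <- t(U) %*% m
  zp <- array(m, dim = d[perm])
  aperm(zp, order(perm))
}

sim_time_bins <- function(spec) {
  if (spec$mode == "epoch") 0:(spec$n_time_bins - 1L) else NULL
}

in_window <- function(bins, window) bins >= window[1] & bins < window[2]

sim_geometry <- function(spec) {
  if (spec$mode == "volume") {
    list(dim = spec$volume_shape, affine = diag(4))
  } else NULL
}

sim_unit_ids <- function(spec) {
  if (spec$mode == "volume") as.character(0:(spec$n_units - 1L))
  else paste0("u", seq_len(spec$n_units))
}

#' Simulate a localizer dataset
#'
#' Every localizer trial is its condition's true template plus a noise draw
#' from the spec's covariance; trials are balanced across runs. In epoch mode
#' the template is present only inside `active_window` (each bin gets an
#' independent noise draw); in volume mode the template occupies only ROI
#' voxels.
#'
#' @param truth a [generate_truth()] result.
#' @param spec the [sim_spec()] used to build `truth`.
#' @return A [pattern_set()] labeled with condition and run.
#' @export
simulate_localizer <- function(truth, spec) {
  sim_phase(truth, spec, phase = "localizer")
}

#' Simulate a main-task dataset
#'
#' Every main-task trial is the weighted template mixture
#' `sum_k w_k template_k` given by `spec$activation_weights` for its
#' condition, plus noise, plus an optional per-chunk baseline offset
#' (a single scalar added to every unit). In epoch mode the weights apply
#' only inside `active_window` (boxcar); in volume mode templates occupy
#' only ROI voxels. The generating weights are attached as attribute
#' `"true_weights"` (observations x K) for recovery tests.
#'
#' @inheritParams simulate_localizer
#' @return A [pattern_set()] labeled with condition and chunk (in `run`).
#' @export
simulate_main_task <- function(truth, spec) {
  sim_phase(truth, spec, phase = "main")
}

sim_phase <- function(truth, spec, phase) {
  if (!inherits(truth, "ground_truth")) abort_ctt("`truth` must be a ground_truth")
  if (!inherits(spec, "sim_spec")) abort_ctt("`spec` must be a sim_spec")
  if (!identical(dim(truth$true_templates),
                 c(spec$n_conditions, spec$n_units))) {
    abort_ctt("`truth` is inconsistent with `spec` (template dimensions differ)")
  }
  K <- spec$n_conditions
  V <- spec$n_units
  conds <- spec$conditions
  main <- phase == "main"
  n_groups <- if (main) spec$n_chunks_main else spec$n_runs_localizer
  per_cond <- if (main) spec$n_main_trials_per_condition else
    spec$n_localizer_trials_per_condition
  per_cell <- per_cond %/% n_groups
  bins <- sim_time_bins(spec)
  nb <- if (is.null(bins)) 1L else length(bins)

  if (main) {
    W <- do.call(rbind, spec$activation_weights[conds])
    if (is.null(W) || ncol(W) != K) {
      abort_ctt("activation_weights vectors must have length K")
    }
  }

  # signal pattern evoked by each condition (row k)
  signal <- if (main) W %*% truth$true_templates else truth$true_templates
  n_rows_group <- per_cell * K * nb
  # within-group row layout: condition-major, then trial, then time bin
  g_cond <- rep(seq_len(K), each = per_cell * nb)
  g_trial <- rep(seq_len(K * per_cell), each = nb)
  g_bins <- if (is.null(bins)) rep(NA_integer_, n_rows_group) else
    rep(bins, times = K * per_cell)
  g_active <- if (is.null(bins)) rep(TRUE, n_rows_group) else
    in_window(g_bins, spec$active_window)

  blocks <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    blocks[[g]] <- with_seed(derive_seed(spec$seed, phase, g), {
      shift <- if (main && spec$baseline_shift_sd > 0) {
        stats::rnorm(1L, 0, spec$baseline_shift_sd)
      } else 0
      noise <- draw_noise(truth, n_rows_group, V)
      x <- noise + shift
      for (k in seq_len(K)) {
        sel <- g_cond == k & g_active
        x[sel, ] <- sweep(x[sel, , drop = FALSE], 2L, signal[k, ], `+`)
      }
      x
    })
  }
  patterns <- do.call(rbind, blocks)
  condition <- rep(conds[g_cond], times = n_groups)
  run <- rep(seq_len(n_groups), each = n_rows_group)
  trial <- as.integer(rep(g_trial, times = n_groups) +
                        rep((seq_len(n_groups) - 1L) * K * per_cell,
                            each = n_rows_group))
  ps <- pattern_set(
    patterns, condition = condition, run = run,
    time_bin = if (!is.null(bins)) rep(g_bins, times = n_groups),
    trial = trial,
    unit_ids = sim_unit_ids(spec),
    space = if (spec$mode == "volume") "volume" else "channel",
    geometry = sim_geometry(spec)
  )
  ps <- ps_note(ps, paste0("simulate_", phase),
                list(seed = spec$seed, mode = spec$mode))
  if (main) {
    tw <- matrix(0, n_rows_group, K)
    tw[g_active, ] <- W[g_cond[g_active], , drop = FALSE]
    attr(ps, "true_weights") <- tw[rep(seq_len(n_rows_group), n_groups), ,
                                   drop = FALSE]
  }
  ps
}

#' Noise covariance of a ground-truth object
#'
#' @param truth a [generate_truth()] result.
#' @return The V x V noise covariance matrix (materialized on demand for
#'   volumes above the storage cutoff).
#' @export
noise_covariance <- function(truth) {
  if (!is.null(truth$noise_covariance)) return(truth$noise_covariance)
  V <- ncol(truth$true_templates)
  coords <- id_to_vox(0:(V - 1L), truth$volume_shape)
  S <- se_kernel(coords)
  truth$noise_sd^2 * ((1 - truth$spatial_corr) * diag(V) +
                        truth$spatial_corr * S)
}
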