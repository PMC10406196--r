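container_meta_path <- function(path) paste0(path, ".json")

#' Write a pattern or template set as a TSV container
#'
#' The container is a tab-separated table (UTF-8, header row) with the label
#' columns `.condition`, `.run`, `.trial` (and `.time_bin` for epoch data)
#' followed by one column per unit, plus a JSON sidecar (`<path>.json`)
#' holding the schema version, space, unit ids, geometry and provenance.
#' Values are written at full double precision, so a write/read roundtrip is
#' bit-exact.
#'
#' @param x a [pattern_set()] or `template_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pattern_container <- function(x, path) {
  if (inherits(x, "template_set")) {
    df <- data.frame(.condition = x$conditions, check.names = FALSE)
    m <- x$templates
    meta_type <- "template_set"
    prov <- list()
  } else {
    stopifnot_pattern_set(x)
    df <- data.frame(.condition = x$obs$condition, .run = x$obs$run,
                     .trial = x$obs$trial, check.names = FALSE)
    if (!is.null(x$obs[["time_bin"]])) df$.time_bin <- x$obs[["time_bin"]]
    m <- x$patterns
    meta_type <- "pattern_set"
    prov <- x$provenance
  }
  vals <- as.data.frame(m)
  names(vals) <- x$unit_ids
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  utils::write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(schema_version = "1.0", type = meta_type, space = x$space,
               unit_ids = x$unit_ids,
               geometry = if (!is.null(x$geometry)) {
                 list(dim = x$geometry$dim,
                      affine = as.vector(x$geometry$affine))
               },
               provenance = prov)
  jsonlite::write_json(meta, container_meta_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TSV pattern or template container
#'
#' @param path a TSV written by [write_pattern_container()] (or any TSV with
#'   a `.condition` column and numeric unit columns).
#' @return A [pattern_set()] or `template_set`, per the sidecar metadata.
#' @export
load_pattern_container <- function(path) {
  if (!file.exists(path)) abort_ctt(paste0("no such container: ", path))
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE)
  meta <- if (file.exists(container_meta_path(path))) {
    jsonlite::read_json(container_meta_path(path), simplifyVector = TRUE)
  } else list(type = "pattern_set", space = "channel")
  if (!is.null(meta$schema_version) && meta$schema_version != "1.0") {
    abort_ctt(paste0("unsupported container schema version: ",
                     meta$schema_version))
  }
  if (!".condition" %in% names(df)) {
    abort_ctt("container is missing the `.condition` column")
  }
  label_cols <- intersect(c(".condition", ".run", ".trial", ".time_bin"),
                          names(df))
  unit_cols <- setdiff(names(df), label_cols)
  if (!length(unit_cols)) abort_ctt("container holds no unit columns")
  m <- as.matrix(df[unit_cols])
  storage.mode(m) <- "double"
  geometry <- if (!is.null(meta$geometry$dim)) {
    list(dim = as.integer(meta$geometry$dim),
         affine = matrix(meta$geometry$affine, 4, 4))
  }
  if (identical(meta$type, "template_set")) {
    tm <- unname(m)
    rownames(tm) <- df$.condition
    return(structure(
      list(templates = tm, conditions = df$.condition,
           unit_ids = unit_cols, space = meta$space %||% "channel",
           geometry = geometry, exemplars = NULL, runwise_estimates = NULL),
      class = "template_set"))
  }
  if (nrow(df) != nrow(m)) abort_ctt("label/row count mismatch")
  pattern_set(m, condition = df$.condition,
              run = df$.run %||% 1L,
              time_bin = df$.time_bin,
              trial = df$.trial %||%
                (if (is.null(df$.time_bin)) NULL else
                   abort_ctt("epoch container is missing the `.trial` column")),
              unit_ids = unit_cols,
              space = meta$space %||% "channel", geometry = geometry)
}

#' Read a NIfTI volume (plus optional mask) into a pattern set
#'
#' A 4D image contributes one observation per 4th-dimension frame (a 3D
#' image contributes one). In-mask voxels become the units, identified by
#' 0-based C-order linear voxel indexes; the affine is retained so statistic
#' maps can be written back into the same grid.
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @param mask_path optional mask NIfTI with matching shape and affine
#'   (affine tolerance 1e-4).
#' @param condition,run optional per-observation labels (defaults: `"obs"`,
#'   run 1).
#' @return A volumetric [pattern_set()].
#' @export
read_volume <- function(path, mask_path = NULL, condition = NULL, run = 1L) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dims <- dim(arr)
  if (length(dims) == 3L) {
    arr <- array(arr, c(dims, 1L)); dims <- dim(arr)
  }
  if (length(dims) != 4L) abort_ctt("read_volume expects a 3D or 4D image")
  sp <- dims[1:3]
  affine <- unclass(RNifti::xform(img))
  keep <- rep(TRUE, prod(sp))
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    marr <- as.array(mimg)
    if (!identical(as.integer(dim(marr)[1:3]), as.integer(sp))) {
      abort_ctt("mask shape does not match the image")
    }
    maff <- unclass(RNifti::xform(mimg))
    if (max(abs(maff - affine)) > 1e-4) {
      abort_ctt("mask affine does not match the image (tolerance 1e-4)")
    }
    keep <- as.vector(marr != 0)
  }
  n_obs <- dims[4]
  flat <- matrix(arr, nrow = prod(sp), ncol = n_obs)
  pat <- t(flat[keep, , drop = FALSE])
  bad <- sum(!is.finite(pat))
  if (bad > 0) {
    abort_ctt(sprintf("%d non-finite voxel value(s) inside the mask", bad))
  }
  # R arrays are Fortran-order; convert kept positions to C-order ids
  lin <- which(keep)
  coords <- id_to_vox_from_lin(lin, sp)
  ids <- vox_to_id(coords, sp)
  ord <- order(ids)
  pattern_set(pat[, ord, drop = FALSE],
              condition = condition %||% rep("obs", n_obs), run = run,
              unit_ids = as.character(ids[ord]), space = "volume",
              geometry = list(dim = as.integer(sp), affine = affine))
}

#' Write a statistic map as NIfTI (volume) or TSV (time)
#'
#' @param map a `ctt_statmap`.
#' @param path output path (.nii/.nii.gz or .tsv).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  if (!inherits(map, "ctt_statmap")) abort_ctt("`map` must be a ctt_statmap")
  if (map$geometry$type == "volume") {
    arr <- map$values
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(map$geometry$affine, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    df <- data.frame(time_bin = names(map$values),
                     value = sprintf("%.17g", map$values))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load an analysis configuration
#'
#' A single YAML file describing the pipeline: simulation (or input paths),
#' extraction options, tracking options, inference options, seed and output
#' directory. Values passed in `overrides` (e.g. from CLI flags) take
#' precedence over the file.
#'
#' @param path YAML file.
#' @param overrides named list merged over the file's values.
#' @return A named list of class `ctt_config`.
#' @export
load_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = c("ctt_config", "list"))
}

#' Write analysis artifacts with a provenance manifest
#'
#' Writes each result in `results` to `out_dir` under its list name --
#' tracking tibbles and cluster tables as TSV, temporal-generalization
#' matrices as TSV matrices with bin headers, volumetric statistic maps as
#' NIfTI, time-course maps as TSV, everything else as JSON -- and a
#' `manifest.json` listing every artifact together with the configuration
#' hash and seed, so each output file is traceable to its configuration.
#'
#' @param results named list of result objects.
#' @param out_dir output directory (created if needed).
#' @param config the configuration list the results came from.
#' @param seed the seed used.
#' @return The manifest, invisibly.
#' @export
write_results <- function(results, out_dir, config = list(), seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_ctt(paste0("cannot create output directory: ", out_dir))
  }
  artifacts <- list()
  add <- function(name, file, kind) {
    artifacts[[length(artifacts) + 1L]] <<-
      list(name = name, file = basename(file), kind = kind)
  }
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "ctt_tgm")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      m <- obj$values
      df <- data.frame(localizer_bin = rownames(m),
                       apply(m, 2L, function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
      names(df) <- c("localizer_bin", colnames(m))
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(nm, f, "temporal_generalization")
    } else if (inherits(obj, "ctt_statmap")) {
      ext <- if (obj$geometry$type == "volume") ".nii.gz" else ".tsv"
      f <- file.path(out_dir, paste0(nm, ext))
      write_stat_map(obj, f)
      add(nm, f, "stat_map")
    } else if (inherits(obj, "ctt_clusters")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      tab <- obj$clusters
      tab$units <- vapply(tab$units, paste, "", collapse = ",")
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(nm, f, "cluster_table")
    } else if (inherits(obj, "data.frame")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- as.data.frame(obj)
      for (j in seq_along(df)) {
        if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
        if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
      }
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(nm, f, "table")
    } else if (inherits(obj, "pattern_set") || inherits(obj, "template_set")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_pattern_container(obj, f)
      add(nm, f, "container")
      add(paste0(nm, "_meta"), container_meta_path(f), "container_meta")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      add(nm, f, "summary")
    }
  }
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   config = config, artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Design matrix from a BIDS-style events table
#'
#' Builds boxcar regressors (one per `trial_type`, or one per trial row when
#' `trial_wise`) sampled at `n_timepoints` frames of length `tr`. No
#' hemodynamic convolution is applied; the boxcar is 1 while a frame's
#' acquisition midpoint falls within an event.
#'
#' @param events data frame with `onset`, `duration`, `trial_type` (seconds).
#' @param n_timepoints number of frames.
#' @param tr frame duration in seconds.
#' @param trial_wise one regressor per event row instead of per trial type.
#' @param intercept append a constant column.
#' @return A numeric design matrix with named columns.
#' @export
design_from_events <- function(events, n_timepoints, tr = 1,
                               trial_wise = FALSE, intercept = TRUE) {
  need <- c("onset", "duration", "trial_type")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    abort_ctt(paste0("events table is missing column(s): ",
                     paste(missing, collapse = ", ")))
  }
  mid <- (seq_len(n_timepoints) - 0.5) * tr
  cols <- if (trial_wise) seq_len(nrow(events)) else unique(events$trial_type)
  X <- vapply(cols, function(cl) {
    rows <- if (trial_wise) cl else which(events$trial_type == cl)
    on <- rep(0, n_timepoints)
    for (r in rows) {
      on <- on + as.numeric(mid >= events$onset[r] &
                              mid < events$onset[r] + events$duration[r])
    }
    pmin(on, 1)
  }, numeric(n_timepoints))
  colnames(X) <- if (trial_wise) {
    paste0("trial", cols, "_", events$trial_type)
  } else as.character(cols)
  if (intercept) X <- cbind(X, intercept = 1)
  X
}
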