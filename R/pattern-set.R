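#' Labeled activity-pattern container
#'
#' A `pattern_set` holds an observations x units matrix of activity values
#' together with per-observation labels (condition, run/chunk, optional time
#' bin and trial) and per-unit identifiers. It is the common currency of the
#' package: the simulator, the extraction steps, template estimation and
#' tracking all consume and produce `pattern_set` objects. Units can be
#' voxels (`space = "volume"`), channels (`space = "channel"`) or principal
#' components (`space = "component"`).
#'
#' @param patterns numeric matrix, observations in rows, spatial units in
#'   columns.
#' @param condition character or factor, one label per observation.
#' @param run integer-like run (localizer) or chunk (main task) id per
#'   observation; recycled if length 1.
#' @param time_bin optional integer time-bin id per observation (0-based),
#'   for epoch (time-resolved) data.
#' @param trial optional trial id per observation; defaults to the row number
#'   (or is required to group bins of the same trial in epoch data).
#' @param unit_ids unique identifiers for the columns; defaults to
#'   `"u1" ... "uV"`. Volume data uses 0-based C-order linear voxel indexes.
#' @param space one of `"channel"`, `"volume"`, `"component"`.
#' @param geometry for volume data, a list with `dim` (3 integers) and
#'   `affine` (4 x 4 matrix); `NULL` otherwise.
#'
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(patterns, condition, run = 1L, time_bin = NULL,
                        trial = NULL, unit_ids = NULL,
                        space = c("channel", "volume", "component"),
                        geometry = NULL) {
  space <- match.arg(space)
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "double"
  n <- nrow(patterns)
  if (length(run) == 1L) run <- rep(run, n)
  condition <- as.character(condition)
  if (length(condition) != n || length(run) != n) {
    abort_ctt("condition/run label lengths must equal the observation count")
  }
  if (!is.null(time_bin) && length(time_bin) != n) {
    abort_ctt("time_bin labels must equal the observation count")
  }
  if (is.null(trial)) {
    trial <- if (is.null(time_bin)) seq_len(n) else
      abort_ctt("epoch data (time_bin given) requires explicit trial ids")
  }
  if (any(!is.finite(patterns))) {
    abort_ctt("patterns contain NaN/Inf values")
  }
  unit_ids <- unit_ids %||% paste0("u", seq_len(ncol(patterns)))
  if (anyDuplicated(unit_ids)) abort_ctt("unit_ids must be unique")
  if (length(unit_ids) != ncol(patterns)) {
    abort_ctt("unit_ids length must equal the unit count")
  }
  obs <- tibble::tibble(
    condition = condition,
    run = as.integer(run),
    trial = as.integer(trial)
  )
  if (!is.null(time_bin)) obs$time_bin <- as.integer(time_bin)
  structure(
    list(patterns = unname(patterns), obs = obs,
         unit_ids = as.character(unit_ids), space = space,
         geometry = geometry, provenance = list()),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d observations x %d units (%s)\n",
              n_obs(x), n_units(x), x$space))
  cat("  conditions:", paste(unique(x$obs$condition), collapse = ", "), "\n")
  cat("  runs/chunks:", paste(sort(unique(x$obs$run)), collapse = ", "), "\n")
  if (!is.null(x$obs[["time_bin"]])) {
    cat("  time bins:", min(x$obs[["time_bin"]]), "..", max(x$obs[["time_bin"]]), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(vapply(x$provenance, `[[`, "", "op"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @rdname pattern_set
#' @param x a `pattern_set`.
#' @export
n_obs <- function(x) nrow(x$patterns)

#' @rdname pattern_set
#' @export
n_units <- function(x) ncol(x$patterns)

#' @export
as.matrix.pattern_set <- function(x, ...) {
  m <- x$patterns
  colnames(m) <- x$unit_ids
  m
}

#' Long-format view of a pattern set
#'
#' @param x a `pattern_set`.
#' @param ... unused.
#' @return A tibble with one row per observation x unit.
#' @method tidy pattern_set
#' @export
tidy.pattern_set <- function(x, ...) {
  wide <- tibble::as_tibble(x$obs)
  wide$.obs <- seq_len(n_obs(x))
  m <- x$patterns
  colnames(m) <- x$unit_ids
  dplyr::bind_cols(wide, tibble::as_tibble(m)) |>
    tidyr::pivot_longer(dplyr::all_of(x$unit_ids),
                        names_to = "unit", values_to = "value")
}

ps_note <- function(ps, op, params = list()) {
  ps$provenance <- c(ps$provenance, list(list(op = op, params = params)))
  ps
}

ps_subset_obs <- function(ps, idx) {
  ps$patterns <- ps$patterns[idx, , drop = FALSE]
  ps$obs <- ps$obs[idx, , drop = FALSE]
  ps
}

ps_subset_units <- function(ps, idx) {
  ps$patterns <- ps$patterns[, idx, drop = FALSE]
  ps$unit_ids <- ps$unit_ids[idx]
  ps
}

stopifnot_pattern_set <- function(x, arg = "x") {
  if (!inherits(x, "pattern_set")) {
    abort_ctt(sprintf("`%s` must be a pattern_set", arg))
  }
  invisible(x)
}
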