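default_config <- function() {
  list(
    seed = 1L, out_dir = "ctt_out",
    simulate = list(n_subjects = 8L, n_units = 80L, n_conditions = 2L,
                    n_localizer_trials_per_condition = 16L,
                    n_main_trials_per_condition = 16L,
                    n_runs_localizer = 4L, n_chunks_main = 4L,
                    noise_sd = 0.8),
    extract = list(supertrial_k = NULL, normalize = "none",
                   smooth_window = NULL, pca_fraction = NULL),
    track = list(metric = "pearson", target = "cond1", baseline = "cond2"),
    infer = list(n_perm = 1000L, alternative = "greater"),
    diagnostics = TRUE
  )
}

merge_config <- function(cfg) {
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(cfg[[nm]])) base[[nm]][[k]] <- cfg[[nm]][[k]]
    } else base[[nm]] <- cfg[[nm]]
  }
  base
}

pipeline_extract <- function(ps, ext, noise) {
  if (!is.null(ext$supertrial_k) && ext$supertrial_k > 1L) {
    ps <- make_supertrials(ps, ext$supertrial_k, seed = 1L)
  }
  if (!identical(ext$normalize, "none") && !is.null(ext$normalize)) {
    ps <- noise_normalize(ps, noise, mode = ext$normalize)
  }
  if (!is.null(ext$smooth_window) && !is.null(ps$obs[["time_bin"]])) {
    ps <- smooth_temporal(ps, ext$smooth_window)
  }
  ps
}

# within-cell residuals of a localizer pattern set, for noise modeling
localizer_residuals <- function(loc) {
  res <- loc$patterns
  key <- paste(loc$obs$condition, loc$obs$run, sep = "\r")
  for (cell in unique(key)) {
    sel <- key == cell
    res[sel, ] <- sweep(res[sel, , drop = FALSE], 2L,
                        colMeans(res[sel, , drop = FALSE]))
  }
  res
}

#' Run the full template-tracking pipeline from a configuration
#'
#' Simulates (or will later load) one dataset per subject, applies the
#' configured extraction steps, estimates canonical templates from the
#' localizer, tracks them on the main task, forms the relative activation
#' index (target vs baseline over target-condition observations), and
#' performs group inference (exact Wilcoxon signed-rank plus sign-flip
#' permutation). All randomness derives from the configuration seed, so two
#' runs of the same configuration produce byte-identical outputs.
#'
#' @param config a `ctt_config` (from [load_config()]), a path to a YAML
#'   configuration, or a plain list; missing entries take package defaults.
#' @param seed optional seed overriding the configuration.
#' @param out_dir optional output directory overriding the configuration;
#'   `NULL` with no configured directory skips writing.
#' @return A list with `subject_indexes` (tibble), `group_tests` (tibble),
#'   `permutation` (`ctt_permutation`), `diagnostics` (tibble or NULL) and
#'   `manifest` (when written).
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  simc <- cfg$simulate
  n_subjects <- simc$n_subjects %||% 8L
  simc$n_subjects <- NULL
  subj_rows <- list()
  diag_rows <- list()
  for (s in seq_len(n_subjects)) {
    spec <- do.call(sim_spec, c(simc, list(seed = derive_seed(cfg$seed,
                                                              "subject", s))))
    truth <- generate_truth(spec)
    loc <- simulate_localizer(truth, spec)
    main <- simulate_main_task(truth, spec)
    noise <- if (!identical(cfg$extract$normalize, "none")) {
      noise_model(localizer_residuals(loc))
    }
    loc <- pipeline_extract(loc, cfg$extract, noise)
    main <- pipeline_extract(main, cfg$extract, noise)
    if (!is.null(cfg$extract$pca_fraction)) {
      red <- reduce_dimensions(loc, list(main), cfg$extract$pca_fraction)
      loc <- red$train; main <- red$applied[[1]]
    }
    ts <- estimate_templates(loc, keep_runwise = spec$n_runs_localizer >= 2L)
    tr <- similarity_index(main, ts, metric = cfg$track$metric)
    rel <- relative_activation(tr, cfg$track$target, cfg$track$baseline)
    vals <- rel$value[rel$condition == cfg$track$target]
    subj_rows[[s]] <- tibble::tibble(
      subject = s, relative_index = mean(vals), n_obs = length(vals))
    if (isTRUE(cfg$diagnostics)) {
      corr <- compute_correlationability(ts)
      ent <- vapply(seq_along(ts$conditions),
                    function(k) compute_entropy(ts$templates[k, ],
                                                n_bins = min(16L, n_units(loc))),
                    numeric(1))
      snr <- vapply(ts$conditions, function(k) {
        compute_snr(tr$value[tr$template == k])
      }, numeric(1))
      diag_rows[[s]] <- dplyr::mutate(corr, subject = s, entropy_bits = ent,
                                      snr = snr)
    }
  }
  subject_indexes <- dplyr::bind_rows(subj_rows)
  wil <- wilcoxon_signed_rank(subject_indexes$relative_index,
                              alternative = cfg$infer$alternative %||% "greater")
  perm <- permutation_test(subject_indexes$relative_index,
                           scheme = "group_sign_flip",
                           n_perm = cfg$infer$n_perm %||% 1000L,
                           seed = derive_seed(cfg$seed, "perm"),
                           alternative = cfg$infer$alternative %||% "greater")
  group_tests <- dplyr::bind_rows(
    dplyr::mutate(wil, test = "wilcoxon_signed_rank", .before = 1L),
    tibble::tibble(test = "sign_flip_permutation",
                   statistic = unname(perm$observed),
                   p_value = unname(perm$p_values),
                   n = n_subjects, n_zero = NA_integer_,
                   method = if (perm$exact) "full enumeration" else
                     sprintf("%d sampled flips", perm$n_perm),
                   alternative = perm$alternative))
  diagnostics <- if (length(diag_rows)) dplyr::bind_rows(diag_rows)
  out <- list(subject_indexes = subject_indexes, group_tests = group_tests,
              permutation = perm, diagnostics = diagnostics, config = cfg)
  if (!is.null(cfg$out_dir)) {
    results <- list(subject_indexes = subject_indexes,
                    group_tests = group_tests)
    if (!is.null(diagnostics)) results$diagnostics <- diagnostics
    out$manifest <- write_results(results, cfg$out_dir, config = cfg,
                                  seed = cfg$seed)
  }
  out
}
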