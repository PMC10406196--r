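# small in-code fixtures shared across test files

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_units = 60L, n_conditions = 2L,
                   n_localizer_trials_per_condition = 8L,
                   n_main_trials_per_condition = 8L,
                   n_runs_localizer = 2L, n_chunks_main = 2L,
                   noise_sd = 0.5, seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_spec, defaults)
}

tiny_datasets <- function(spec = tiny_spec()) {
  truth <- generate_truth(spec)
  list(spec = spec, truth = truth,
       loc = simulate_localizer(truth, spec),
       main = simulate_main_task(truth, spec))
}

toy_pattern_set <- function(m, condition = NULL, ...) {
  m <- as.matrix(m)
  pattern_set(m, condition = condition %||% rep("a", nrow(m)), ...)
}

# independent brute-force Wilcoxon oracle: enumerate all 2^n sign patterns
brute_wilcoxon_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_v <- apply(signs, 1L, function(s) sum(r[s > 0]))
  switch(alternative,
         greater = mean(null_v >= v_obs),
         less = mean(null_v <= v_obs),
         two.sided = min(1, 2 * min(mean(null_v >= v_obs),
                                    mean(null_v <= v_obs))))
}
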