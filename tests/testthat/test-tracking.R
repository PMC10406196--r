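make_ts <- function(templates, conditions = NULL) {
  conditions <- conditions %||% paste0("cond", seq_len(nrow(templates)))
  estimate_templates(pattern_set(templates, condition = conditions))
}

test_that("similarity indexes reproduce closed-form cases", {
  tmpl <- rbind(c(1, 0, 1, 0), c(0, 0, 3, 4))
  ts <- make_ts(tmpl, c("A", "B"))
  main <- pattern_set(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(3, 4, 0, 0)),
                      condition = c("x", "y", "z"))
  r <- similarity_index(main, ts, "pearson")
  expect_equal(r$value[r$obs == 1 & r$template == "A"], 1)
  expect_equal(r$value[r$obs == 2 & r$template == "A"], -1)
  eu <- similarity_index(main, ts, "euclidean")
  expect_equal(eu$value[eu$obs == 1 & eu$template == "A"], 0)
  # template (0,0,3,4) vs pattern (3,4,0,0): sqrt(9+16+9+16) -- and the
  # classic 3-4-5 against the zero pattern
  z <- pattern_set(rbind(c(0, 0, 3, 4)), condition = "w")
  ts0 <- make_ts(rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)), c("zero", "one"))
  eu0 <- similarity_index(z, ts0, "euclidean")
  expect_equal(eu0$value[eu0$template == "zero"], 5)
  # sq_euclidean = euclidean^2 for every observation
  sq <- similarity_index(main, ts, "sq_euclidean")
  expect_equal(sq$value, eu$value^2)
  # fisher_z = atanh(pearson)
  fz <- similarity_index(main, ts, "fisher_z")
  expect_equal(fz$value, atanh(r$value))
  expect_identical(attr(r, "polarity"), "higher_is_more_active")
  expect_identical(attr(eu, "polarity"), "lower_is_more_active")
})

test_that("correlation indexes are scale-invariant while distances are not", {
  d <- tiny_datasets()
  ts <- estimate_templates(d$loc)
  scaled <- d$main
  scaled$patterns <- 3.7 * scaled$patterns + 1.2
  r1 <- similarity_index(d$main, ts, "pearson")
  r2 <- similarity_index(scaled, ts, "pearson")
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  e1 <- similarity_index(d$main, ts, "euclidean")
  e2 <- similarity_index(scaled, ts, "euclidean")
  expect_gt(mean(abs(e2$value - e1$value)), 0.1)
  # zero-variance vectors are refused for correlation metrics
  flat <- pattern_set(matrix(2, 1, n_units(d$main)), condition = "f",
                      unit_ids = d$main$unit_ids)
  expect_error(similarity_index(flat, ts, "pearson"), "zero-variance")
  # mismatched support is refused
  sub <- cttrack:::ps_subset_units(d$main, 1:10)
  expect_error(similarity_index(sub, ts, "pearson"), "support")
})

test_that("cross-validated estimators are exact in degenerate cases and unbiased under noise", {
  # sigma = 0 and main patterns equal to the template -> exactly 0
  d0 <- tiny_datasets(tiny_spec(noise_sd = 0))
  ts0 <- estimate_templates(d0$loc)
  cv0 <- crossvalidated_index(ts0, d0$main, "cv_sq_euclidean")
  expect_equal(cv0$value[cv0$condition == cv0$template], c(0, 0),
               tolerance = 1e-20)
  # identity noise covariance -> mahalanobis_cv equals cv_sq_euclidean
  d <- tiny_datasets()
  ts <- estimate_templates(d$loc)
  nm_id <- structure(list(covariance = diag(n_units(d$main)), shrinkage = 0,
                          whitener = diag(n_units(d$main))),
                     class = "noise_model")
  cv <- crossvalidated_index(ts, d$main, "cv_sq_euclidean")
  mh <- crossvalidated_index(ts, d$main, "mahalanobis_cv", noise = nm_id)
  expect_equal(cv$value, mh$value, tolerance = 1e-10)
  expect_true(isTRUE(attr(cv, "may_be_negative")))
  # single chunk is refused with guidance
  one_chunk <- cttrack:::ps_subset_obs(d$main, which(d$main$obs$run == 1L))
  expect_error(crossvalidated_index(ts, one_chunk, "cv_sq_euclidean"),
               "chunks")
  expect_error(crossvalidated_index(ts, d$main, "mahalanobis_cv"),
               "noise_model")
})

test_that("the naive distance is biased by the noise norm while the cv estimator is centered", {
  sp <- sim_spec(n_units = 100L, n_conditions = 1L, noise_sd = 0.5,
                 n_main_trials_per_condition = 10L, n_chunks_main = 10L,
                 n_localizer_trials_per_condition = 10L,
                 n_runs_localizer = 1L, seed = 21L)
  ba <- bias_audit(sp, n_reps = 300L)
  naive <- ba[ba$estimator == "naive_pattern_sqdist", ]
  cv <- ba[ba$estimator == "cv_sqdist", ]
  analytic <- attr(ba, "analytic_naive")  # 2 * V * sigma^2 = 50
  expect_equal(analytic, 50)
  expect_lt(abs(naive$mean - analytic) / analytic, 0.1)
  expect_lt(abs(cv$mean), 2 * cv$se + 1e-12)
  expect_gt(naive$mean, 10 * abs(cv$mean))
})

test_that("regression partitioning matches least-squares and residualization oracles", {
  set.seed(30)
  V <- 50
  t1 <- rnorm(V); t1 <- t1 - mean(t1)
  t2 <- rnorm(V); t2 <- t2 - mean(t2) - t1 * sum(t1 * t2) / sum(t1^2)
  # orthogonal templates, noiseless y = 2 t1 + 3 t2
  ts <- make_ts(rbind(t1, t2), c("T1", "T2"))
  y <- pattern_set(rbind(2 * t1 + 3 * t2), condition = "m")
  rp <- regression_partition(y, ts)
  expect_equal(rp$beta[rp$template == "T1"], 2, tolerance = 1e-10)
  expect_equal(rp$beta[rp$template == "T2"], 3, tolerance = 1e-10)
  expect_equal(rp$r_squared[1], 1, tolerance = 1e-10)
  # K = 1: beta = 1 and sr = r = 1 for y = t1
  ts1 <- make_ts(rbind(t1), "T1")
  rp1 <- regression_partition(pattern_set(rbind(t1), condition = "m"), ts1)
  expect_equal(rp1$beta, 1, tolerance = 1e-10)
  expect_equal(rp1$semipartial, 1, tolerance = 1e-10)
  # correlated templates: sr from the R^2 difference equals the
  # residualization oracle (correlate y with t_k residualized on others)
  t3 <- 0.6 * t1 + rnorm(V)
  ts2 <- make_ts(rbind(t1, t3), c("T1", "T3"))
  yy <- 1.5 * t1 - 0.8 * t3 + rnorm(V, sd = 0.3)
  rp2 <- regression_partition(pattern_set(rbind(yy), condition = "m"), ts2)
  yc <- yy - mean(yy)
  for (pair in list(list("T1", 1L), list("T3", 2L))) {
    tk <- ts2$templates[pair[[2]], ]
    to <- ts2$templates[-pair[[2]], ]
    tk <- tk - mean(tk); to <- to - mean(to)
    resid_k <- tk - to * sum(to * tk) / sum(to^2)
    sr_oracle <- sum(yc * resid_k) / sqrt(sum(yc^2) * sum(resid_k^2))
    expect_equal(rp2$semipartial[rp2$template == pair[[1]]], sr_oracle,
                 tolerance = 1e-10)
  }
  # collinear templates are refused with the condition number
  ts_col <- make_ts(rbind(t1, 2 * t1 + 1e-12 * t2), c("a", "b"))
  expect_error(regression_partition(y, ts_col), "condition number")
})

test_that("mean regression betas recover generating weights within 10%", {
  sp <- tiny_spec(n_units = 300L, noise_sd = 0.2,
                  activation_weights = list(cond1 = c(2, 3),
                                            cond2 = c(2, 3)),
                  n_main_trials_per_condition = 20L, seed = 31L)
  d <- tiny_datasets(sp)
  ts <- estimate_templates(d$loc)
  rp <- regression_partition(d$main, ts)
  b1 <- mean(rp$beta[rp$template == "cond1"])
  b2 <- mean(rp$beta[rp$template == "cond2"])
  expect_lt(abs(b1 - 2) / 2, 0.1)
  expect_lt(abs(b2 - 3) / 3, 0.1)
})

test_that("classifier tracking has the closed-form geometry and high accuracy when separable", {
  # 2D worked case: identity-proportional pooled covariance,
  # mu1 = (1, 0), mu2 = (-1, 0) -> discriminant direction (2, 0)
  dd <- 0.5
  ex <- pattern_set(rbind(c(1 + dd, 0), c(1 - dd, 0), c(-1, dd), c(-1, -dd)),
                    condition = c("A", "A", "B", "B"))
  ts <- estimate_templates(ex, keep_exemplars = TRUE)
  mm <- pattern_set(rbind(c(0.5, 7), c(0, 3)), condition = c("A", "B"))
  ct <- classifier_tracking(ts, mm, shrinkage = 0)
  expect_identical(ct$predicted[ct$obs == 1][1], "A")
  expect_equal(ct$value[ct$obs == 1 & ct$template == "A"], 0.5)
  # a pattern exactly midway between the class means has d = 0
  expect_equal(ct$value[ct$obs == 2 & ct$template == "A"], 0)
  # far-separated Gaussian classes -> accuracy 1 at n = 100
  set.seed(40)
  V <- 20
  mu <- matrix(0, 2, V); mu[1, 1] <- 10; mu[2, 1] <- -10
  exb <- pattern_set(rbind(matrix(rnorm(50 * V), 50, V) +
                             rep(mu[1, ], each = 50),
                           matrix(rnorm(50 * V), 50, V) +
                             rep(mu[2, ], each = 50)),
                     condition = rep(c("A", "B"), each = 50))
  tsb <- estimate_templates(exb, keep_exemplars = TRUE)
  test <- pattern_set(rbind(matrix(rnorm(50 * V), 50, V) +
                              rep(mu[1, ], each = 50),
                            matrix(rnorm(50 * V), 50, V) +
                              rep(mu[2, ], each = 50)),
                      condition = rep(c("A", "B"), each = 50))
  ctb <- classifier_tracking(tsb, test)
  expect_equal(attr(ctb, "accuracy"), 1)
  # reference LDA implementation agrees on the predicted labels
  ref <- MASS::lda(exb$patterns, grouping = exb$obs$condition)
  ref_pred <- as.character(predict(ref, test$patterns)$class)
  expect_identical(ctb$predicted[!duplicated(ctb$obs)], ref_pred)
  # exemplar requirements
  ex1 <- cttrack:::ps_subset_obs(exb, c(1L, 51:100))
  expect_error(classifier_tracking(estimate_templates(ex1,
                                                      keep_exemplars = TRUE),
                                   test), "2 exemplars")
  expect_error(classifier_tracking(estimate_templates(exb), test),
               "exemplars")
})

test_that("classifier decisions agree with correlation assignments on separable data", {
  d <- tiny_datasets(tiny_spec(n_units = 150L, noise_sd = 0.4,
                               n_localizer_trials_per_condition = 16L,
                               seed = 44L))
  ts <- estimate_templates(d$loc, keep_exemplars = TRUE)
  ct <- classifier_tracking(ts, d$main)
  r <- similarity_index(d$main, ts, "pearson")
  wide_r <- tidyr::pivot_wider(tibble::as_tibble(r)[c("obs", "template",
                                                      "value")],
                               names_from = "template",
                               values_from = "value")
  argmax <- ts$conditions[max.col(as.matrix(wide_r[ts$conditions]))]
  wide_d <- tidyr::pivot_wider(tibble::as_tibble(ct)[c("obs", "template",
                                                       "value")],
                               names_from = "template",
                               values_from = "value")
  agree <- vapply(seq_along(argmax), function(i) {
    wide_d[[argmax[i]]][i] > 0
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("relative activation is oriented so positive means target more active", {
  # equal indexes -> relative index 0 (proportional templates correlate
  # identically with any pattern)
  eq <- similarity_index(
    pattern_set(rbind(c(1, 2, 0, 1, 3)), condition = "m"),
    make_ts(rbind(c(2, 2, 0, 0, 2), c(0.4, 0.4, 0, 0, 0.4)),
            c("tgt", "base")), "pearson")
  rel_eq <- relative_activation(eq, "tgt", "base")
  expect_equal(rel_eq$value, 0, tolerance = 1e-12)
  # r_target = 0.5, r_base = 0 -> relative index atanh(0.5): build centered
  # orthonormal directions so the sample correlations are exact
  set.seed(50)
  V <- 200
  gs <- qr.Q(qr(cbind(1, matrix(rnorm(V * 3), V, 3))))[, 2:4]
  e1 <- gs[, 1]; e2 <- gs[, 2]; e3 <- gs[, 3]  # centered, orthonormal
  yv <- 0.5 * e1 + sqrt(0.75) * e3
  tsx <- make_ts(rbind(e1, e2), c("tgt", "base"))
  rx <- similarity_index(pattern_set(rbind(yv), condition = "m"), tsx,
                         "pearson")
  expect_equal(rx$value[rx$template == "tgt"], 0.5, tolerance = 1e-12)
  expect_equal(rx$value[rx$template == "base"], 0, tolerance = 1e-12)
  relx <- relative_activation(rx, "tgt", "base")
  expect_equal(relx$value, atanh(0.5), tolerance = 1e-12)
  # distance polarity flips: d_target = 1, d_base = 3 -> +2
  fake <- cttrack:::tracking_result(
    tibble::tibble(obs = c(1L, 1L), condition = "m", chunk = 1L,
                   template = c("tgt", "base"), value = c(1, 3)),
    "euclidean", "lower_is_more_active")
  rel_d <- relative_activation(fake, "tgt", "base")
  expect_equal(rel_d$value, 2)
  expect_error(relative_activation(fake, "tgt", "tgt"), "differ")
})

test_that("relative indexes recover the activated template for every metric family", {
  sp <- tiny_spec(n_units = 200L, noise_sd = 0.5,
                  activation_weights = list(cond1 = c(1, 0),
                                            cond2 = c(1, 0)),
                  n_main_trials_per_condition = 16L, n_chunks_main = 4L,
                  seed = 60L)
  d <- tiny_datasets(sp)
  ts <- estimate_templates(d$loc, keep_exemplars = TRUE)
  for (metric in c("pearson", "euclidean")) {
    tr <- similarity_index(d$main, ts, metric)
    rel <- relative_activation(tr, "cond1", "cond2")
    expect_gt(mean(rel$value), 0)
  }
  cv <- crossvalidated_index(ts, d$main, "cv_sq_euclidean")
  rel_cv <- relative_activation(cv, "cond1", "cond2")
  expect_gt(mean(rel_cv$value), 0)
  rp <- regression_partition(d$main, ts)
  rel_rp <- relative_activation(rp, "cond1", "cond2")
  expect_gt(mean(rel_rp$value), 0)
  ct <- classifier_tracking(ts, d$main)
  rel_ct <- relative_activation(ct, "cond1", "cond2")
  expect_gt(mean(rel_ct$value), 0)
})
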