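test_that("least-squares extraction matches the normal-equations oracle", {
  set.seed(11)
  X <- cbind(1, matrix(rnorm(12), 6, 2))
  Y <- matrix(rnorm(6 * 4), 6, 4)
  fit <- fit_run_glm(Y, X)
  B_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(fit$betas), unname(B_oracle), tolerance = 1e-10)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(X) %*% fit$residuals)) / max(abs(Y)), 1e-8)
  expect_equal(fit$dof, 3)
  # t values equal beta / SE from (X'X)^-1 and residual variance
  s2 <- colSums(fit$residuals^2) / fit$dof
  se <- sqrt(outer(diag(solve(crossprod(X))), s2))
  expect_equal(unname(fit$t_values), unname(B_oracle / se), tolerance = 1e-10)
})

test_that("degenerate designs and exact cases behave as closed forms say", {
  set.seed(2)
  Y <- matrix(rnorm(20), 10, 2)
  # intercept only -> betas are column means
  fit <- fit_run_glm(Y, matrix(1, 10, 1))
  expect_equal(unname(fit$betas[1, ]), unname(colMeans(Y)))
  # noiseless Y = X B0 -> exact recovery
  X <- cbind(1, rnorm(10))
  B0 <- matrix(c(2, -1, 0.5, 3), 2, 2)
  fit2 <- fit_run_glm(X %*% B0, X)
  expect_equal(unname(fit2$betas), unname(B0), tolerance = 1e-10)
  expect_lt(max(abs(fit2$residuals)), 1e-10)
  # rank-deficient design errors naming the dependent column
  Xr <- cbind(a = rep(1, 10), b = rnorm(10))
  Xr <- cbind(Xr, c = Xr[, "b"] * 2)
  expect_error(fit_run_glm(Y, Xr), "c")
  expect_error(fit_run_glm(Y[1:2, ], X[1:2, ]), "timepoints")
})

test_that("supertrial averaging partitions cells and scales noise variance", {
  d <- tiny_datasets(tiny_spec(n_localizer_trials_per_condition = 8L))
  # k = 1 is the identity
  expect_identical(make_supertrials(d$loc, 1L)$patterns, d$loc$patterns)
  # k = cell size -> one pattern per cell equal to the cell mean
  st <- make_supertrials(d$loc, 4L, seed = 3L)
  expect_equal(n_obs(st), 4L)  # 2 conditions x 2 runs
  for (i in seq_len(n_obs(st))) {
    sel <- d$loc$obs$condition == st$obs$condition[i] &
      d$loc$obs$run == st$obs$run[i]
    expect_equal(unname(st$patterns[i, ]),
                 unname(colMeans(d$loc$patterns[sel, ])))
  }
  # permuting trial order never changes the k = cell-size means
  perm <- sample(n_obs(d$loc))
  dp <- cttrack:::ps_subset_obs(d$loc, perm)
  stp <- make_supertrials(dp, 4L, seed = 99L)
  o1 <- st$patterns[order(st$obs$condition, st$obs$run), ]
  o2 <- stp$patterns[order(stp$obs$condition, stp$obs$run), ]
  expect_equal(o1, o2)
  # deterministic under seed
  expect_identical(make_supertrials(d$loc, 2L, seed = 5L)$patterns,
                   make_supertrials(d$loc, 2L, seed = 5L)$patterns)
  # variance of k = 4 supertrials of unit-variance noise is ~ sigma^2 / 4
  sp <- tiny_spec(n_units = 50L, n_conditions = 1L, noise_sd = 1,
                  n_localizer_trials_per_condition = 4000L,
                  n_runs_localizer = 1L,
                  activation_weights = list(cond1 = 1), seed = 9L)
  big <- tiny_datasets(sp)
  st4 <- make_supertrials(big$loc, 4L)
  v <- mean(apply(st4$patterns, 2L, var))
  expect_lt(abs(v - 0.25) / 0.25, 0.1)
  # cells smaller than k are refused with the cells listed
  expect_error(make_supertrials(d$loc, 5L), "fewer than 5")
})

test_that("noise normalization has its exact special cases", {
  set.seed(4)
  V <- 12
  ps <- toy_pattern_set(matrix(rnorm(5 * V), 5, V))
  # residual SD 1 at every unit -> univariate normalization is the identity
  # (residuals are uncentered in the noise model, so scale by the raw
  # second moment)
  res_unit <- matrix(rnorm(400 * V), 400, V)
  res_unit <- scale(res_unit, center = FALSE,
                    scale = sqrt(colSums(res_unit^2) / 399))
  nm_unit <- noise_model(res_unit, shrinkage = 1)
  expect_equal(noise_normalize(ps, nm_unit, "univariate")$patterns,
               ps$patterns, tolerance = 1e-12)
  # full shrinkage to the diagonal: multivariate == univariate exactly
  res <- matrix(rnorm(200 * V), 200, V) %*% diag(seq(0.5, 3, length.out = V))
  nm1 <- noise_model(res, shrinkage = 1)
  expect_equal(noise_normalize(ps, nm1, "multivariate")$patterns,
               noise_normalize(ps, nm1, "univariate")$patterns,
               tolerance = 1e-10)
  # input is never mutated
  before <- ps$patterns
  invisible(noise_normalize(ps, nm1, "multivariate"))
  expect_identical(ps$patterns, before)
})

test_that("the whitener decorrelates spatially correlated residuals", {
  set.seed(10)
  V <- 40
  S <- 0.25 * ((1 - 0.3) * diag(V) +
                 0.3 * exp(-as.matrix(dist(1:V))^2 / 8))
  X <- matrix(rnorm(5000 * V), 5000, V) %*% chol(S)
  nm <- noise_model(X)
  emp <- crossprod(X %*% nm$whitener) / (5000 - 1)
  expect_lt(norm(emp - diag(V), "F"), 0.1 * V)
  # whitener inverts the shrunk covariance on both sides
  expect_equal(nm$whitener %*% nm$covariance %*% t(nm$whitener), diag(V),
               tolerance = 1e-8)
})

test_that("temporal smoothing follows truncated moving-average arithmetic", {
  eps <- pattern_set(matrix(c(0, 4, 0, 4), 4, 3),
                     condition = rep("a", 4), time_bin = 0:3,
                     trial = rep(1L, 4))
  sm <- smooth_temporal(eps, 3L)
  expect_equal(unname(sm$patterns[, 1]), c(2, 4 / 3, 8 / 3, 2))
  # w = 1 is the identity; constant trials are fixed points
  expect_identical(smooth_temporal(eps, 1L)$patterns, eps$patterns)
  const <- pattern_set(matrix(5, 4, 2), condition = rep("a", 4),
                       time_bin = 0:3, trial = rep(1L, 4))
  expect_equal(smooth_temporal(const, 3L)$patterns, const$patterns)
  expect_error(smooth_temporal(eps, 5L), "exceeds")
  expect_error(smooth_temporal(eps, 2L), "odd")
})

test_that("component reduction retains the minimal count per the eigen oracle", {
  set.seed(12)
  lam <- c(8, 4, 2, 1, 0.5, rep(0.05, 15))
  X <- matrix(rnorm(300 * 20), 300, 20) %*% diag(sqrt(lam))
  train <- toy_pattern_set(X)
  red <- reduce_dimensions(train, list(train), variance_fraction = 0.99)
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  d_oracle <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  expect_equal(red$projection$n_components, d_oracle)
  expect_identical(red$applied[[1]]$space, "component")
  # rank-1 data -> exactly one component for any f
  r1 <- toy_pattern_set(outer(rnorm(30), rnorm(6)))
  expect_equal(reduce_dimensions(r1, variance_fraction = 0.5)$
                 projection$n_components, 1L)
  # f = 1 keeps all nonzero-variance components; projection preserves
  # pairwise distances on the data's span
  full <- reduce_dimensions(train, list(train), variance_fraction = 1)
  expect_equal(as.vector(dist(full$applied[[1]]$patterns)),
               as.vector(dist(X)), tolerance = 1e-8)
  expect_error(reduce_dimensions(train, variance_fraction = 0), "fraction")
})
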