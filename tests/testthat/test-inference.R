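test_that("exact signed-rank p-values match full sign enumeration", {
  # the classic all-positive case: p = 1/2^5
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(res$p_value, 1 / 32)
  expect_equal(res$statistic, 15)
  expect_identical(res$method, "exact sign enumeration")
  # random inputs (with ties) for every n in 5..12 against the brute-force
  # 2^n oracle
  set.seed(13)
  for (n in 5:12) {
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(wilcoxon_signed_rank(d, alternative = alt)$p_value,
                   brute_wilcoxon_p(d, alt), tolerance = 1e-12,
                   info = sprintf("n=%d alt=%s", n, alt))
    }
  }
  # untied case agrees with the closed-form signed-rank distribution
  d <- c(0.3, -1.2, 2.4, 3.1, -0.7, 1.9, -2.2, 0.9)
  r <- rank(abs(d)); V <- sum(r[d > 0])
  expect_equal(wilcoxon_signed_rank(d, alternative = "greater")$p_value,
               psignrank(V - 1, 8, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("signed-rank conventions: zeros dropped, symmetry, pairing, approximation", {
  # symmetric construction (x and -x) puts the statistic at the null center
  res <- wilcoxon_signed_rank(c(-5:-1, 1:5))
  expect_equal(res$statistic, 10 * 11 / 4)
  # zero differences are dropped and counted
  res0 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(res0$n_zero, 2L)
  expect_equal(res0$n, 5L)
  # paired form tests the differences
  x <- c(3, 5, 4, 6, 7, 8)
  y <- c(1, 2, 2, 3, 3, 4)
  expect_equal(wilcoxon_signed_rank(x, paired_with = y)$p_value,
               wilcoxon_signed_rank(x - y)$p_value)
  expect_error(wilcoxon_signed_rank(x, paired_with = y[1:3]), "equal length")
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 0, 0, 0, 0)), "at least 5")
  # n > 25 normal approximation agrees with the reference implementation
  set.seed(14)
  d26 <- rnorm(26) + 0.3
  got <- wilcoxon_signed_rank(d26, alternative = "greater")
  expect_identical(got$method,
                   "normal approximation with continuity correction")
  ref <- wilcox.test(d26, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("permutation schemes are deterministic, bounded and enumerable", {
  set.seed(15)
  x <- rnorm(20, mean = 0.5)
  p1 <- permutation_test(x, n_perm = 500, seed = 9)
  p2 <- permutation_test(x, n_perm = 500, seed = 9)
  expect_identical(p1$p_values, p2$p_values)
  expect_identical(p1$null, p2$null)
  # add-one bound
  expect_gte(p1$p_values, 1 / (p1$n_perm + 1))
  # n <= 12 subjects -> full 2^n enumeration, deterministic without RNG,
  # and the identity sign pattern reproduces the observed statistic
  xs <- rnorm(10)
  pe <- permutation_test(xs, n_perm = 500)
  expect_true(pe$exact)
  expect_equal(pe$n_perm, 1024L)
  expect_true(any(abs(pe$null[, 1] - mean(xs)) < 1e-15))
  expect_identical(permutation_test(xs, n_perm = 500)$p_values, pe$p_values)
  # matrix input gives one p-value per unit
  m <- matrix(rnorm(8 * 5), 8, 5)
  pm <- permutation_test(m, n_perm = 500)
  expect_length(pm$p_values, 5L)
  # t statistic variant works and enumerates too
  pt <- permutation_test(xs, statistic = "t", n_perm = 500)
  expect_true(pt$exact)
  # label shuffle: difference of condition means
  vals <- c(rnorm(30, 1), rnorm(30, 0))
  labs <- rep(c("a", "b"), each = 30)
  ps <- permutation_test(vals, scheme = "trial_label_shuffle",
                         labels = labs, n_perm = 300, seed = 2)
  expect_equal(ps$observed, mean(vals[1:30]) - mean(vals[31:60]))
  expect_lt(ps$p_values, 0.05)
  expect_error(permutation_test(x, n_perm = 50), "at least 100")
  expect_error(permutation_test(vals, scheme = "trial_label_shuffle",
                                n_perm = 200), "labels")
})

test_that("sign-flip permutation p-values are calibrated under the null", {
  # exact enumeration at n = 10 subjects; rejection rate at alpha = 0.05
  # stays inside the binomial 95% interval over 400 null repetitions
  set.seed(16)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    permutation_test(rnorm(10), n_perm = 500)$p_values <= 0.05
  }, logical(1))
  bounds <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("cluster labeling and FWE correction follow hand-computed cases", {
  # 1D map [0,3,3,0,3] at threshold 2 -> clusters of sizes 2 and 1
  null0 <- matrix(0, 100, 5)
  cl <- cluster_correct(c(0, 3, 3, 0, 3), null0, forming_threshold = 2)
  expect_equal(sort(cl$clusters$size), c(1L, 2L))
  expect_identical(cl$clusters$units[[which(cl$clusters$size == 2)]],
                   c(2L, 3L))
  # null maps all sub-threshold -> every cluster at the add-one bound
  expect_equal(cl$clusters$p_fwe, rep(1 / 101, 2))
  # no suprathreshold units -> empty cluster table
  cl0 <- cluster_correct(c(0, 1, 0), matrix(0, 100, 3),
                         forming_threshold = 2)
  expect_equal(nrow(cl0$clusters), 0L)
  # FWE p counts null max sizes at least as large
  set.seed(17)
  nulls <- matrix(rnorm(200 * 5), 200, 5)
  cl2 <- cluster_correct(c(0, 3, 3, 0, 0), nulls, forming_threshold = 2)
  sz <- cl2$clusters$size[1]
  null_max <- vapply(seq_len(200), function(i) {
    r <- rle(nulls[i, ] > 2)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, integer(1))
  expect_equal(cl2$clusters$p_fwe[1],
               (1 + sum(null_max >= sz)) / 201)
  # p-threshold forming: cutoff from the pointwise null quantile
  clp <- cluster_correct(c(0, 3, 3, 0, 0), nulls,
                         forming_threshold = list(p = 0.05))
  expect_equal(clp$threshold,
               apply(nulls, 2, quantile, 0.95, names = FALSE))
})

test_that("3D cluster labeling nests 6-connectivity inside 26-connectivity", {
  arr <- array(FALSE, c(4, 4, 4))
  arr[1, 1, 1] <- TRUE; arr[2, 2, 1] <- TRUE  # diagonal neighbors
  arr[4, 4, 4] <- TRUE
  l6 <- cttrack:::label_components(arr, 6L)
  l26 <- cttrack:::label_components(arr, 26L)
  expect_equal(max(l6), 3L)   # diagonal pair split under 6-connectivity
  expect_equal(max(l26), 2L)  # joined under 26-connectivity
  # every 26-cluster is a union of 6-clusters
  for (id in seq_len(max(l26))) {
    members6 <- unique(l6[l26 == id & arr])
    expect_true(all(l6[l6 %in% members6 & arr] >= 1))
    covered <- l26[arr & l6 %in% members6]
    expect_true(all(covered == id))
  }
  # random 3D mask: the nesting property holds in general
  set.seed(18)
  m <- array(runif(6^3) < 0.3, c(6, 6, 6))
  a6 <- cttrack:::label_components(m, 6L)
  a26 <- cttrack:::label_components(m, 26L)
  split_tab <- table(a6[m], a26[m])
  expect_true(all(rowSums(split_tab > 0) == 1))
})

test_that("false-discovery-rate adjustment is Benjamini-Hochberg step-up", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(rep(0.02, 4)), rep(0.02, 4))
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # agrees with the reference implementation on random input
  set.seed(19)
  p <- runif(50)
  expect_equal(fdr_correct(p), p.adjust(p, "BH"))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})
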