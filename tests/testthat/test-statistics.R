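# Nonparametric group statistics.

test_that("Mann-Whitney U, z and p behave across regimes", {
  same <- c(3, 1, 4, 1, 5)
  r <- mann_whitney(same, same)
  expect_equal(r$z, 0)
  expect_gt(r$p, 0.9)

  sep <- mann_whitney(6:10, 1:5)
  expect_equal(sep$U, 25)  # complete separation, n1 = n2 = 5
  expect_gt(sep$z, 0)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney p matches exact enumeration for small samples", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 1), 1))
    expect_equal(mann_whitney(x, y)$p, exact_mwu_p(x, y), tolerance = 1e-12)
  }
})

test_that("Friedman test recovers degenerate and maximal concordance", {
  m <- matrix(rnorm(10), 10, 4)  # identical columns
  f0 <- friedman_rank_test(matrix(rep(rnorm(10), 4), 10))
  expect_equal(f0$chi2, 0)

  inc <- t(replicate(10, 1:4 + rnorm(4, 0, 1e-6)))
  # strictly increasing rows: chi2 = 12n/(k(k+1)) * sum Rj^2 - 3n(k+1) = 30
  f1 <- friedman_rank_test(t(apply(inc, 1, sort)))
  expect_equal(f1$chi2, 30)
  expect_equal(f1$df, 3)
  expect_error(friedman_rank_test(matrix(1, 1, 3)), "at least 2")
})

test_that("Friedman p-values are calibrated under column shuffling", {
  set.seed(17)
  ps <- replicate(60, {
    m <- matrix(rnorm(8 * 4), 8, 4)
    friedman_rank_test(m)$p
  })
  # valid (discrete, super-uniform) null p-values: small tails, wide body
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.3), 0.3)
})

test_that("BH adjustment follows the step-up rule", {
  r <- bh_fdr(rep(0.001, 40))
  expect_true(all(r$significant))
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_identical(r2$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r2$q, c(0.04, 0.04, 0.04, 0.5))
  r3 <- bh_fdr(rep(1, 10))
  expect_false(any(r3$significant))
  # adjusted values are monotone in the p ordering
  set.seed(3)
  p <- runif(30)
  q <- bh_fdr(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("nNI bootstrap flags a planted ROI and nothing in homogeneous input", {
  flat <- matrix(0.025, 20, 40)
  rb <- nni_bootstrap(flat, n_boot = 500, seed = 1)
  expect_false(any(rb$significant))
  expect_true(all(rb$p >= 1 / (500 * 40 + 1)))

  set.seed(12)
  m <- matrix(runif(20 * 40, 0.5, 1.5), 20, 40)
  m[, 7] <- m[, 7] * 3
  rb2 <- nni_bootstrap(m, n_boot = 2000, seed = 2)
  expect_true(rb2$significant[7])
  expect_equal(sum(rb2$significant), 1)
  expect_true(all(rb2$q >= rb2$p))
  expect_gt(rb2$z[7], 3)
  expect_error(nni_bootstrap(matrix(c(1, NA), 2, 2)), "missing")
  expect_warning(nni_bootstrap(matrix(runif(40), 4), n_boot = 50), "coarse")
})

test_that("bootstrap null medians are approximately normal for Gaussian input", {
  set.seed(4)
  m <- matrix(rnorm(20 * 40), 20, 40)
  rb <- nni_bootstrap(m, n_boot = 500, seed = 5)
  sub <- sample(rb$null_medians, 300)
  expect_gt(shapiro.test(sub)$p.value, 0.05)
})

test_that("MVPA separates separable features and stays at chance on noise", {
  set.seed(21)
  labels <- factor(rep(c("A", "B"), each = 15))
  sep <- cbind(as.integer(labels == "B") + rnorm(30, 0, 0.05),
               matrix(rnorm(30 * 3), 30))
  fit <- mvpa_auc(sep, labels, seed = 1)
  expect_gte(fit$auc_mean, 0.95)

  null_auc <- vapply(1:5, function(s) {
    X <- matrix(rnorm(30 * 5), 30)
    mvpa_auc(X, labels, n_reps = 10, seed = s)$auc_mean
  }, numeric(1))
  expect_true(all(null_auc > 0.2 & null_auc < 0.8))
  expect_gt(mean(null_auc), 0.3); expect_lt(mean(null_auc), 0.7)

  f2 <- mvpa_auc(sep, labels, seed = 1)
  expect_identical(fit$folds, f2$folds)
  expect_identical(fit$auc, f2$auc)
  expect_error(mvpa_auc(sep, factor(rep("A", 30))), "2 levels")
})

test_that("MVPA permutation reuses folds and bounds its p-value", {
  set.seed(22)
  labels <- factor(rep(c("A", "B"), each = 12))
  sep <- cbind(as.integer(labels == "B") + rnorm(24, 0, 0.05),
               matrix(rnorm(24 * 2), 24))
  res <- mvpa_permutation(sep, labels, n_perm = 99, seed = 2, n_reps = 5)
  expect_lte(res$p, 0.05)
  expect_gte(res$p, 1 / 100)

  X <- matrix(rnorm(24 * 4), 24)
  res0 <- mvpa_permutation(X, labels, n_perm = 59, seed = 3, n_reps = 3)
  expect_gt(res0$p, 0.05)
  # identical folds between observed statistic and permutations (recorded)
  expect_identical(res$observed$folds,
                   mvpa_auc(sep, labels, n_reps = 5, seed = 2)$folds)
})

test_that("the rank-formula AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    scores <- rnorm(40)
    truth <- factor(sample(c("A", "B"), 40, replace = TRUE))
    got <- ictogenicity:::rank_auc(scores, truth)
    ref <- suppressMessages(as.numeric(pROC::auc(truth, scores,
                                                 levels = c("A", "B"),
                                                 direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})
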