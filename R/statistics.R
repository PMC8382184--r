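# Nonparametric group statistics for BNI / nNI analyses.

#' Mann-Whitney U test with z effect size
#'
#' Two-sided rank-sum comparison reporting the U statistic of the first
#' sample, the tie-corrected normal-approximation z-score (used as an
#' effect size), and the p-value.  For small untied samples the p-value is
#' exact (enumeration of rank arrangements via [stats::wilcox.test()]);
#' otherwise the normal approximation is used.  No continuity correction
#' is applied to z.
#'
#' @param x,y numeric samples; `x` is the first group (z > 0 means `x`
#'   tends larger).
#' @return an object of class `rank_test` with `U`, `z`, `p`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(5, 6, 7), c(1, 2, 3))$U  # 9, complete separation
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  mu <- n1 * n2 / 2
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (v > 0) (U - mu) / sqrt(v) else 0
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  structure(list(U = U, z = z, p = p, n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, z = %.4f, p = %.4g (n = %d, %d)\n",
              x$U, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

#' Friedman test for paired group-level comparisons
#'
#' Rank test across conditions within participants; reports the chi-square
#' statistic as the effect size.
#'
#' @param m numeric matrix, participants x conditions (>= 2 each).
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman_rank_test <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 participants and 2 conditions")
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(chi2)) {
    # fully tied rows (no between-condition variation): zero evidence
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(ft$parameter), p = p)
}

#' Bootstrap null test for node-wise nNI contributions
#'
#' Tests which ROIs contribute more than expected under the null that all
#' nodes contribute equally: surrogate nNI matrices of the original shape
#' are drawn by resampling the pooled entries with replacement (destroying
#' any ROI effect), per-ROI medians over participants are computed for
#' each surrogate, and every surrogate column contributes to one pooled
#' null distribution of medians (columns are exchangeable under pooled
#' resampling).  One-sided add-one p-values per ROI are
#' Benjamini-Hochberg adjusted.
#'
#' @param nni numeric matrix, participants x ROIs, no missing entries.
#' @param n_boot surrogate data sets (default 10000).
#' @param seed integer seed.
#' @param q_level FDR level for the significance mask.
#' @param alternative `"greater"` scores high-median ROIs (seizure
#'   driving, the default reading); `"two.sided"` doubles the smaller
#'   tail.
#' @return an object of class `nni_bootstrap`: per-ROI `z`, `p`, `q`,
#'   `significant`, plus `null_medians` (the pooled null), `observed`
#'   medians and `n_boot`.
#' @export
nni_bootstrap <- function(nni, n_boot = 10000, seed = 1, q_level = 0.05,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nni <- as.matrix(nni)
  if (any(!is.finite(nni))) stop("nni matrix has missing entries")
  if (n_boot < 100) warning("n_boot < 100 gives very coarse p-values")
  n_p <- nrow(nni); n_roi <- ncol(nni)
  obs <- apply(nni, 2, median)
  set.seed(seed)
  pool <- as.vector(nni)
  # all surrogates in one draw: (participants) x (ROIs * n_boot)
  surr <- matrix(sample(pool, n_p * n_roi * n_boot, replace = TRUE), nrow = n_p)
  null_med <- .cpp_col_medians(surr)
  m0 <- mean(null_med); s0 <- sd(null_med)
  z <- (obs - m0) / s0
  n_null <- length(null_med)
  p_hi <- (1 + vapply(obs, function(o) sum(null_med >= o), numeric(1))) /
    (1 + n_null)
  if (alternative == "greater") {
    p <- p_hi
  } else {
    p_lo <- (1 + vapply(obs, function(o) sum(null_med <= o), numeric(1))) /
      (1 + n_null)
    p <- pmin(1, 2 * pmin(p_hi, p_lo))
  }
  adj <- bh_fdr(p, q_level)
  structure(list(z = z, p = p, q = adj$q, significant = adj$significant,
                 observed = obs, null_medians = null_med, n_boot = n_boot,
                 alternative = alternative, q_level = q_level),
            class = "nni_bootstrap")
}

#' @export
print.nni_bootstrap <- function(x, ...) {
  cat(sprintf(
    "nNI bootstrap: %d ROIs, %d surrogates (%s); %d significant at FDR %g\n",
    length(x$p), x$n_boot, x$alternative, sum(x$significant), x$q_level))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with a significance mask at `q_level`.
#'
#' @param p p-values in `[0, 1]`.
#' @param q_level FDR level.
#' @return list with `q` (adjusted values) and logical `significant`.
#' @export
bh_fdr <- function(p, q_level = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= q_level)
}

# stratified fold assignment: each class split as evenly as possible
stratified_folds <- function(labels, n_folds) {
  f <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    f[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  f
}

# AUC by the rank (Mann-Whitney) formula; positive class = second level
rank_auc <- function(scores, truth) {
  pos <- truth == levels(truth)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(scores)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# cross-validated logistic-regression AUC for one set of fold assignments;
# folds without test samples (more folds than class members) score NA
cv_auc_once <- function(X, labels, folds, n_folds = max(folds)) {
  aucs <- vapply(seq_len(n_folds), function(k) {
    if (!any(folds == k)) return(NA_real_)
    tr <- folds != k
    if (length(unique(labels[tr])) < 2)
      stop("single-class training fold; use stratified folds / larger groups")
    y <- as.integer(labels[tr] == levels(labels)[2])
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X[tr, , drop = FALSE]), y,
                     family = stats::binomial()))
    eta <- cbind(1, X[!tr, , drop = FALSE]) %*% fit$coefficients
    rank_auc(as.numeric(eta), labels[!tr])
  }, numeric(1))
  aucs
}

#' Cross-validated MVPA classification of group from nNI/NI profiles
#'
#' Multivariate pattern analysis: unregularized logistic regression on the
#' spatial feature profiles, scored by stratified 5-fold cross-validated
#' AUC, repeated `n_reps` times with fresh fold assignments; the mean AUC
#' over all folds and repetitions is the performance metric.  Fold
#' assignments are recorded so permutation testing can reuse them.
#'
#' @param features numeric matrix, subjects x features (e.g. nNI per ROI).
#' @param labels two-level factor (or coercible) of group membership.
#' @param n_folds cross-validation folds (stratified).
#' @param n_reps repetitions with re-drawn folds.
#' @param seed integer seed.
#' @return an object of class `mvpa_result`: `auc_mean`, `auc_sd` (across
#'   folds and repetitions), matrix `auc` (reps x folds), and the recorded
#'   `folds` (reps x subjects).
#' @export
mvpa_auc <- function(features, labels, n_folds = 5, n_reps = 20, seed = 1) {
  X <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
  if (nrow(X) != length(labels)) stop("features/labels length mismatch")
  set.seed(seed)
  folds <- t(vapply(seq_len(n_reps), function(r) stratified_folds(labels, n_folds),
                    integer(length(labels))))
  auc <- t(vapply(seq_len(n_reps),
                  function(r) cv_auc_once(X, labels, folds[r, ], n_folds),
                  numeric(n_folds)))
  structure(list(auc_mean = mean(auc, na.rm = TRUE),
                 auc_sd = sd(as.vector(auc), na.rm = TRUE),
                 auc = auc, folds = folds, n_folds = n_folds,
                 n_reps = n_reps, seed = seed),
            class = "mvpa_result")
}

#' @export
print.mvpa_result <- function(x, ...) {
  cat(sprintf("MVPA: AUC = %.4f +/- %.4f (%d-fold CV, %d repetitions)\n",
              x$auc_mean, x$auc_sd, x$n_folds, x$n_reps))
  invisible(x)
}

#' Permutation test for MVPA classification
#'
#' Permutes the group labels `n_perm` times and re-evaluates the mean
#' cross-validated AUC using the *same* fold assignments and repetitions
#' as the observed statistic, so the degree of overfitting is identical in
#' observed and permuted data.  The add-one p-value is
#' `(1 + #\{perm AUC >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams mvpa_auc
#' @param n_perm number of label permutations.
#' @param fit optional precomputed [mvpa_auc()] result (its folds and
#'   observed AUC are reused).
#' @return list with `p`, `observed` (the `mvpa_result`), and `perm_auc`.
#' @export
mvpa_permutation <- function(features, labels, n_perm = 1000, seed = 1,
                             n_folds = 5, n_reps = 20, fit = NULL) {
  X <- as.matrix(features)
  labels <- factor(labels)
  if (is.null(fit))
    fit <- mvpa_auc(X, labels, n_folds = n_folds, n_reps = n_reps, seed = seed)
  set.seed(derive_seed(seed, 1))
  perm_auc <- vapply(seq_len(n_perm), function(pp) {
    pl <- labels[sample(length(labels))]
    mean(vapply(seq_len(fit$n_reps),
                function(r) mean(cv_auc_once(X, pl, fit$folds[r, ],
                                             fit$n_folds), na.rm = TRUE),
                numeric(1)))
  }, numeric(1))
  p <- (1 + sum(perm_auc >= fit$auc_mean)) / (1 + n_perm)
  list(p = p, observed = fit, perm_auc = perm_auc)
}
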