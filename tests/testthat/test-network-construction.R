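# PLV functional-network pipeline: filter, phases, surrogates, masks.

make_ts <- function(f, fs = 250, dur = 8, noise = 0, seed = 1, n = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- t(vapply(seq_len(n), function(i)
    cos(2 * pi * f * t) + rnorm(length(t), 0, noise), numeric(length(t))))
  roi_timeseries(x, fs)
}

test_that("theta band-pass keeps 6 Hz and rejects 20 Hz", {
  pass <- theta_bandpass(make_ts(6, fs = 1000, dur = 4))
  mid <- 1000:3000  # avoid filter edges
  expect_gte(max(abs(pass$data[1, mid])), 0.95)
  stopb <- theta_bandpass(make_ts(20, fs = 1000, dur = 4))
  expect_lte(max(abs(stopb$data[1, mid])), 0.1)
  z <- roi_timeseries(matrix(0, 1, 1000), 250)
  expect_identical(unique(as.vector(theta_bandpass(z)$data)), 0)
  expect_error(theta_bandpass(roi_timeseries(matrix(rnorm(32), 1), 15)),
               "too low")
})

test_that("instantaneous phase advances at the oscillation frequency", {
  ts <- make_ts(6, fs = 500, dur = 6)
  ph <- instantaneous_phase(ts)
  mid <- 500:2500
  slope <- mean(diff(unwrap_phase(ph[1, mid]))) * 500
  expect_equal(slope, 2 * pi * 6, tolerance = 0.005 * 2 * pi * 6)

  # cos vs sin: quarter-cycle mean offset
  t <- seq(0, 6 - 1 / 500, by = 1 / 500)
  both <- roi_timeseries(rbind(cos(2 * pi * 6 * t), sin(2 * pi * 6 * t)), 500)
  phb <- instantaneous_phase(both)
  d <- Arg(mean(exp(1i * (phb[1, mid] - phb[2, mid]))))
  expect_equal(d, pi / 2, tolerance = 0.01)

  # channel permutation permutes phases
  three <- roi_timeseries(rbind(cos(2 * pi * 5 * t), cos(2 * pi * 6 * t),
                                cos(2 * pi * 7 * t)), 500)
  p1 <- instantaneous_phase(three)
  swapped <- roi_timeseries(three$data[c(3, 1, 2), ], 500,
                            three$labels[c(3, 1, 2)])
  expect_equal(unname(instantaneous_phase(swapped)),
               unname(p1[c(3, 1, 2), ]))
  expect_error(instantaneous_phase(roi_timeseries(matrix(1, 1, 100), 100)),
               "degenerate")
})

test_that("PLV matches the direct phasor-average definition", {
  set.seed(1)
  a <- runif(1000, -pi, pi); b <- runif(1000, -pi, pi)
  r <- plv_pair(a, b)
  # independent oracle: resultant length from separate cos/sin sums
  d <- a - b
  oracle <- sqrt(mean(cos(d))^2 + mean(sin(d))^2)
  expect_equal(r$plv, oracle, tolerance = 1e-12)
  expect_equal(plv_pair(a, a)$plv, 1, tolerance = 1e-12)
  expect_equal(plv_pair(a, a)$mean_dphi, 0)
  off <- plv_pair(a, a - pi / 2)
  expect_equal(off$plv, 1, tolerance = 1e-12)
  expect_equal(off$mean_dphi, pi / 2, tolerance = 1e-12)
  expect_error(plv_pair(a, b[-1]), "length mismatch")
})

test_that("PLV of independent random phases is near zero, and is shift-invariant", {
  set.seed(7)
  hits <- vapply(1:50, function(i) {
    a <- runif(1000, -pi, pi); b <- runif(1000, -pi, pi)
    plv_pair(a, b)$plv < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.98)
  a <- cumsum(rnorm(500)); b <- cumsum(rnorm(500))
  expect_equal(plv_pair(a + 1.3, b + 1.3)$plv, plv_pair(a, b)$plv,
               tolerance = 1e-12)
})

test_that("IAAFT surrogates keep amplitudes exactly and the spectrum closely", {
  ts <- make_ts(6, fs = 250, dur = 20, noise = 0.5, seed = 3)
  x <- ts$data[1, ]
  s <- iaaft_surrogate(x, seed = 5)
  expect_identical(sort(as.numeric(s)), sort(x))
  expect_lt(attr(s, "spec_error"), 0.05)
  s2 <- iaaft_surrogate(x, seed = 6)
  expect_false(identical(as.numeric(s), as.numeric(s2)))
  # spectral error decreases with iteration budget
  e1 <- attr(iaaft_surrogate(x, n_iter = 1, tol = 0, seed = 5), "spec_error")
  e9 <- attr(iaaft_surrogate(x, n_iter = 50, tol = 0, seed = 5), "spec_error")
  expect_lt(e9, e1)
  expect_error(iaaft_surrogate(rep(1, 100)), "constant")
  expect_error(iaaft_surrogate(rnorm(8)), "too short")
})

test_that("zero-lag rejection uses the strict one-sample threshold", {
  expect_equal(zero_lag_threshold(1000) / pi, 0.008)
  d <- matrix(c(0, 0, 0, 0), 2)
  expect_false(any(zero_lag_mask(d, 1000)))
  d2 <- matrix(c(0, 0.008 * pi, 0.008 * pi, 0), 2)
  expect_true(zero_lag_mask(d2, 1000)[1, 2])  # exactly at threshold: retained
  d3 <- matrix(c(0, pi / 2, pi / 2, 0), 2)
  expect_true(zero_lag_mask(d3, 1000)[1, 2])
  d4 <- matrix(c(0, 0.007 * pi, 0.007 * pi, 0), 2)
  expect_false(zero_lag_mask(d4, 1000)[1, 2])
})

test_that("indirect-path filter matches exhaustive enumeration and is idempotent", {
  # worked triangle: direct AC length 2.5 exceeds the via-B path 2.22
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9; w[2, 3] <- w[3, 2] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.4
  out <- indirect_path_filter(weighted_network(w))
  expect_equal(out$weights[1, 3], 0)
  expect_equal(out$weights[1, 2], 0.9)

  two <- weighted_network(matrix(c(0, .3, .3, 0), 2))
  expect_equal(indirect_path_filter(two)$weights, two$weights)

  eq <- matrix(0.5, 3, 3); diag(eq) <- 0
  expect_equal(indirect_path_filter(weighted_network(eq))$weights,
               weighted_network(eq)$weights)

  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    on <- runif(length(up)) < 0.7
    w[up[on]] <- runif(sum(on), 0.1, 1)
    w <- w + t(w)
    got <- indirect_path_filter(weighted_network(w))$weights
    expect_equal(unname(got), brute_force_path_filter(w))
    # idempotence
    expect_equal(indirect_path_filter(weighted_network(got))$weights,
                 got, ignore_attr = TRUE)
  }
})

test_that("surrogate mask retains locked pairs and calibrates near alpha under the null", {
  # genuinely lagged-locked pair survives
  fs <- 250; t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  set.seed(2)
  base <- 2 * pi * 6 * t + cumsum(rnorm(length(t), 0, 0.05))
  x <- rbind(cos(base) + rnorm(length(t), 0, .2),
             cos(base - 0.3) + rnorm(length(t), 0, .2))
  ts <- theta_bandpass(roi_timeseries(x, fs))
  ph <- ictogenicity:::trim_phases(instantaneous_phase(ts), fs, 1)
  pm <- ictogenicity:::plv_matrix(ph)
  m <- surrogate_mask(ts, pm$plv, n_surr = 19, seed = 3)
  expect_true(m[1, 2])

  # independent white noise: per-edge retention approximately alpha
  set.seed(5)
  nts <- theta_bandpass(roi_timeseries(matrix(rnorm(10 * 1500), 10), 250))
  nph <- ictogenicity:::trim_phases(instantaneous_phase(nts), 250, 1)
  npm <- ictogenicity:::plv_matrix(nph)
  nm <- surrogate_mask(nts, npm$plv, n_surr = 19, seed = 6)
  rate <- mean(nm[upper.tri(nm)])
  expect_lt(rate, 0.25)  # 45 edges at alpha = 0.05: binomial upper bound
  expect_error(surrogate_mask(nts, npm$plv, n_surr = 5), "n_surr too small")
})

test_that("the full pipeline is monotone and kills identical-copy channels", {
  net <- make_topology(6, "modular", n_modules = 2, p_in = 0.9, p_out = 0,
                       seed = 4)
  ts <- simulate_roi_signals(net, fs = 250, duration = 8, seed = 5)
  fn <- build_network(ts, n_surr = 19, seed = 6)
  expect_true(isSymmetric(fn$final$weights))
  expect_true(all(diag(fn$final$weights) == 0))
  # monotone: every final edge passed every mask
  fin <- fn$final$weights > 0
  expect_true(all(fin[fn$masks$surrogate == FALSE] == FALSE))
  expect_true(all(fin[fn$masks$zero_lag == FALSE] == FALSE))

  # identical copies of one signal: zero-lag rejection empties the network
  set.seed(8)
  one <- cos(2 * pi * 6 * seq(0, 8, by = 1 / 250)) + rnorm(2001, 0, .1)
  copies <- roi_timeseries(matrix(rep(one, 5), 5, byrow = TRUE), 250)
  fn2 <- build_network(copies, n_surr = 19, seed = 9)
  expect_equal(sum(fn2$final$weights), 0)
})
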