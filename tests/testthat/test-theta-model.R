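# Theta-model integrator and seizure classifier.

test_that("stable rest phase solves the drift equation on the attracting branch", {
  expect_equal(stable_phase(-1), -pi / 2)
  expect_equal(stable_phase(-1 / 3), -pi / 3)
  expect_lt(abs(stable_phase(-1e-9)), 1e-4)  # theta_s -> 0 as I0 -> 0-
  expect_error(stable_phase(0.5), "no fixed point")

  # independent root-find of the drift for I0 = -1/3 lands on -pi/3
  root <- uniroot(function(th) theta_drift(th, -1 / 3),
                  c(-pi + 1e-6, -1e-6), tol = 1e-14)$root
  expect_equal(root, -pi / 3, tolerance = 1e-9)

  for (I0 in seq(-1.7, -1e-3, length.out = 50)) {
    th <- stable_phase(I0)
    expect_lt(abs(theta_drift(th, I0)), 1e-12)
    # linear stability of the negative branch: f'(theta_s) < 0
    expect_lt(sin(th) * (1 - I0), 0)
  }
})

test_that("drift evaluates the phase equation", {
  expect_equal(theta_drift(pi, 123), 2)
  expect_equal(theta_drift(pi, -7), 2)
  expect_equal(theta_drift(0, 0.3), 0.6)
  expect_equal(theta_drift(0, -2), -4)
})

test_that("rest is a fixed point and coupling vanishes at rest", {
  net1 <- weighted_network(matrix(0, 1, 1))
  p <- quick_params(-0.5, sigma = 0, steps = 5000)
  sim <- simulate_theta(net1, p, seed = 1)
  expect_true(all(abs(sim$phases - stable_phase(-0.5)) < 1e-12))

  # with every node at rest the network drive is exactly zero
  net <- rand_weighted_net(6, seed = 3)
  simn <- simulate_theta(net, quick_params(-0.9, sigma = 0, steps = 3000), seed = 1)
  expect_true(all(abs(simn$phases - stable_phase(-0.9)) < 1e-12))
})

test_that("noiseless rotation period matches the closed form pi/sqrt(I0)", {
  # independent oracle: quadrature of dtheta / drift over one cycle
  for (I0 in c(0.04, 0.25)) {
    quad <- integrate(function(th) 1 / theta_drift(th, I0), 0, 2 * pi,
                      rel.tol = 1e-10)$value
    expect_equal(quad, pi / sqrt(I0), tolerance = 1e-8)

    p <- model_params(I0, sigma = 0, dt = 1e-3, steps = 3e5, K = 0)
    sim <- simulate_theta(weighted_network(matrix(0, 1, 1)), p, seed = 1)
    span <- sim$phases[1, ncol(sim$phases)] - sim$phases[1, 1]
    period <- unname((p$steps - 1) * p$dt / (span / (2 * pi)))
    expect_equal(period, pi / sqrt(I0), tolerance = 0.01)
  }
})

test_that("trajectories are bit-identical given (network, params, seed)", {
  net <- rand_weighted_net(5, seed = 2)
  p <- quick_params(-0.8, steps = 5000)
  s1 <- simulate_theta(net, p, seed = 42)
  s2 <- simulate_theta(net, p, seed = 42)
  s3 <- simulate_theta(net, p, seed = 43)
  expect_identical(s1$phases, s2$phases)
  expect_false(identical(s1$phases, s3$phases))
})

test_that("node permutation permutes trajectories and seizure times exactly", {
  net <- rand_weighted_net(6, seed = 4)
  p <- quick_params(-0.7, steps = 8000)
  perm <- c(3, 1, 6, 2, 5, 4)
  net_p <- weighted_network(net$weights[perm, perm], net$labels[perm])
  s <- simulate_theta(net, p, seed = 9)
  s_p <- simulate_theta(net_p, p, seed = 9)
  # noise streams follow labels; only the coupling summation order differs,
  # so trajectories agree to floating accumulation error
  expect_equal(unname(s_p$phases), unname(s$phases[perm, ]), tolerance = 1e-8)
  t1 <- classify_seizure(s)$t_sz
  t2 <- classify_seizure(s_p)$t_sz
  expect_equal(unname(t2), unname(t1[perm]), tolerance = 1e-3)
})

test_that("classifier scores rest as zero and a planted rotation plateau as half", {
  net1 <- weighted_network(matrix(0, 1, 1))
  p <- quick_params(-0.6, sigma = 0, steps = 2e4, burn_in = 0)
  sim <- simulate_theta(net1, p, seed = 1)
  expect_equal(sum(classify_seizure(sim)$t_sz), 0)

  # constructed trajectory: first half at rest, second half at the antipode
  ths <- stable_phase(-0.6)
  sim$phases[1, ] <- rep(c(ths, ths + pi), each = p$steps / 2)
  st <- classify_seizure(sim)
  frac <- st$t_sz / st$T_scored
  expect_equal(unname(frac), 0.5, tolerance = p$window / (p$steps * p$dt))
})

test_that("noiseless supra-threshold rotation is scored at its far-phase duty cycle", {
  # The rotation lingers near the SNIC ghost (close to the rest reference),
  # so the classifier scores only the far-half fraction of each period.
  I0 <- 0.1
  duty_oracle <- integrate(function(th) 1 / theta_drift(th, I0), pi / 2,
                           3 * pi / 2, rel.tol = 1e-10)$value /
    integrate(function(th) 1 / theta_drift(th, I0), 0, 2 * pi,
              rel.tol = 1e-10)$value
  p <- model_params(I0, sigma = 0, dt = 1e-3, steps = 2e5, K = 0,
                    burn_in = 0)
  sim <- simulate_theta(weighted_network(matrix(0, 1, 1)), p, seed = 1)
  st <- classify_seizure(sim, theta_ref = 0)
  expect_equal(unname(st$t_sz / st$T_scored), duty_oracle, tolerance = 0.03)
  expect_gt(duty_oracle, 0.15)  # sanity: the oracle itself
  expect_lt(duty_oracle, 0.25)
})

test_that("seizure fraction is the average seizure-time proportion", {
  st <- structure(list(t_sz = c(100, 0), T_scored = 100,
                       counts = c(10000L, 0L), n_scored = 10000L),
                  class = "seizure_times")
  expect_equal(seizure_fraction(st), 0.5)
  st$t_sz <- c(0, 0); expect_equal(seizure_fraction(st), 0)
  st$t_sz <- c(100, 100); expect_equal(seizure_fraction(st), 1)
})

test_that("fast scored path equals simulate + classify exactly", {
  net <- rand_weighted_net(5, seed = 6)
  for (scaling in c("dt", "sqrt_dt")) {
    p <- quick_params(-0.8, steps = 2e4, noise_scaling = scaling)
    sim <- simulate_theta(net, p, seed = 11)
    slow <- seizure_fraction(classify_seizure(sim))
    fast <- ictogenicity:::psz_point(net, p, 11)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("explicit noise matrices override the internal streams", {
  net <- rand_weighted_net(4, seed = 8)
  p <- quick_params(-0.9, steps = 3000)
  noise <- matrix(rnorm(4 * (p$steps - 1)), 4)
  s1 <- simulate_theta(net, p, seed = 1, noise = noise)
  s2 <- simulate_theta(net, p, seed = 999, noise = noise)
  expect_identical(s1$phases, s2$phases)
  # permuting network and noise rows together permutes the trajectories
  perm <- c(4, 2, 1, 3)
  net_p <- weighted_network(net$weights[perm, perm], net$labels[perm])
  s3 <- simulate_theta(net_p, p, seed = 1, noise = noise[perm, ])
  expect_equal(unname(s3$phases), unname(s1$phases[perm, ]))
})

test_that("invalid model setups are rejected", {
  expect_error(model_params(-1, dt = 0), "dt")
  expect_error(model_params(-1, sigma = -1), "sigma")
  expect_error(model_params(-1, steps = 100, burn_in = 100), "burn_in")
  net <- weighted_network(matrix(c(0, .5, .5, 0), 2))
  expect_error(simulate_theta(net, quick_params(0.2, steps = 1000), seed = 1),
               "theta_s is undefined")
  expect_error(weighted_network(matrix(c(0, 1, 2, 0), 2)), "asymmetric")
  expect_error(weighted_network(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})
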