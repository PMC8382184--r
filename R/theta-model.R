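#' Stable rest phase of the theta model
#'
#' For subthreshold excitability `I0 <= 0` the theta neuron has a pair of
#' fixed points; the attracting one sits on the negative branch,
#' `theta_s = -acos((1 + I0) / (1 - I0))`, with the saddle at the mirrored
#' positive angle.  The drift vanishes there and its linearization is
#' stable (`sin(theta_s) (1 - I0) < 0`).
#'
#' @param I0 excitability (unitless); must satisfy `I0 <= 0`.
#' @return rest phase in radians, in `[-pi/2, 0]`.
#' @export
#' @examples
#' stable_phase(-1)      # -pi/2
#' theta_drift(stable_phase(-0.3), -0.3)  # 0
stable_phase <- function(I0) {
  if (any(I0 > 0))
    stop("no fixed point: the theta model has no rest state for I0 > 0 ",
         "(SNIC bifurcation at I = 0)")
  -acos((1 + I0) / (1 - I0))
}

#' Phase drift of the theta model
#'
#' The deterministic right-hand side `(1 - cos(theta)) + (1 + cos(theta)) I`.
#'
#' @param theta phase in radians.
#' @param I total input current.
#' @return drift (rate of phase change), vectorized over inputs.
#' @export
theta_drift <- function(theta, I) {
  (1 - cos(theta)) + (1 + cos(theta)) * I
}

#' Simulation parameters for the stochastic theta model
#'
#' Bundles the model constants of the seizure-transition simulations.
#' Defaults are the standard values of the framework: global coupling
#' `K = 10`, noise level `sigma = 6`, step `dt = 1e-2` and `steps = 4e6`
#' total samples.  Scaled-down runs (e.g. `steps = 1e5`) are used for
#' testing; see the methods vignette.
#'
#' @param I0 excitability of all ROIs (the model assumes one shared value).
#' @param K global coupling constant.
#' @param sigma standard deviation of the Gaussian input noise.
#' @param dt integration step (arbitrary time units).
#' @param steps total number of samples in a trajectory (`steps - 1` Euler
#'   steps are taken).
#' @param burn_in samples discarded before seizure scoring; default 5% of
#'   `steps`.
#' @param noise_scaling `"dt"` folds the noise into the input current
#'   (update `dt * (1 + cos) * sigma * zeta`); `"sqrt_dt"` is the
#'   Euler-Maruyama convention (`(1 + cos) * sigma * sqrt(dt) * zeta`).
#'   The two differ only by a `sqrt(dt)` rescaling of `sigma`; with the
#'   standard `sigma = 6` only `"dt"` yields the regime in which coupling
#'   controls seizure propensity (see the vignette), hence the default.
#' @param window smoothing window of the seizure classifier, in time units.
#' @param threshold smoothed-indicator threshold of the classifier.
#' @param theta0 optional initial phase(s); defaults to the rest phase
#'   `stable_phase(I0)` (or 0 when `I0 > 0`, where no rest state exists).
#' @return an object of class `model_params`.
#' @export
model_params <- function(I0, K = 10, sigma = 6, dt = 1e-2, steps = 4e6,
                         burn_in = round(0.05 * steps),
                         noise_scaling = c("dt", "sqrt_dt"),
                         window = 1, threshold = 0.5, theta0 = NULL) {
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(length(I0) == 1, is.finite(I0))
  if (dt <= 0) stop("dt must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  steps <- as.integer(steps); burn_in <- as.integer(burn_in)
  if (burn_in < 0 || steps <= burn_in)
    stop("need steps > burn_in >= 0")
  theta_s <- if (I0 <= 0) stable_phase(I0) else NA_real_
  structure(list(I0 = I0, K = K, sigma = sigma, dt = dt, steps = steps,
                 burn_in = burn_in, noise_scaling = noise_scaling,
                 window = window, threshold = threshold,
                 theta_s = theta_s, theta0 = theta0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "theta-model parameters: I0=%g K=%g sigma=%g dt=%g steps=%g burn_in=%g\n",
    x$I0, x$K, x$sigma, x$dt, x$steps, x$burn_in))
  cat(sprintf("  noise scaling: %s; classifier window %g, threshold %g\n",
              x$noise_scaling, x$window, x$threshold))
  invisible(x)
}

# shared argument checks + node keys for the C++ steppers
sim_args <- function(network, params, n_norm = NULL) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(params, "model_params"))
  has_edges <- any(network$weights > 0)
  if (params$I0 > 0 && has_edges && params$K != 0)
    stop("I0 > 0: the rest phase theta_s is undefined, so the coupling ",
         "term of the network model cannot be evaluated")
  theta_s <- if (is.na(params$theta_s)) 0 else params$theta_s
  theta0 <- params$theta0 %||% theta_s
  theta0 <- rep_len(theta0, network$N)
  list(theta_s = theta_s, theta0 = theta0,
       n_norm = n_norm %||% network$N,
       keys = label_key(network$labels))
}

#' Simulate the stochastic theta model on a network
#'
#' Integrates `steps - 1` Euler steps of the coupled phase oscillators
#' \deqn{\dot\theta_i = (1-\cos\theta_i) + (1+\cos\theta_i)\, I_i(t),}
#' where the input current combines the shared excitability `I0`, Gaussian
#' noise of standard deviation `sigma`, and diffusive network drive
#' `(K/N) \sum_j a_{ji} (1 - \cos(\theta_j - \theta_s))`.  All nodes start
#' at the rest phase unless `params$theta0` overrides.
#'
#' Noise streams are keyed per node by the ROI label, so a run is
#' reproducible given `(network, params, seed)` and the streams of
#' surviving nodes are unchanged under node removal or permutation
#' (common random numbers for node-ictogenicity contrasts).
#'
#' @param network a [weighted_network].
#' @param params a [model_params].
#' @param seed integer seed of the run.
#' @param noise optional `N x (steps - 1)` matrix of standard-normal
#'   deviates overriding the internal streams (used for exact
#'   counterfactual experiments).
#' @param n_norm divisor of the `K/N` coupling normalization; defaults to
#'   the current network size.
#' @return an object of class `theta_sim` with the `N x steps` phase matrix
#'   `phases` (radians, unwrapped; column 1 is the initial condition),
#'   plus `params`, `seed` and the network.
#' @export
#' @examples
#' net <- make_topology(3, "star", hub_weight = 0.6, seed = 1)
#' p <- model_params(-0.8, steps = 2000)
#' sim <- simulate_theta(net, p, seed = 7)
#' dim(sim$phases)
simulate_theta <- function(network, params, seed = 1, noise = NULL,
                           n_norm = NULL) {
  a <- sim_args(network, params, n_norm)
  if (!is.null(noise)) {
    noise <- as.matrix(noise)
    if (nrow(noise) != network$N || ncol(noise) != params$steps - 1)
      stop("noise must be N x (steps - 1)")
    if (any(!is.finite(noise))) stop("non-finite noise")
  }
  ph <- .cpp_theta_phases(network$weights, params$I0, params$K, params$sigma,
                          params$dt, params$steps, a$theta_s, a$theta0,
                          a$n_norm, a$keys, as.numeric(seed),
                          params$noise_scaling == "sqrt_dt", noise)
  rownames(ph) <- network$labels
  structure(list(phases = ph, params = params, seed = seed,
                 network = network),
            class = "theta_sim")
}

#' @export
print.theta_sim <- function(x, ...) {
  cat(sprintf("theta-model trajectory: %d nodes x %d samples (dt=%g, seed=%s)\n",
              nrow(x$phases), ncol(x$phases), x$params$dt,
              format(x$seed)))
  invisible(x)
}

# Integer-exact centered moving-average classifier shared (in logic) with
# the streaming C++ scorer: raw indicator 1 - cos(theta - ref) > 1, mean
# over a truncated centered window, strictly above `threshold`.
smooth_counts <- function(r, window_steps, threshold) {
  T <- length(r)
  h <- window_steps %/% 2
  cs <- c(0L, cumsum(r))
  t <- seq_len(T)
  lo <- pmax(t - h, 1L); hi <- pmin(t + h, T)
  s <- cs[hi + 1L] - cs[lo]
  if (threshold == 0.5) s * 2L > (hi - lo + 1L) else
    s > threshold * (hi - lo + 1L)
}

#' Classify per-node time spent in the seizure (rotating) state
#'
#' A node is scored as seizing when its phase is sustainedly far from the
#' rest phase: the raw indicator `1 - cos(theta - theta_s) > 1` (more than
#' pi/2 from rest) is smoothed by a centered moving average over
#' `params$window` time units and thresholded at `params$threshold`.
#' Samples before `params$burn_in` are discarded.
#'
#' @param sim a [theta_sim] trajectory (finite phases).
#' @param params parameters used for scoring; defaults to the simulation's.
#' @param theta_ref reference (rest) phase; defaults to `params$theta_s`.
#'   Must be given explicitly when `I0 > 0`.
#' @return an object of class `seizure_times`: named per-node seizure
#'   durations `t_sz` (time units), the scored duration `T_scored`, and the
#'   underlying sample counts.
#' @export
classify_seizure <- function(sim, params = sim$params, theta_ref = NULL) {
  stopifnot(inherits(sim, "theta_sim"))
  ph <- sim$phases
  if (any(!is.finite(ph))) stop("non-finite phases in trajectory")
  theta_ref <- theta_ref %||% params$theta_s
  if (is.na(theta_ref))
    stop("I0 > 0 has no rest phase; supply theta_ref explicitly")
  Tn <- ncol(ph)
  if (Tn <= params$burn_in) stop("no scored samples: steps <= burn_in")
  w <- max(1L, as.integer(round(params$window / params$dt)))
  keep <- (params$burn_in + 1L):Tn
  counts <- vapply(seq_len(nrow(ph)), function(i) {
    r <- as.integer((1 - cos(ph[i, ] - theta_ref)) > 1)
    sum(smooth_counts(r, w, params$threshold)[keep])
  }, integer(1))
  names(counts) <- rownames(ph)
  structure(list(t_sz = counts * params$dt,
                 T_scored = length(keep) * params$dt,
                 counts = counts, n_scored = length(keep)),
            class = "seizure_times")
}

#' @export
print.seizure_times <- function(x, ...) {
  cat(sprintf("seizure times: %d nodes, T_scored=%g, P_sz=%.4f\n",
              length(x$t_sz), x$T_scored, seizure_fraction(x)))
  invisible(x)
}

#' Average proportion of time spent in seizures
#'
#' `P_sz = (1/N) sum_i t_sz[i] / T_scored`, in `[0, 1]`.
#'
#' @param times a [classify_seizure] result.
#' @return the seizure-time fraction.
#' @export
seizure_fraction <- function(times) {
  stopifnot(inherits(times, "seizure_times"))
  mean(times$t_sz) / times$T_scored
}

# Fast path: one simulation scored without materializing the trajectory.
# Identical (integer-exact) to classify_seizure(simulate_theta(...)).
psz_point <- function(network, params, seed, n_norm = NULL,
                      n_realizations = 1) {
  a <- sim_args(network, params, n_norm)
  theta_ref <- a$theta_s  # 0 stands in for the rest phase when I0 > 0
  w <- max(1L, as.integer(round(params$window / params$dt)))
  if (params$threshold != 0.5)
    stop("the streaming scorer supports the default threshold 0.5; ",
         "use classify_seizure() for other thresholds")
  # realization 1 uses the seed itself so the fast path matches
  # classify_seizure(simulate_theta(net, params, seed)) exactly
  seeds <- c(seed, if (n_realizations > 1)
    derive_seed(seed, seq_len(n_realizations - 1)))
  vals <- vapply(seeds, function(s) {
    cnt <- .cpp_theta_tsz(network$weights, params$I0, params$K, params$sigma,
                          params$dt, params$steps, a$theta_s, a$theta0,
                          a$n_norm, a$keys, as.numeric(s),
                          params$noise_scaling == "sqrt_dt", NULL,
                          theta_ref, w, params$burn_in)
    mean(cnt) / (params$steps - params$burn_in)
  }, numeric(1))
  mean(vals)
}

#' Dump phase trajectories to CSV
#'
#' Writes a simulated trajectory as a samples x nodes CSV (header = ROI
#' labels) with a JSON sidecar recording seed and parameters, so a run
#' can be archived and regenerated.
#'
#' @param sim a [theta_sim].
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(sim, path) {
  stopifnot(inherits(sim, "theta_sim"))
  d <- as.data.frame(t(sim$phases), check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- sim$params
  meta$theta0 <- NULL
  jsonlite::write_json(list(seed = sim$seed, params = unclass(meta),
                            units = "radians; rows are samples"),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
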