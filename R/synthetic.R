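# Synthetic data: planted networks, theta-band ROI signals and two-group
# cohorts.  These stand in for the non-deposited EEG cohort; the generator
# defaults define the study conditions of the test suite (see vignette).

#' Generate a planted network topology
#'
#' Symmetric, zero-diagonal networks with weights in `[0, 1]`.  Families:
#' `"uniform"` (Erdos-Renyi edges at `density`, weights uniform around
#' `base_weight`), `"modular"` (blocks with dense within- and sparse
#' between-module connectivity), `"star"` (hub connected to every leaf, no
#' leaf-leaf edges), `"custom"` (weights supplied).
#'
#' @param n node count (>= 2).
#' @param family topology family.
#' @param density edge probability (uniform family), in `(0, 1]`.
#' @param base_weight mean nonzero edge weight; weights are drawn uniformly
#'   on `[0.5, 1.5] * base_weight` (clipped to 1).
#' @param hub_weight star-family hub-leaf weight.
#' @param n_modules,p_in,p_out modular-family block count and within- /
#'   between-block edge probabilities.
#' @param weights custom adjacency matrix (family `"custom"`).
#' @param seed integer seed.
#' @param labels optional node labels.
#' @return a [weighted_network].
#' @export
#' @examples
#' make_topology(8, "star")$weights[1, ]
make_topology <- function(n, family = c("uniform", "modular", "star", "custom"),
                          density = 0.3, base_weight = 0.5, hub_weight = 0.8,
                          n_modules = 2, p_in = 0.6, p_out = 0.05,
                          weights = NULL, seed = 1, labels = NULL) {
  family <- match.arg(family)
  if (n < 2) stop("need at least 2 nodes")
  if (family != "custom" && (density <= 0 || density > 1))
    stop("density must be in (0, 1]")
  set.seed(seed)
  draw_w <- function(m) pmin(runif(m, 0.5 * base_weight, 1.5 * base_weight), 1)
  A <- matrix(0, n, n)
  if (family == "uniform") {
    up <- which(upper.tri(A))
    on <- runif(length(up)) < density
    A[up[on]] <- draw_w(sum(on))
  } else if (family == "modular") {
    mod <- rep_len(seq_len(n_modules), n)
    up <- which(upper.tri(A), arr.ind = TRUE)
    p <- ifelse(mod[up[, 1]] == mod[up[, 2]], p_in, p_out)
    on <- runif(nrow(up)) < p
    A[up[on, , drop = FALSE]] <- draw_w(sum(on))
    attr(A, "modules") <- mod
  } else if (family == "star") {
    A[1, 2:n] <- hub_weight
  } else {
    if (is.null(weights)) stop("family 'custom' needs a weights matrix")
    A <- as.matrix(weights)
  }
  mods <- attr(A, "modules")
  A <- A + t(A) - diag(diag(A))
  net <- weighted_network(A, labels)
  if (!is.null(mods)) net$modules <- mods
  net
}

#' Simulate coupled theta-band ROI signals on a planted network
#'
#' Emulates a resting-state regional recording (defaults: 40 ROIs, 20 s at
#' 1 kHz): each channel is a noisy phase oscillator with natural frequency
#' jittered inside the theta band, pairwise Kuramoto-type coupling
#' proportional to the planted edge weights, and a nonzero imposed phase
#' lag per edge (drawn from `lag_range`, random sign) so that genuinely
#' coupled pairs survive zero-lag rejection.  The observation is
#' `amp * cos(phase) + measurement noise`.
#'
#' @param net the planted [weighted_network].
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param osc_freq center oscillation frequency (Hz).
#' @param freq_jitter half-width of the uniform natural-frequency jitter
#'   (Hz).
#' @param coupling coupling gain in rad/s per unit edge weight; the
#'   default gives partial (not rigid) locking of planted pairs.
#' @param lag_range range of imposed phase-lag magnitudes (radians).
#' @param phase_noise phase-diffusion intensity (rad/sqrt(s)).
#' @param amp oscillation amplitude.
#' @param meas_noise standard deviation of additive white measurement
#'   noise.
#' @param seed integer seed.
#' @return a [roi_timeseries].
#' @export
simulate_roi_signals <- function(net, fs = 1000, duration = 20,
                                 osc_freq = 6, freq_jitter = 1,
                                 coupling = 5,
                                 lag_range = c(0.02, 0.1) * pi,
                                 phase_noise = 2, amp = 1,
                                 meas_noise = 0.2, seed = 1) {
  stopifnot(inherits(net, "weighted_network"))
  n_samp <- round(fs * duration)
  if (n_samp < 16 * 4) stop("duration * fs too short for the PLV pipeline")
  n <- net$N
  set.seed(seed)
  freqs <- runif(n, osc_freq - freq_jitter, osc_freq + freq_jitter)
  # antisymmetric lag matrix on planted edges
  D <- matrix(0, n, n)
  up <- which(upper.tri(D) & net$weights > 0)
  lag <- runif(length(up), lag_range[1], lag_range[2]) *
    sample(c(-1, 1), length(up), replace = TRUE)
  D[up] <- lag
  D <- D - t(D)
  C <- net$weights * exp(-1i * D)
  dt <- 1 / fs
  phi <- runif(n, 0, 2 * pi)
  noise <- matrix(rnorm(n * n_samp), n, n_samp)
  out <- matrix(0, n, n_samp)
  om <- 2 * pi * freqs
  sq <- phase_noise * sqrt(dt)
  for (t in seq_len(n_samp)) {
    out[, t] <- phi
    drift <- om + coupling * Im(Conj(exp(1i * phi)) * (C %*% exp(1i * phi)))
    phi <- phi + drift * dt + sq * noise[, t]
  }
  x <- amp * cos(out) + meas_noise * matrix(rnorm(n * n_samp), n, n_samp)
  roi_timeseries(x, fs, net$labels)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults mirror the reference cohort layout (26 vs 21 participants, 40
#' ROIs); the group effect is a multiplicative scaling `effect` of every
#' edge weight in group B, planting higher network-level seizure
#' propensity for `effect > 1`.
#'
#' @param n_group_a,n_group_b group sizes.
#' @param n_rois nodes per network.
#' @param effect multiplicative edge-weight scaling applied to group B
#'   (`>= 0`; weights are clipped at 1 with a warning).
#' @param topology topology family for [make_topology()].
#' @param base_weight,density base network parameters.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 26, n_group_b = 21, n_rois = 40,
                        effect = 1, topology = "uniform",
                        base_weight = 0.5, density = 0.3, seed = 1) {
  if (n_group_a < 1 || n_group_b < 1) stop("group sizes must be >= 1")
  if (effect < 0) stop("effect must be >= 0")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 n_rois = n_rois, effect = effect, topology = topology,
                 base_weight = base_weight, density = density, seed = seed),
            class = "cohort_spec")
}

#' Generate a two-group cohort of synthetic networks
#'
#' Group A networks are drawn from the base distribution; group B networks
#' are drawn the same way and then all weights are scaled by
#' `spec$effect`.  Per-subject seeds are recorded so regeneration is
#' bit-identical.
#'
#' @param spec a [cohort_spec].
#' @return an object of class `group_dataset`: list of
#'   [weighted_network]s, a factor `labels` with levels `A`/`B`, and
#'   provenance (spec + per-subject seeds).
#' @export
#' @examples
#' ds <- make_group_dataset(cohort_spec(3, 2, n_rois = 6, effect = 1.3))
#' table(ds$labels)
make_group_dataset <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_group_a + spec$n_group_b
  seeds <- derive_seed(spec$seed, seq_len(n_tot))
  labels <- factor(rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)))
  clipped <- FALSE
  nets <- lapply(seq_len(n_tot), function(s) {
    net <- make_topology(spec$n_rois, spec$topology,
                         density = spec$density,
                         base_weight = spec$base_weight, seed = seeds[s])
    if (labels[s] == "B" && spec$effect != 1) {
      w <- net$weights * spec$effect
      if (any(w > 1)) { clipped <<- TRUE; w <- pmin(w, 1) }
      net <- weighted_network(w, net$labels)
    }
    net
  })
  if (clipped)
    warning("effect scaling pushed some weights above 1; clipped to 1")
  names(nets) <- sprintf("subj%02d", seq_len(n_tot))
  structure(list(networks = nets, labels = labels,
                 provenance = list(spec = unclass(spec),
                                   subject_seeds = seeds)),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d + %d subjects, %d ROIs, effect %g\n",
              sum(x$labels == "A"), sum(x$labels == "B"),
              x$networks[[1]]$N, x$provenance$spec$effect))
  invisible(x)
}

#' BNI for every subject of a cohort
#'
#' Convenience sweep used by the group-level analyses: fits
#' [ictogenicity()] to each network of a [make_group_dataset()] cohort.
#'
#' @param dataset a `group_dataset`.
#' @param grid a [bni_grid].
#' @param params a [model_params].
#' @param seed master seed; per-subject seeds are derived from it.
#' @param n_realizations realizations per grid point.
#' @return data.frame with `subject`, `group`, `bni`, `bni_normalized`.
#' @export
cohort_bni <- function(dataset, grid = bni_grid(), params = model_params(0),
                       seed = 1, n_realizations = 1) {
  stopifnot(inherits(dataset, "group_dataset"))
  res <- lapply(seq_along(dataset$networks), function(s) {
    b <- bni_from_curve(psz_curve(dataset$networks[[s]], grid, params,
                                  seed = derive_seed(seed, s),
                                  n_realizations = n_realizations))
    data.frame(subject = names(dataset$networks)[s],
               group = as.character(dataset$labels[s]),
               bni = b$bni, bni_normalized = b$normalized)
  })
  do.call(rbind, res)
}
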