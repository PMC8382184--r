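#' Multichannel ROI time-series container
#'
#' @param data numeric matrix of regional time courses, channels x samples
#'   (a samples x channels matrix is accepted and transposed when `labels`
#'   match its columns).
#' @param fs sampling rate in Hz.
#' @param labels channel (ROI) names; defaults to rownames or `ROI1...`.
#' @return an object of class `roi_timeseries` with `data` (channels x
#'   samples), `fs` and `labels`.
#' @export
roi_timeseries <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (any(!is.finite(data))) stop("non-finite samples in time series")
  labels <- labels %||% rownames(data) %||% paste0("ROI", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("label count does not match channel count")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read ROI time series from CSV (+ JSON sidecar)
#'
#' The CSV holds samples as rows and channels as columns with a label
#' header; the sampling rate comes from `fs` or from a JSON sidecar
#' `<path>.json` with an `fs` field.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz; overrides the sidecar.
#' @return a [roi_timeseries].
#' @export
read_roi_timeseries <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(fs)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("no sampling rate: supply fs or a sidecar ", side)
    fs <- jsonlite::read_json(side)$fs
  }
  d <- utils::read.csv(path, check.names = FALSE)
  roi_timeseries(t(as.matrix(d)), fs = as.numeric(fs), labels = colnames(d))
}

#' Write ROI time series to CSV with a JSON sidecar
#'
#' @param ts a [roi_timeseries].
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  d <- as.data.frame(t(ts$data), check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(fs = ts$fs, units = "arbitrary"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Zero-phase theta-band filter
#'
#' Band-passes every channel into the theta band (default 4-8 Hz) with a
#' Butterworth design applied forward-backward (`signal::filtfilt`), so
#' the filter adds no phase distortion.
#'
#' @param ts a [roi_timeseries] with `fs` comfortably above twice the upper
#'   band edge.
#' @param f_low,f_high passband edges in Hz.
#' @param order Butterworth design order (default 4).
#' @return the filtered [roi_timeseries].
#' @export
theta_bandpass <- function(ts, f_low = 4, f_high = 8, order = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ts$fs <= 2 * f_high)
    stop("sampling rate ", ts$fs, " Hz too low for a ", f_low, "-", f_high,
         " Hz passband")
  bf <- signal::butter(order, c(f_low, f_high) / (ts$fs / 2), type = "pass")
  out <- t(apply(ts$data, 1, function(x) signal::filtfilt(bf, x)))
  roi_timeseries(out, ts$fs, ts$labels)
}

#' Instantaneous phase via the analytic signal
#'
#' Hilbert-transform phase of each (band-limited) channel, computed with
#' the FFT analytic-signal construction.
#'
#' @param ts a band-limited [roi_timeseries].
#' @return matrix of phases (radians, wrapped), channels x samples.
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ncol(ts$data)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  ph <- t(apply(ts$data, 1, function(x) {
    x <- x - mean(x)
    if (sd(x) == 0)
      stop("degenerate (constant) channel: instantaneous phase undefined")
    Arg(fft(fft(x) * h, inverse = TRUE))
  }))
  rownames(ph) <- ts$labels
  ph
}

#' Phase-locking value of one channel pair
#'
#' Modulus of the time-averaged unit phasor of the phase difference; the
#' circular mean phase difference is the argument of the same phasor.
#'
#' @param phi_a,phi_b phase series in radians, equal length >= 2.
#' @return list with `plv` in `[0, 1]` and `mean_dphi` in `(-pi, pi]`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' plv_pair(2 * pi * 6 * t, 2 * pi * 6 * t + pi / 2)
plv_pair <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b)) stop("phase series length mismatch")
  if (length(phi_a) < 2) stop("need at least 2 samples")
  m <- mean(exp(1i * (phi_a - phi_b)))
  list(plv = Mod(m), mean_dphi = Arg(m))
}

# all-pairs PLV / circular mean phase difference from a phase matrix
plv_matrix <- function(phases) {
  e <- exp(1i * phases)
  m <- (e %*% Conj(t(e))) / ncol(phases)
  list(plv = Mod(m), mean_dphi = Arg(m))
}

#' Iterative amplitude adjusted Fourier transform surrogate
#'
#' Random surrogate of one channel preserving its amplitude distribution
#' exactly and its amplitude spectrum approximately: iterates a spectral
#' substitution step and a rank remap onto the sorted original values
#' until the relative spectral error converges or `n_iter` is reached.
#'
#' @param x numeric series, length >= 16, non-constant.
#' @param n_iter maximum iterations (default 100).
#' @param tol relative L2 error of the amplitude spectrum at which to stop.
#' @param seed integer seed.
#' @return surrogate series with attributes `iterations` and `spec_error`.
#' @export
iaaft_surrogate <- function(x, n_iter = 100, tol = 1e-4, seed = 1) {
  x <- as.numeric(x)
  if (length(x) < 16) stop("series too short for IAAFT (need >= 16 samples)")
  if (sd(x) == 0) stop("constant input has no meaningful surrogate")
  .cpp_iaaft(x, as.integer(n_iter), tol, as.numeric(seed))
}

#' Surrogate-significance mask for PLV edges
#'
#' Builds, per edge, a null PLV distribution from `n_surr` pairs of IAAFT
#' surrogates (both channels independently surrogated in each pair, then
#' passed through the same band-pass / phase / trim pipeline) and retains
#' an edge only if its observed PLV exceeds the `(1 - alpha)` point of its
#' null — with 99 surrogates and `alpha = 0.05`, strictly greater than the
#' 95th of the 99 sorted null values.
#'
#' Surrogates are drawn from the band-passed series (IAAFT preserves the
#' amplitude spectrum, so surrogates stay band-limited) and their phases
#' are taken directly from the analytic signal; this avoids re-filtering
#' every surrogate without changing the null being sampled.
#'
#' @param ts the band-passed [roi_timeseries] (as produced by
#'   [theta_bandpass()]).
#' @param plv observed PLV matrix (from the same pipeline settings).
#' @param n_surr surrogate pairs per edge (>= 19 for alpha 0.05).
#' @param alpha one-sided significance level.
#' @param seed integer seed.
#' @param trim seconds trimmed at each end before PLV, see [build_network()].
#' @return logical retain-mask matrix (diagonal `FALSE`).
#' @export
surrogate_mask <- function(ts, plv, n_surr = 99, alpha = 0.05, seed = 1,
                           trim = 1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (n_surr < ceiling(1 / alpha) - 1)
    stop("n_surr too small for alpha = ", alpha)
  n <- nrow(ts$data)
  k_idx <- ceiling((1 - alpha) * n_surr)
  null_vals <- array(NA_real_, c(n_surr, n, n))
  for (k in seq_len(n_surr)) {
    surr <- t(vapply(seq_len(n), function(ch)
      as.numeric(iaaft_surrogate(ts$data[ch, ],
                                 seed = derive_seed(seed, (k - 1) * n + ch))),
      numeric(ncol(ts$data))))
    sts <- roi_timeseries(surr, ts$fs, ts$labels)
    ph <- trim_phases(instantaneous_phase(sts), ts$fs, trim)
    null_vals[k, , ] <- plv_matrix(ph)$plv
  }
  thr <- apply(null_vals, c(2, 3), function(v) sort(v)[k_idx])
  mask <- plv > thr
  diag(mask) <- FALSE
  dimnames(mask) <- list(ts$labels, ts$labels)
  mask
}

# drop `trim` seconds at each end before computing PLV, guarding both
# filter and Hilbert boundary artifacts
trim_phases <- function(phases, fs, trim) {
  n <- ncol(phases)
  k <- round(trim * fs)
  if (2 * k >= n - 1) stop("trim leaves no samples")
  if (k > 0) phases[, (k + 1):(n - k), drop = FALSE] else phases
}

#' Zero-phase-lag rejection mask
#'
#' Edges whose circular mean phase difference is smaller in magnitude than
#' the one-sample phase resolution at the lower band edge,
#' `2 pi f_low / fs` (0.008 pi radians at 4 Hz and 1 kHz), are rejected as
#' likely source-leakage artifacts.  The comparison is strict: a lag
#' exactly at the threshold is retained.
#'
#' @param mean_dphi matrix of circular mean phase differences (radians).
#' @param fs sampling rate in Hz.
#' @param f_low lower band edge in Hz.
#' @return logical retain-mask matrix (diagonal `FALSE`).
#' @export
zero_lag_mask <- function(mean_dphi, fs, f_low = 4) {
  stopifnot(fs > 0)
  d <- ((mean_dphi + pi) %% (2 * pi)) - pi
  mask <- abs(d) >= zero_lag_threshold(fs, f_low)
  diag(mask) <- FALSE
  mask
}

#' One-sample phase resolution used for zero-lag rejection
#'
#' @inheritParams zero_lag_mask
#' @return threshold in radians, `2 pi f_low / fs`.
#' @export
#' @examples
#' zero_lag_threshold(1000) / pi  # 0.008
zero_lag_threshold <- function(fs, f_low = 4) 2 * pi * f_low / fs

#' Remove edges with an indirect shortest path
#'
#' With edge length `1 / weight`, computes all-pairs shortest paths
#' (Dijkstra) and removes every edge whose direct length strictly exceeds
#' the shortest path between its endpoints; ties keep the edge.  The
#' operation is idempotent: every surviving edge is itself a shortest
#' path, which removals elsewhere can only confirm.
#'
#' @param net a [weighted_network] with non-negative weights.
#' @return the pruned `weighted_network`.
#' @export
indirect_path_filter <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  if (net$N < 3 || all(w == 0)) return(net)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  keep <- w
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    direct <- 1 / w[i, j]
    if (d[i, j] < direct * (1 - 1e-12)) keep[i, j] <- keep[j, i] <- 0
  }
  weighted_network(keep, net$labels)
}

#' Build a surrogate-corrected theta-band PLV network
#'
#' The full functional-network pipeline: zero-phase band-pass into the
#' theta band, Hilbert instantaneous phases, edge-trimmed PLV, IAAFT
#' surrogate significance mask, zero-phase-lag rejection, and
#' indirect-shortest-path pruning.  Masks are recorded per stage and only
#' remove edges (the pipeline is monotone).
#'
#' @param ts a [roi_timeseries] of raw regional time courses.
#' @param f_low,f_high theta-band edges in Hz.
#' @param order Butterworth design order.
#' @param trim seconds discarded at each end before PLV (Hilbert/filter
#'   boundary guard).
#' @param n_surr IAAFT surrogate pairs per edge.
#' @param alpha one-sided surrogate significance level.
#' @param seed integer seed for the surrogates.
#' @return an object of class `functional_network`: `plv`, `mean_dphi`,
#'   per-stage logical `masks` (`surrogate`, `zero_lag`, `path`), the
#'   masked [weighted_network] `final`, and provenance settings.
#' @export
build_network <- function(ts, f_low = 4, f_high = 8, order = 4, trim = 1,
                          n_surr = 99, alpha = 0.05, seed = 1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  filt <- theta_bandpass(ts, f_low, f_high, order)
  ph <- trim_phases(instantaneous_phase(filt), ts$fs, trim)
  pm <- plv_matrix(ph)
  m_surr <- surrogate_mask(filt, pm$plv, n_surr = n_surr, alpha = alpha,
                           seed = seed, trim = trim)
  m_lag <- zero_lag_mask(pm$mean_dphi, ts$fs, f_low)
  w <- pm$plv
  diag(w) <- 0
  w[!(m_surr & m_lag)] <- 0
  pruned <- indirect_path_filter(weighted_network(w, ts$labels))
  structure(list(plv = pm$plv, mean_dphi = pm$mean_dphi,
                 masks = list(surrogate = m_surr, zero_lag = m_lag,
                              path = pruned$weights > 0),
                 final = pruned,
                 settings = list(f_low = f_low, f_high = f_high,
                                 order = order, trim = trim,
                                 n_surr = n_surr, alpha = alpha,
                                 seed = seed, edge_length = "1/PLV")),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  n <- x$final$N
  tot <- n * (n - 1) / 2
  surv <- function(m) sum(m[upper.tri(m)])
  cat(sprintf("functional network: %d ROIs, %d candidate edges\n", n, tot))
  cat(sprintf("  surrogate mask kept %d, zero-lag kept %d, final %d edges\n",
              surv(x$masks$surrogate), surv(x$masks$surrogate & x$masks$zero_lag),
              surv(x$final$weights > 0)))
  invisible(x)
}
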