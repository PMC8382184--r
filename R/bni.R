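#' Excitability grid for the BNI sweep
#'
#' Ordered grid of `I0` values over which the seizure-time fraction is
#' simulated.  Defaults follow the standard sweep: 13 evenly spaced points
#' on `[-1.7, -0.5]` (step 0.1).
#'
#' @param lambda1,lambda2 lower and upper excitability bounds
#'   (`lambda1 < lambda2`).
#' @param n_points number of evenly spaced grid points (endpoints
#'   included), or supply `points` directly.
#' @param points optional strictly increasing vector of `I0` values within
#'   `[lambda1, lambda2]` including the endpoints.
#' @return an object of class `bni_grid`.
#' @export
#' @examples
#' bni_grid()$points
bni_grid <- function(lambda1 = -1.7, lambda2 = -0.5, n_points = 13,
                     points = NULL) {
  if (!(lambda1 < lambda2)) stop("need lambda1 < lambda2")
  if (is.null(points)) {
    if (n_points < 2) stop("need at least 2 grid points")
    points <- seq(lambda1, lambda2, length.out = n_points)
  } else {
    if (any(diff(points) <= 0)) stop("grid points must be strictly increasing")
    if (points[1] != lambda1 || points[length(points)] != lambda2 ||
        any(points < lambda1 | points > lambda2))
      stop("grid points must span [lambda1, lambda2] with endpoints included")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, points = points),
            class = "bni_grid")
}

#' Seizure-likelihood curve over an excitability grid
#'
#' Runs one scored simulation (or an average of `n_realizations`) of the
#' stochastic theta model per grid point and records the seizure-time
#' fraction `P_sz(I0)`.  Per-point seeds are derived deterministically from
#' the master seed, so passing the same `point_seeds` to repeated calls
#' (e.g. before and after node removal) pairs the noise realizations.
#'
#' @param network a [weighted_network].
#' @param grid a [bni_grid].
#' @param params a [model_params]; its `I0` is replaced point by point.
#' @param seed master seed.
#' @param point_seeds optional vector of per-point seeds (length of the
#'   grid) overriding the derived ones.
#' @param n_realizations noise realizations averaged per grid point
#'   (default 1).
#' @param n_norm coupling normalization divisor (default: network size).
#' @return an object of class `psz_curve` with `I0`, `psz`, `seeds` and the
#'   generating arguments.
#' @export
psz_curve <- function(network, grid = bni_grid(), params = model_params(0),
                      seed = 1, point_seeds = NULL, n_realizations = 1,
                      n_norm = NULL) {
  stopifnot(inherits(grid, "bni_grid"))
  pts <- grid$points
  seeds <- point_seeds %||% derive_seed(seed, seq_along(pts))
  if (length(seeds) != length(pts)) stop("need one seed per grid point")
  psz <- vapply(seq_along(pts), function(k) {
    pk <- params; pk$I0 <- pts[k]
    pk$theta_s <- if (pts[k] <= 0) stable_phase(pts[k]) else NA_real_
    psz_point(network, pk, seeds[k], n_norm = n_norm,
              n_realizations = n_realizations)
  }, numeric(1))
  structure(list(I0 = pts, psz = psz, grid = grid, seeds = seeds,
                 params = params, n_realizations = n_realizations),
            class = "psz_curve")
}

#' @export
print.psz_curve <- function(x, ...) {
  cat(sprintf("P_sz curve on [%g, %g], %d points: %s\n",
              x$grid$lambda1, x$grid$lambda2, length(x$I0),
              paste(sprintf("%.2f", x$psz), collapse = " ")))
  invisible(x)
}

#' @export
plot.psz_curve <- function(x, ...) {
  plot(x$I0, x$psz, type = "b", pch = 19, ylim = c(0, 1),
       xlab = expression(I[0]), ylab = expression(P[sz]), ...)
  invisible(x)
}

#' Brain network ictogenicity from a seizure-likelihood curve
#'
#' BNI is the area under `P_sz(I0)` over `[lambda1, lambda2]`, computed by
#' trapezoidal quadrature on the grid; the normalized variant divides by
#' the interval width so it lies in `[0, 1]`.
#'
#' @param curve a [psz_curve] (at least 2 points).
#' @return an object of class `bni` with `bni`, `normalized` and the curve.
#' @export
bni_from_curve <- function(curve) {
  stopifnot(inherits(curve, "psz_curve"))
  x <- curve$I0; y <- curve$psz
  if (length(x) < 2) stop("need at least 2 grid points for quadrature")
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  width <- curve$grid$lambda2 - curve$grid$lambda1
  structure(list(bni = area, normalized = area / width, curve = curve),
            class = "bni")
}

#' @export
print.bni <- function(x, ...) {
  cat(sprintf("BNI = %.4f (normalized %.4f over [%g, %g])\n",
              x$bni, x$normalized, x$curve$grid$lambda1, x$curve$grid$lambda2))
  invisible(x)
}

#' Node ictogenicity by virtual node removal
#'
#' For each ROI, removes the node and all its edges, recomputes BNI on the
#' reduced network with the same per-grid-point seeds (common random
#' numbers, so removal contrasts are paired), and scores
#' `NI = (BNI_pre - BNI_post) / BNI_pre`.  `NI = 1` marks a node entirely
#' responsible for simulated seizures; negative NI marks a node whose
#' removal increases seizure propensity.  `nNI` normalizes NI to unit sum.
#'
#' @inheritParams psz_curve
#' @param n_norm `"current"` renormalizes the `K/N` coupling by the reduced
#'   size `N - 1` after removal (the literal model definition);
#'   `"original"` keeps the pre-removal `N`.
#' @return an object of class `ni_profile`: named `ni` and `nni` vectors,
#'   `bni_pre` (a `bni` object) and per-node `bni_post`.
#' @export
node_ictogenicity <- function(network, grid = bni_grid(),
                              params = model_params(0), seed = 1,
                              n_realizations = 1,
                              n_norm = c("current", "original")) {
  n_norm <- match.arg(n_norm)
  if (network$N < 2) stop("node removal needs at least 2 nodes")
  seeds <- derive_seed(seed, seq_along(grid$points))
  pre <- bni_from_curve(psz_curve(network, grid, params, point_seeds = seeds,
                                  n_realizations = n_realizations))
  if (pre$bni <= 0)
    stop("BNI_pre = 0: the network never seizes on this grid, NI undefined")
  post <- vapply(seq_len(network$N), function(i) {
    red <- remove_node(network, i)
    bni_from_curve(psz_curve(red, grid, params, point_seeds = seeds,
                             n_realizations = n_realizations,
                             n_norm = if (n_norm == "original") network$N))$bni
  }, numeric(1))
  ni <- (pre$bni - post) / pre$bni
  names(ni) <- names(post) <- network$labels
  nni <- if (sum(ni) != 0) normalise_ni(ni) else {
    warning("NI values sum to zero; nNI undefined for this network")
    rep(NA_real_, length(ni))
  }
  structure(list(ni = ni, nni = nni, bni_pre = pre, bni_post = post,
                 seeds = seeds, n_norm = n_norm),
            class = "ni_profile")
}

#' @export
print.ni_profile <- function(x, ...) {
  cat(sprintf("node ictogenicity: %d ROIs, BNI_pre=%.4f\n",
              length(x$ni), x$bni_pre$bni))
  top <- sort(x$ni, decreasing = TRUE)[seq_len(min(5, length(x$ni)))]
  cat("  highest NI:", paste(sprintf("%s=%.3f", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Normalise node-ictogenicity values to unit sum
#'
#' `nNI[i] = NI[i] / sum(NI)`; preserves the relative importance of each
#' ROI while removing between-subject differences in absolute NI scale.
#'
#' @param ni vector of NI values with nonzero sum.
#' @return vector summing to 1 exactly.
#' @export
#' @examples
#' normalise_ni(c(2, 3, 5))
normalise_ni <- function(ni) {
  s <- sum(ni)
  if (s == 0) stop("cannot normalise: NI values sum to zero")
  ni / s
}

#' Fit brain network ictogenicity to a functional network
#'
#' The main entry point of the package: sweeps the excitability grid,
#' estimates the seizure-likelihood curve `P_sz(I0)` of the stochastic
#' theta model on the supplied network, integrates it into the BNI score,
#' and (optionally) attributes it to nodes by virtual node removal.
#'
#' @inheritParams psz_curve
#' @param nodes if `TRUE`, also compute the per-node NI/nNI profile
#'   (`N + 1` sweeps instead of one).
#' @param n_norm coupling renormalization after node removal, see
#'   [node_ictogenicity()].
#' @return an object of class `ictogenicity` with components `bni` (a
#'   `bni` object), `curve`, and `ni` (a `ni_profile` or `NULL`); methods
#'   [print()], [summary()], [coef()] and [plot()] are provided.  `coef()`
#'   returns the BNI (and NI values when present).
#' @export
#' @examples
#' net <- make_topology(6, "uniform", density = 0.5, seed = 2)
#' fit <- ictogenicity(net, params = model_params(0, steps = 2e4), seed = 3)
#' coef(fit)
ictogenicity <- function(network, grid = bni_grid(),
                         params = model_params(0), seed = 1,
                         nodes = FALSE, n_realizations = 1,
                         n_norm = c("current", "original")) {
  n_norm <- match.arg(n_norm)
  cl <- match.call()
  if (nodes) {
    ni <- node_ictogenicity(network, grid, params, seed = seed,
                            n_realizations = n_realizations, n_norm = n_norm)
    b <- ni$bni_pre
  } else {
    ni <- NULL
    b <- bni_from_curve(psz_curve(network, grid, params, seed = seed,
                                  n_realizations = n_realizations))
  }
  structure(list(bni = b, curve = b$curve, ni = ni, network = network,
                 grid = grid, params = params, seed = seed, call = cl),
            class = "ictogenicity")
}

#' @export
print.ictogenicity <- function(x, ...) {
  cat("Brain network ictogenicity fit\n")
  cat(sprintf("  network: %d ROIs; grid: %d points on [%g, %g]; seed %s\n",
              x$network$N, length(x$grid$points), x$grid$lambda1,
              x$grid$lambda2, format(x$seed)))
  print(x$bni)
  if (!is.null(x$ni)) print(x$ni)
  invisible(x)
}

#' @export
summary.ictogenicity <- function(object, ...) {
  s <- list(bni = object$bni$bni, normalized = object$bni$normalized,
            psz = setNames(object$curve$psz, format(object$curve$I0)),
            ni = object$ni$ni, nni = object$ni$nni)
  class(s) <- "summary.ictogenicity"
  s
}

#' @export
print.summary.ictogenicity <- function(x, ...) {
  cat(sprintf("BNI %.4f (normalized %.4f)\nP_sz by I0:\n", x$bni, x$normalized))
  print(round(x$psz, 3))
  if (!is.null(x$ni)) {
    cat("NI / nNI:\n")
    print(round(rbind(NI = x$ni, nNI = x$nni), 3))
  }
  invisible(x)
}

#' @export
coef.ictogenicity <- function(object, ...) {
  if (is.null(object$ni)) c(BNI = object$bni$bni)
  else c(BNI = object$bni$bni, setNames(object$ni$ni,
                                        paste0("NI.", names(object$ni$ni))))
}

#' @export
plot.ictogenicity <- function(x, which = c("curve", "ni"), ...) {
  which <- match.arg(which)
  if (which == "curve") {
    plot(x$curve, main = sprintf("BNI = %.3f", x$bni$bni), ...)
  } else {
    if (is.null(x$ni)) stop("fit has no node-ictogenicity profile")
    barplot(x$ni$ni, las = 2, ylab = "NI", ...)
    abline(h = 0)
  }
  invisible(x)
}
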