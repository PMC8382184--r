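#' Weighted undirected network over regions of interest
#'
#' Container for the symmetric, zero-diagonal, non-negative adjacency matrix
#' that the seizure-transition model runs on.  Entry `weights[j, i]` carries
#' the influence of ROI `j` on ROI `i`; symmetry makes the convention moot
#' but it is fixed here.  Weights derived from phase-locking values lie in
#' `[0, 1]`.
#'
#' @param weights square numeric matrix of non-negative coupling strengths.
#'   Must be symmetric (within `tol`); the diagonal is zeroed.
#' @param labels character vector of unique ROI names.  Defaults to existing
#'   dimnames or `ROI1 ... ROIn`.
#' @param tol tolerance for the symmetry check.
#' @return an object of class `weighted_network` with elements `weights`
#'   (labelled matrix), `labels` and `N`.
#' @export
#' @examples
#' w <- matrix(c(0, .5, .5, 0), 2)
#' weighted_network(w, c("L", "R"))
weighted_network <- function(weights, labels = NULL, tol = 1e-12) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("adjacency matrix must be square, got ", nrow(weights), "x", ncol(weights))
  n <- nrow(weights)
  if (n < 1) stop("network must have at least one node")
  if (any(!is.finite(weights))) stop("non-finite weights in adjacency matrix")
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop("negative weight at [", bad[1], ",", bad[2], "]")
  }
  asym <- abs(weights - t(weights))
  if (any(asym > tol)) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric adjacency: entry [%d,%d]=%g vs [%d,%d]=%g",
                 bad[1], bad[2], weights[bad[1], bad[2]],
                 bad[2], bad[1], weights[bad[2], bad[1]]))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights) %||% paste0("ROI", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("need ", n, " labels, got ", length(labels))
  if (anyDuplicated(labels)) stop("ROI labels must be unique")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, N = n),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted network: %d ROIs, %d edges, mean nonzero weight %.3f\n",
              x$N, nz, if (nz) mean(x$weights[upper.tri(x$weights) & x$weights > 0]) else NA))
  invisible(x)
}

#' Remove one node (and all its edges) from a network
#'
#' @param net a [weighted_network].
#' @param node node index or label.
#' @return the reduced `weighted_network`.
#' @export
remove_node <- function(net, node) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.character(node)) node <- match(node, net$labels)
  if (is.na(node) || node < 1 || node > net$N) stop("invalid node")
  if (net$N < 2) stop("cannot remove the only node")
  weighted_network(net$weights[-node, -node, drop = FALSE], net$labels[-node])
}

#' Read a network adjacency matrix from CSV
#'
#' Expects the plain-text interchange format used throughout the package:
#' a header row of ROI labels followed by N numeric rows.  Symmetry is
#' enforced to `tol` and the diagonal zeroed.
#'
#' @param path CSV file path.
#' @param tol symmetry tolerance.
#' @return a [weighted_network].
#' @export
load_network <- function(path, tol = 1e-12) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  weighted_network(as.matrix(d), labels = colnames(d), tol = tol)
}

#' Write a network adjacency matrix to CSV
#'
#' @param net a [weighted_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  utils::write.csv(as.data.frame(net$weights, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
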