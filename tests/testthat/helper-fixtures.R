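# Shared fixture builders.  All simulations in the test suite run at
# scaled-down sizes (see the methods vignette): steps = 1e4-1e5 instead of
# the production 4e6.

quick_params <- function(I0, steps = 2e4, ...) {
  model_params(I0, steps = steps, ...)
}

rand_weighted_net <- function(n, density = 0.5, seed = 1) {
  make_topology(n, "uniform", density = density, seed = seed)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(2 * pi * ((d < -pi) - (d > pi))))
}

# exhaustive simple-path oracle for the indirect-path filter (n <= 6)
brute_force_path_filter <- function(w) {
  n <- nrow(w)
  shortest <- function(i, j) {
    best <- Inf
    visit <- function(node, dist, seen) {
      if (dist >= best) return()
      if (node == j) { best <<- dist; return() }
      for (k in seq_len(n)) {
        if (!seen[k] && w[node, k] > 0)
          visit(k, dist + 1 / w[node, k], `[<-`(seen, k, TRUE))
      }
    }
    visit(i, 0, `[<-`(rep(FALSE, n), i, TRUE))
    best
  }
  keep <- w
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      d <- shortest(i, j)
      if (d < (1 / w[i, j]) * (1 - 1e-12)) keep[i, j] <- keep[j, i] <- 0
    }
  }
  keep
}

# exact two-sided Mann-Whitney p by enumeration of all rank arrangements
exact_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(s) sum(seq_len(n1 + n2)[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
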