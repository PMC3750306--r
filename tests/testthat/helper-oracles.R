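# Independent oracles used to cross-check the analytical machinery.

# Brute-force steady states of the clamped-Bax caspase pair: dense-grid
# sign changes of the reduced residual, refined by uniroot. Independent
# of the cubic/polyroot path used by the package.
brute_force_caspase_roots <- function(bax, params, n_grid = 200001) {
  S <- params$s3 / params$d3
  g <- function(C) (params$a1 * bax + params$a2 * C^2) * (S - C) -
    params$d3 * C
  grid <- seq(0, S, length.out = n_grid)
  gv <- g(grid)
  roots <- grid[gv == 0]
  idx <- which(gv[-n_grid] * gv[-1] < 0)
  for (i in idx) {
    roots <- c(roots, uniroot(g, c(grid[i], grid[i + 1]),
                              tol = 1e-13 * S)$root)
  }
  sort(roots)
}

# Stability of a caspase steady state from the full 2x2 Jacobian of the
# (Procasp, Casp) pair at clamped Bax.
jacobian_stable <- function(casp, bax, params) {
  S <- params$s3 / params$d3
  pro <- S - casp
  act <- params$a1 * bax + params$a2 * casp^2
  J <- matrix(c(-act - params$d3, -2 * params$a2 * casp * pro,
                act, 2 * params$a2 * casp * pro - params$d3),
              2, 2, byrow = TRUE)
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

# Fold location by bisection on the brute-force root count (3 below the
# fold, 1 above); independent of the double-root reduction.
brute_force_bax_bif <- function(params, lo = 0, hi = 2e4, tol = 1e-4) {
  n <- function(b) length(brute_force_caspase_roots(b, params))
  stopifnot(n(lo) == 3, n(hi) == 1)
  while (hi - lo > tol * hi) {
    mid <- (lo + hi) / 2
    if (n(mid) == 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# relative difference helper
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# conservation drift of a trajectory relative to its pool configuration
max_pool_drift <- function(traj) {
  pools <- traj$pools
  ref <- c(pools$BclxL_tot, pools$Bad_tot, pools$Scaffold_tot)
  worst <- 0
  for (i in seq_len(nrow(traj$states))) {
    got <- conserved_pools(traj$states[i, ])
    worst <- max(worst, abs(got - ref) / ref)
  }
  worst
}
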