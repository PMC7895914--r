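# shared fixtures and independent oracles

unif <- signal_uniform()

# quadrature oracle for the partial expectation, independent of the
# closed forms used inside the package
quad_pe <- function(dens, a) {
  stats::integrate(function(p) p * dens(p), a, 1, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

# quadrature oracle for the coarsened posteriors
quad_coarsen <- function(dens, cdf, T) {
  E <- quad_pe(dens, 0)
  qH <- 1 - cdf(T)
  pH <- quad_pe(dens, T) / qH
  pL <- (E - quad_pe(dens, T)) / cdf(T)
  list(q_H = qH, p_H = pH, p_L = pL, E = E, gap = pH - pL - E)
}

default_cfg <- function(M, dist = unif) game_config(M, dist)

random_beta_dists <- function(n, lo = 0.3, hi = 5) {
  lapply(seq_len(n), function(i)
    signal_beta(stats::runif(1, lo, hi), stats::runif(1, lo, hi)))
}

# continuation-value vector (length k) carrying v^{k-1}, v^{k-2} for use
# with deviation_value()
cont_values <- function(k, v1, v2 = 0) {
  vals <- numeric(k)
  if (k > 1) vals[k - 1] <- v1
  if (k > 2) vals[k - 2] <- v2
  vals
}

# brute-force symmetric stage-equilibrium search on a threshold grid:
# returns the grid point minimizing the maximal one-stage deviation gain
brute_stage_equilibrium <- function(k, v1, v2, cfg, n_grid = 101L) {
  dg <- seq(0, cfg$dist$support_max - 1e-9, length.out = n_grid)
  vals <- cont_values(k, v1, v2)
  maxgain <- vapply(dg, function(d) {
    base <- deviation_value(k, d, d, vals, cfg)
    max(deviation_value(k, dg, d, vals, cfg)) - base
  }, numeric(1))
  dg[which.min(maxgain)]
}
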