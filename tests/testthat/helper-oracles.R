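# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the grid scan never calls the package optimiser and
# the monodisperse parameter builder works from first principles.

# brute-force grid scan of the truncated-fit SSE objective
grid_fit_mu <- function(support, obs, grid = seq(0.001, 3, by = 1e-4)) {
  sses <- vapply(grid, function(mu) {
    sum((obs - truncated_occupancy(support, mu))^2)
  }, numeric(1))
  grid[which.min(sses)]
}

# histogram generated exactly from the zero-truncated model, scaled to n
ztp_histogram <- function(mu, n = 1e4, kmax = 12) {
  occupancy_histogram(1:kmax, truncated_occupancy(1:kmax, mu) * n)
}

# monodisperse simulation parameters achieving rate mu_true with about
# n_bc bead-containing droplets: n_beads = mu * n_droplets at fixed
# concentration mu / v_pl
mono_params <- function(mu_true, n_bc = 1e4, v_pl = 3.6, seed = 1) {
  n_droplets <- ceiling(n_bc / (-expm1(-mu_true)) * 1.05)
  simulation_params(n_beads = max(1, round(mu_true * n_droplets)),
                    aqueous_volume_ul = n_droplets * v_pl / 1e6,
                    log_mean = log(v_pl), log_sd = 0,
                    seed = seed)
}

# compare an empirical occupancy histogram against model probabilities,
# per k, within z_max standard errors, for classes expected to hold at
# least min_expected droplets
expect_occupancy_match <- function(bead_counts, model_prob_fn, n_total,
                                   z_max = 3, min_expected = 5) {
  kmax <- max(bead_counts)
  emp <- tabulate(bead_counts, nbins = kmax) / n_total
  p <- model_prob_fn(1:kmax)
  se <- sqrt(p * (1 - p) / n_total)
  keep <- p * n_total >= min_expected
  expect_true(any(keep))
  expect_lt(max(abs(emp[keep] - p[keep]) / se[keep]), z_max)
}
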