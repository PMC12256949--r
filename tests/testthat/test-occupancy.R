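test_that("the occupancy pmf matches reference values and the dpois oracle", {
  # closed-form anchors
  expect_equal(poisson_pmf(1, 1), exp(-1), tolerance = 1e-12)
  expect_identical(poisson_pmf(0, 0), 1)
  expect_identical(poisson_pmf(3, 0), 0)

  # factorial-free recurrence oracle: f(k) = f(k-1) * mu / k
  mu <- 0.41
  f <- poisson_pmf(0:10, mu)
  expect_equal(f[-1], f[-11] * mu / (1:10), tolerance = 1e-12)
  expect_equal(f[3], 0.0557798, tolerance = 1e-6)

  # independent library implementation as cross-check, over a wide grid
  for (m in c(0.01, 0.41, 1, 5, 20)) {
    expect_equal(poisson_pmf(0:60, m), dpois(0:60, m), tolerance = 1e-12)
  }
})

test_that("the pmf is a normalised distribution with the 37% ceiling", {
  for (m in c(0.1, 0.41, 1, 7, 20)) {
    expect_equal(sum(poisson_pmf(0:200, m)), 1, tolerance = 1e-12)
  }
  # single-occupancy probability is maximised at mu = 1, value exp(-1)
  grid <- seq(0.01, 5, by = 1e-3)
  p1 <- poisson_pmf(rep(1, length(grid)), grid)
  expect_equal(grid[which.max(p1)], 1, tolerance = 2e-3)
  expect_equal(max(p1), exp(-1), tolerance = 1e-6)
})

test_that("zero-truncated occupancy conditions on bead-bearing droplets", {
  # frozen values at the reference rate 0.41 (see acceptance suite for the
  # derived percentages); computed independently from dpois
  expect_equal(truncated_occupancy(1, 0.41),
               dpois(1, 0.41) / (1 - dpois(0, 0.41)), tolerance = 1e-12)
  expect_equal(truncated_occupancy(1, 0.41), 0.8089692, tolerance = 1e-6)
  expect_equal(truncated_occupancy(2, 0.41), 0.1658387, tolerance = 1e-6)
  expect_equal(sum(truncated_occupancy(1:50, 0.41)), 1, tolerance = 1e-12)

  # P(1 | >=1) is strictly decreasing in mu
  mus <- seq(0.05, 10, length.out = 100)
  p1 <- vapply(mus, function(m) truncated_occupancy(1, m), numeric(1))
  expect_true(all(diff(p1) < 0))

  expect_error(truncated_occupancy(1, 0), "positive")
  expect_error(truncated_occupancy(0, 0.5), "k")
})

test_that("least-squares fitting recovers exact-model histograms", {
  h <- ztp_histogram(0.5, n = 1e4)
  fit <- fit_truncated_poisson(h)
  expect_equal(fit$mu, 0.5, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  expect_false(fit$boundary)

  # invariance to rescaling all counts by a positive constant
  h7 <- occupancy_histogram(h$k, h$n_droplets * 7)
  expect_equal(fit_truncated_poisson(h7)$mu, fit$mu, tolerance = 1e-9)

  # data frames with counts or fractions give the same answer
  df_counts <- data.frame(k = h$k, n_droplets = h$n_droplets)
  df_frac <- data.frame(k = h$k,
                        fraction = h$n_droplets / sum(h$n_droplets))
  expect_equal(fit_truncated_poisson(df_counts)$mu, fit$mu,
               tolerance = 1e-9)
  expect_equal(fit_truncated_poisson(df_frac)$mu, fit$mu, tolerance = 1e-9)
})

test_that("the optimiser agrees with a brute-force grid scan", {
  h <- occupancy_histogram(1:3, c(81, 17, 2))
  fit <- fit_truncated_poisson(h)
  obs <- c(81, 17, 2) / 100
  mu_grid <- grid_fit_mu(1:3, obs)
  expect_lt(abs(fit$mu - mu_grid), 1e-4)
  expect_gt(fit$mu, 0.3)
  expect_lt(fit$mu, 0.5)
  # stored SSE is recomputable from the stored vectors
  expect_equal(fit$sse, sse(fit$observed, fit$fitted), tolerance = 1e-12)
})

test_that("degenerate and alternative fits behave as documented", {
  # all mass at k = 1: truncated Poisson tends to a point mass only as
  # mu -> 0, so the fit pins to the lower bound with a warning
  h1 <- occupancy_histogram(1, 100)
  expect_warning(fit <- fit_truncated_poisson(h1), "k = 1")
  expect_true(fit$boundary)
  expect_equal(fit$mu, 1e-6)

  # a histogram with an empty-droplet class cannot be fit truncated
  h0 <- occupancy_histogram(0:2, c(50, 40, 10))
  expect_error(fit_truncated_poisson(h0), "k = 0")
  fit0 <- fit_truncated_poisson(h0, truncated = FALSE)
  expect_gt(fit0$mu, 0)

  # zero-truncated MLE solves the mean identity kbar = mu / (1 - exp(-mu))
  h <- ztp_histogram(0.8, n = 1e4)
  fit_mle <- fit_truncated_poisson(h, method = "mle")
  expect_equal(fit_mle$mu, 0.8, tolerance = 1e-6)
})

test_that("expected rate follows from dose and mean droplet volume", {
  expect_equal(expected_mu(bead_dose(1e7, 100), 3.6), 0.36,
               tolerance = 1e-12)
  mu_f <- expected_mu(bead_dose(1e7, 200), 8.9)
  expect_equal(mu_f, 0.445, tolerance = 1e-12)
  expect_equal(round(mu_f, 2), 0.45)
  expect_equal(expected_mu(bead_dose(1e7, 100), 0), 0)
  expect_error(bead_dose(0, 100), "n_beads")
  expect_error(bead_dose(1e7, -1), "aqueous_volume_ul")
})

test_that("sse is the plain sum of squared fraction errors", {
  expect_identical(sse(c(0.8, 0.2), c(0.8, 0.2)), 0)
  expect_equal(sse(c(0.8, 0.2), c(0.7, 0.3)), 0.02, tolerance = 1e-12)
  expect_error(sse(c(0.8, 0.2), c(0.7)), "equal length")
})

test_that("ligand density implements the Avogadro arithmetic", {
  # 9.2 ul x 9 uM over 5e7 beads: just under 1e6 molecules per bead
  expect_equal(ligand_density(9.2, 9, 5e7), 997266.5, tolerance = 1e-6)
  expect_equal(ligand_density(5, 0, 1e6), 0)
  # identity: 1 ul x 1 uM = 6.022e11 molecules
  expect_equal(ligand_density(1, 1, 6.02214076e11), 1, tolerance = 1e-12)
  expect_error(ligand_density(1, 1, 0), "n_beads")
})

test_that("occupancy histograms validate and tabulate raw counts", {
  h <- occupancy_histogram(c(2, 1), c(17, 81))
  expect_identical(h$k, c(1L, 2L))  # sorted
  expect_true(h$truncated)
  expect_false(occupancy_histogram(0:1, c(5, 5))$truncated)
  expect_error(occupancy_histogram(1:2, c(0, 0)), "at least one")
  expect_error(occupancy_histogram(c(1, 1), c(2, 3)), "distinct")

  raw <- c(0, 0, 1, 1, 1, 2)
  expect_identical(tabulate_occupancy(raw)$n_droplets, c(3, 1))
  expect_identical(tabulate_occupancy(raw, truncate = FALSE)$n_droplets,
                   c(2, 3, 1))
})
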