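test_that("droplet volumes conserve the aqueous phase exactly", {
  p <- scale_params(simulation_params(seed = 11), 1e-4)
  v <- sample_droplet_volumes(p)
  expect_equal(sum(v), ul_to_pl(p$aqueous_volume_ul), tolerance = 1e-12)
  expect_true(all(v > 0))

  # degenerate width: all droplets the target volume, count emergent
  pd <- simulation_params(n_beads = 100, aqueous_volume_ul = 0.0036,
                          log_mean = log(3.6), log_sd = 0, seed = 2)
  vd <- sample_droplet_volumes(pd)
  # ~1000 droplets of 3.6 pL; cumulative-sum rounding can add one trimmed
  # sliver droplet at the end
  expect_true(length(vd) %in% c(1000L, 1001L))
  expect_equal(vd[1:999], rep(3.6, 999), tolerance = 1e-12)

  # moment check against the lognormal mean
  pm <- simulation_params(n_beads = 1, aqueous_volume_ul = 0.25,
                          log_mean = log(2), log_sd = 0.7, seed = 3)
  vm <- sample_droplet_volumes(pm)
  expect_gt(length(vm), 1e5 * 0.9)
  mean_th <- exp(log(2) + 0.7^2 / 2)
  se <- sqrt(exp(0.7^2) - 1) * mean_th / sqrt(length(vm))
  expect_lt(abs(mean(vm) - mean_th) / se, 4)  # last droplet is trimmed

  # gamma family is available
  pg <- simulation_params(n_beads = 10, aqueous_volume_ul = 0.001,
                          volume_family = "gamma", gamma_shape = 2,
                          gamma_scale_pl = 2, seed = 4)
  vg <- sample_droplet_volumes(pg)
  expect_equal(sum(vg), 1000, tolerance = 1e-9)
})

test_that("cluster sizes are shifted-geometric and conserve beads", {
  expect_identical(sample_cluster_sizes(50, 1, seed = 1), rep(1L, 50))
  for (s in 1:3) {
    expect_identical(sum(sample_cluster_sizes(12345, 0.3, seed = s)), 12345L)
  }
  sizes <- sample_cluster_sizes(1e5, 0.5, seed = 9)
  # mean cluster size 1/p = 2; SE of the mean from geometric variance
  se <- sqrt(1 - 0.5) / 0.5 / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 2) / se, 3)
  expect_error(sample_cluster_sizes(100, 0), "(0, 1]", fixed = TRUE)
  expect_error(sample_cluster_sizes(100, 1.5), "(0, 1]", fixed = TRUE)
})

test_that("volume-proportional loading reaches the Poisson limit", {
  # monodisperse droplets, no clustering: counts are Poisson(mu)
  mu_true <- 0.6
  p <- mono_params(mu_true, n_bc = 5e3, seed = 21)
  em <- simulate_emulsion(p)
  expect_equal(sum(em$bead_counts), p$n_beads)
  bc <- em$bead_counts[em$bead_counts >= 1]
  expect_occupancy_match(bc, function(k) truncated_occupancy(k, mu_true),
                         n_total = length(bc))
})

test_that("polydisperse loading matches the binned-mixture model", {
  # droplets drawn from the binned volume distribution (volumes at bin
  # midpoints) make the count-weighted truncated mixture the exact model
  p <- scale_params(fluosurf_params(seed = 33), 2e-4)
  raw <- sample_droplet_volumes(p, seed = 33)
  b <- bin_droplet_volumes(raw, 2)
  vols <- rep(b$bin_mid_pl, b$bin_counts)
  dose <- bead_dose(p$n_beads, p$aqueous_volume_ul)
  counts <- load_beads(vols, sample_cluster_sizes(p$n_beads, 1, seed = 34),
                       seed = 35)
  mix <- build_mixture(b, dose)
  bc <- counts[counts >= 1]
  expect_occupancy_match(bc, function(k) truncated_mixture_occupancy(mix, k),
                         n_total = length(bc))
})

test_that("aggregation produces super-Poissonian occupancy", {
  base <- mono_params(0.4, n_bc = 4e3, seed = 55)
  disp <- function(p_cluster, seed) {
    prm <- base; prm$cluster_p <- p_cluster; prm$seed <- seed
    em <- simulate_emulsion(prm)
    tab <- render_measurements(em)
    fit <- suppressWarnings(fit_truncated_poisson(
      tabulate_occupancy(tab$n_beads)))
    c(index = var(em$bead_counts) / mean(em$bead_counts), sse = fit$sse)
  }
  d <- vapply(c(1, 0.5, 0.1), disp, numeric(2), seed = 56)
  # index of dispersion ~1 without clustering, strictly growing as the
  # cluster termination probability drops; fit quality degrades in step
  expect_equal(unname(d["index", 1]), 1, tolerance = 0.1)
  expect_true(all(diff(d["index", ]) > 0))
  expect_true(all(diff(d["sse", ]) > 0))
  expect_gt(d["index", 3], 2)
})

test_that("rendered measurements honour filters, budgets and geometry", {
  p <- scale_params(simulation_params(seed = 8), 5e-5)
  em <- simulate_emulsion(p)
  g <- chamber_geometry(p$layer_height_um)

  tab <- render_measurements(em)
  expect_true(all(tab$n_beads >= 1))

  tab_all <- render_measurements(em, only_bead_containing = FALSE)
  expect_identical(nrow(tab_all), length(em$volumes_pl))

  # manual-measurement budget: exactly 360 droplets, deterministic by seed
  s1 <- render_measurements(em, subsample_n = 360, seed = 99)
  s2 <- render_measurements(em, subsample_n = 360, seed = 99)
  expect_identical(nrow(s1), 360L)
  expect_identical(s1, s2)
  expect_error(render_measurements(em, subsample_n = 1e7), "exceeds")

  # observed diameters reproduce true volumes through the geometry round
  # trip, except in the inversion gap at the regime discontinuity
  h <- p$layer_height_um
  gap <- c(pi / 6 * h^3, pi / 4 * h^3) / 1000
  v_true <- em$volumes_pl[tab_all$droplet_id]
  outside <- v_true < gap[1] | v_true > gap[2]
  v_back <- volume_from_diameter(tab_all$diameter_um[outside], g)$volume_pl
  expect_lt(max(abs(v_back - v_true[outside]) / v_true[outside]), 1e-9)
})

test_that("simulation is reproducible and parameter scaling preserves dose", {
  p <- scale_params(simulation_params(seed = 13), 1e-4)
  e1 <- simulate_emulsion(p)
  e2 <- simulate_emulsion(p)
  expect_identical(e1$volumes_pl, e2$volumes_pl)
  expect_identical(e1$bead_counts, e2$bead_counts)

  p0 <- simulation_params()
  ps <- scale_params(p0, 1e-3)
  expect_equal(ps$n_beads / ul_to_pl(ps$aqueous_volume_ul),
               p0$n_beads / ul_to_pl(p0$aqueous_volume_ul),
               tolerance = 1e-9)
  expect_error(simulation_params(cluster_p = 0), "(0, 1]", fixed = TRUE)
  expect_error(simulation_params(log_mean = Inf), "finite")
})
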