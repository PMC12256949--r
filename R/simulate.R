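#' Parameters for the synthetic emulsion generator
#'
#' The generator emulates a stochastic one-step (vortexed) polydisperse
#' emulsification: a fixed total aqueous volume is dispersed into lognormally
#' distributed droplet volumes, a fixed number of beads is partitioned into
#' droplets with probability proportional to droplet volume (whole clusters
#' at a time when aggregation is simulated), and droplets are measured under
#' slab confinement. Defaults reproduce the Abil EM 90 study condition: 10^7
#' beads in 100 ul, lognormal volumes whose *bead-containing* droplets
#' average ~3.6 pL, and a 8.4 um liquid layer. `fluosurf_params()` gives the
#' FluoSurf condition (200 ul, ~8.9 pL, 7.2 um).
#'
#' Because bead-containing droplets are a size-biased sample of all droplets
#' (a droplet is hit with probability ~ proportional to its volume at low
#' rates), a lognormal(m, s) volume distribution has bead-containing mean
#' `exp(m + 3 s^2 / 2)`; the default `log_mean` is solved from the target
#' bead-containing mean at `log_sd = 1`, a typical width for vortexed
#' emulsions.
#'
#' @param n_beads total beads dispersed (conserved exactly by simulation).
#' @param aqueous_volume_ul total aqueous volume (ul), dispersed exactly.
#' @param log_mean,log_sd lognormal parameters of droplet volume (pL scale).
#' @param volume_family `"lognormal"` (default) or `"gamma"`.
#' @param gamma_shape,gamma_scale_pl gamma parameters, used only when
#'   `volume_family = "gamma"`.
#' @param cluster_p probability in (0, 1] that a growing bead cluster
#'   terminates; cluster sizes are shifted-geometric with mean `1/p`, so
#'   `cluster_p = 1` means no aggregation (all clusters are single beads) and
#'   small values mean severe clumping.
#' @param layer_height_um liquid layer height for the measurement model (um).
#' @param seed integer seed from which all the generator's randomness flows.
#' @return an object of class `simulation_params`.
#' @examples
#' simulation_params()
#' scale_params(simulation_params(), 1e-3)  # same concentration, 1/1000 scale
#' @export
simulation_params <- function(n_beads = 1e7,
                              aqueous_volume_ul = 100,
                              log_mean = log(3.6) - 1.5,
                              log_sd = 1,
                              volume_family = c("lognormal", "gamma"),
                              gamma_shape = 1,
                              gamma_scale_pl = 3.6,
                              cluster_p = 1,
                              layer_height_um = 8.4,
                              seed = 1L) {
  .check_positive_scalar(n_beads, "n_beads")
  .check_positive_scalar(aqueous_volume_ul, "aqueous_volume_ul")
  .check_positive_scalar(layer_height_um, "layer_height_um")
  volume_family <- match.arg(volume_family)
  if (!is.finite(log_mean) || !is.finite(log_sd) || log_sd < 0) {
    stop("lognormal parameters must be finite with `log_sd` >= 0",
         call. = FALSE)
  }
  if (volume_family == "gamma" &&
      (!is.finite(gamma_shape) || gamma_shape <= 0 ||
       !is.finite(gamma_scale_pl) || gamma_scale_pl <= 0)) {
    stop("gamma parameters must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(cluster_p) || length(cluster_p) != 1L ||
      !is.finite(cluster_p) || cluster_p <= 0 || cluster_p > 1) {
    stop("`cluster_p` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(n_beads = n_beads,
                 aqueous_volume_ul = aqueous_volume_ul,
                 log_mean = log_mean, log_sd = log_sd,
                 volume_family = volume_family,
                 gamma_shape = gamma_shape, gamma_scale_pl = gamma_scale_pl,
                 cluster_p = cluster_p,
                 layer_height_um = layer_height_um,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
fluosurf_params <- function(seed = 1L, log_sd = 1, cluster_p = 1) {
  simulation_params(n_beads = 1e7, aqueous_volume_ul = 200,
                    log_mean = log(8.9) - 1.5 * log_sd^2, log_sd = log_sd,
                    cluster_p = cluster_p, layer_height_um = 7.2, seed = seed)
}

#' @rdname simulation_params
#' @param params a `simulation_params` object.
#' @param factor positive scale factor applied to both `n_beads` and the
#'   aqueous volume, preserving the bead concentration (and hence all
#'   occupancy rates) while shrinking the droplet population.
#' @export
scale_params <- function(params, factor) {
  stopifnot(inherits(params, "simulation_params"))
  .check_positive_scalar(factor, "factor")
  params$n_beads <- max(1, round(params$n_beads * factor))
  params$aqueous_volume_ul <- params$aqueous_volume_ul * factor
  params
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Synthetic emulsion parameters\n")
  cat("  dose:", format(x$n_beads, big.mark = ","), "beads in",
      x$aqueous_volume_ul, "ul\n")
  cat("  volumes:", x$volume_family,
      if (x$volume_family == "lognormal")
        sprintf("(log-mean %.3f, log-sd %.3f)", x$log_mean, x$log_sd)
      else sprintf("(shape %.3f, scale %.3f pL)", x$gamma_shape,
                   x$gamma_scale_pl), "\n")
  cat("  cluster termination p:", x$cluster_p,
      "| layer height:", x$layer_height_um, "um | seed:", x$seed, "\n")
  invisible(x)
}

.with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

#' Sample polydisperse droplet volumes conserving the aqueous phase
#'
#' Draws droplet volumes from the configured family until their cumulative
#' sum first reaches the total aqueous volume; the last droplet is trimmed so
#' volumes sum to the aqueous volume exactly. The droplet count is therefore
#' emergent, mirroring bulk emulsification where the aqueous phase is fully
#' dispersed.
#'
#' @param params a [simulation_params()].
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used internally by [simulate_emulsion()], which seeds once).
#' @return numeric vector of droplet volumes (pL) summing exactly to the
#'   aqueous volume.
#' @export
sample_droplet_volumes <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  target <- ul_to_pl(params$aqueous_volume_ul)
  draw <- switch(params$volume_family,
                 lognormal = function(n) rlnorm(n, params$log_mean,
                                                params$log_sd),
                 gamma = function(n) rgamma(n, shape = params$gamma_shape,
                                            scale = params$gamma_scale_pl))
  mean_v <- switch(params$volume_family,
                   lognormal = exp(params$log_mean + params$log_sd^2 / 2),
                   gamma = params$gamma_shape * params$gamma_scale_pl)
  if (!is.finite(mean_v) || mean_v <= 0) {
    stop("volume distribution has non-finite mean", call. = FALSE)
  }
  .with_optional_seed(seed, function() {
    vols <- list(); total <- 0
    chunk <- max(1000L, ceiling(target / mean_v * 0.2))
    repeat {
      x <- draw(chunk)
      cs <- total + cumsum(x)
      hit <- which(cs >= target)
      if (length(hit)) {
        i <- hit[1]
        x[i] <- target - (if (i > 1) cs[i - 1] else total)
        vols[[length(vols) + 1L]] <- x[seq_len(i)]
        break
      }
      vols[[length(vols) + 1L]] <- x
      total <- cs[chunk]
    }
    out <- unlist(vols, use.names = FALSE)
    out[out > 0]  # trimmed last droplet can be exactly zero
  })
}

#' Sample bead cluster sizes (aggregation model)
#'
#' Partitions `n_beads` beads into clusters whose sizes are shifted-geometric
#' with termination probability `p` (support >= 1, mean `1/p`); the last
#' cluster is trimmed so sizes sum to `n_beads` exactly. `p = 1` yields all
#' singletons (fully dispersed beads); small `p` emulates severe aggregation,
#' where clumps of many beads co-partition into one droplet. This is a
#' deliberately simple synthetic stand-in for real aggregate-size
#' distributions, which are not quantitatively characterised.
#'
#' @param n_beads total beads to partition.
#' @param p cluster termination probability in (0, 1].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return integer vector of cluster sizes summing to `n_beads`.
#' @export
sample_cluster_sizes <- function(n_beads, p, seed = NULL) {
  .check_positive_scalar(n_beads, "n_beads")
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    stop("`p` must lie in (0, 1]", call. = FALSE)
  }
  .with_optional_seed(seed, function() {
    if (p == 1) return(rep(1L, n_beads))
    sizes <- list(); total <- 0
    chunk <- max(1000L, ceiling(n_beads * p * 0.2))
    repeat {
      x <- rgeom(chunk, p) + 1L
      cs <- total + cumsum(x)
      hit <- which(cs >= n_beads)
      if (length(hit)) {
        i <- hit[1]
        x[i] <- n_beads - (if (i > 1) cs[i - 1] else total)
        sizes[[length(sizes) + 1L]] <- x[seq_len(i)]
        break
      }
      sizes[[length(sizes) + 1L]] <- x
      total <- cs[chunk]
    }
    out <- unlist(sizes, use.names = FALSE)
    as.integer(out[out > 0])
  })
}

#' Load bead clusters into droplets proportionally to volume
#'
#' Each cluster is independently assigned to droplet `j` with probability
#' `V_j / sum(V)`; a droplet's bead count is the total size of the clusters
#' it received. With singleton clusters and many droplets this is the
#' multinomial-thinning construction whose per-droplet counts are Poisson
#' with rate `c V_j` to excellent approximation; with large clusters the
#' counts become overdispersed (super-Poissonian).
#'
#' @param volumes_pl droplet volumes (pL).
#' @param cluster_sizes integer cluster sizes (see [sample_cluster_sizes()]).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return numeric vector of per-droplet bead counts (same length as
#'   `volumes_pl`, summing to `sum(cluster_sizes)`).
#' @export
load_beads <- function(volumes_pl, cluster_sizes, seed = NULL) {
  if (!is.numeric(volumes_pl) || length(volumes_pl) == 0L ||
      any(volumes_pl <= 0)) {
    stop("`volumes_pl` must be positive volumes", call. = FALSE)
  }
  .check_k(cluster_sizes, min_k = 1)
  .with_optional_seed(seed, function() {
    cum <- cumsum(volumes_pl)
    cum <- cum / cum[length(cum)]
    u <- runif(length(cluster_sizes))
    idx <- findInterval(u, cum) + 1L
    counts <- numeric(length(volumes_pl))
    agg <- rowsum(as.numeric(cluster_sizes), idx)
    counts[as.integer(rownames(agg))] <- agg[, 1]
    counts
  })
}

#' Simulate a complete synthetic emulsion
#'
#' Runs volume sampling, cluster sampling and volume-proportional bead
#' loading under a single seed. Bead and volume conservation hold exactly:
#' per-droplet counts sum to `n_beads` and volumes sum to the aqueous volume.
#'
#' @param params a [simulation_params()].
#' @return an object of class `synthetic_emulsion` with fields `volumes_pl`,
#'   `bead_counts`, `cluster_sizes` and `params`.
#' @examples
#' em <- simulate_emulsion(scale_params(simulation_params(seed = 7), 1e-4))
#' sum(em$bead_counts) == em$params$n_beads
#' @export
simulate_emulsion <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    vols <- sample_droplet_volumes(params, seed = NULL)
    clusters <- sample_cluster_sizes(params$n_beads, params$cluster_p,
                                     seed = NULL)
    counts <- load_beads(vols, clusters, seed = NULL)
  })
  structure(list(volumes_pl = vols,
                 bead_counts = counts,
                 cluster_sizes = clusters,
                 params = params),
            class = "synthetic_emulsion")
}

#' @export
print.synthetic_emulsion <- function(x, ...) {
  n_bc <- sum(x$bead_counts >= 1)
  cat("Synthetic emulsion:", length(x$volumes_pl), "droplets,",
      format(sum(x$bead_counts), big.mark = ","), "beads in",
      length(x$cluster_sizes), "clusters\n")
  cat("  bead-containing droplets:", n_bc,
      sprintf("(mean volume %.2f pL)",
              mean(x$volumes_pl[x$bead_counts >= 1])), "\n")
  invisible(x)
}

#' Render per-droplet measurements from a synthetic emulsion
#'
#' Applies the slab-confinement measurement model: true droplet volumes are
#' converted to observed in-plane diameters via [diameter_from_volume()],
#' optionally restricted to bead-containing droplets (the measurable subset
#' in practice) and subsampled without replacement to a manual-measurement
#' budget.
#'
#' @param emulsion a [simulate_emulsion()] result.
#' @param geometry a [chamber_geometry()]; defaults to the layer height in
#'   the emulsion's parameters.
#' @param only_bead_containing keep only droplets with >= 1 bead (default).
#' @param subsample_n if non-`NULL`, subsample exactly this many rows without
#'   replacement; errors when more rows are requested than exist.
#' @param seed integer seed for the subsampling, or `NULL`.
#' @return a data frame with columns `droplet_id`, `diameter_um`, `n_beads`.
#' @export
render_measurements <- function(emulsion,
                                geometry =
                                  chamber_geometry(emulsion$params$layer_height_um),
                                only_bead_containing = TRUE,
                                subsample_n = NULL,
                                seed = NULL) {
  stopifnot(inherits(emulsion, "synthetic_emulsion"))
  tab <- data.frame(droplet_id = seq_along(emulsion$volumes_pl),
                    diameter_um = diameter_from_volume(emulsion$volumes_pl,
                                                       geometry),
                    n_beads = emulsion$bead_counts)
  if (only_bead_containing) tab <- tab[tab$n_beads >= 1, , drop = FALSE]
  if (!is.null(subsample_n)) {
    if (subsample_n > nrow(tab)) {
      stop("`subsample_n` (", subsample_n, ") exceeds available droplets (",
           nrow(tab), ")", call. = FALSE)
    }
    rows <- .with_optional_seed(seed, function() {
      sample.int(nrow(tab), subsample_n)
    })
    tab <- tab[sort(rows), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
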