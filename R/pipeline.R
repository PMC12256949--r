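#' Read a per-droplet measurement table
#'
#' Expects a CSV with one row per measured droplet: `diameter_um` (in-plane
#' diameter, um), `n_beads` (beads counted in the droplet) and optionally
#' `emulsion_id` (replicate identifier). Validation is strict and names the
#' offending rows: negative or non-numeric diameters, non-integer or negative
#' bead counts, and decimal-comma numbers (a common locale pitfall — `1.963`
#' as a thousands-separated count is not the same as `1,963`) are all
#' rejected with explicit messages.
#'
#' @param path path to a CSV file.
#' @return a validated data frame of droplet records.
#' @seealso [write_droplet_table()]
#' @export
read_droplet_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("diameter_um", "n_beads")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("droplet table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    if (is.character(tab[[col]])) {
      if (any(grepl(",", tab[[col]], fixed = TRUE))) {
        stop("column `", col, "` contains commas; use `.` as the decimal ",
             "separator and no thousands separators", call. = FALSE)
      }
      suppressWarnings(tab[[col]] <- as.numeric(tab[[col]]))
    }
    if (anyNA(tab[[col]])) {
      stop("column `", col, "` has non-numeric values in row(s): ",
           paste(which(is.na(tab[[col]])), collapse = ", "), call. = FALSE)
    }
  }
  bad_d <- which(tab$diameter_um <= 0)
  if (length(bad_d)) {
    stop("non-positive `diameter_um` in row(s): ",
         paste(bad_d, collapse = ", "), call. = FALSE)
  }
  bad_k <- which(tab$n_beads < 0 | abs(tab$n_beads - round(tab$n_beads)) > 1e-8)
  if (length(bad_k)) {
    stop("`n_beads` must be non-negative integers; offending row(s): ",
         paste(bad_k, collapse = ", "), call. = FALSE)
  }
  tab$n_beads <- as.integer(round(tab$n_beads))
  tab
}

#' @rdname read_droplet_table
#' @param table a droplet record data frame.
#' @export
write_droplet_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.observed_fractions <- function(table, pooling) {
  bc <- table[table$n_beads >= 1, , drop = FALSE]
  support <- seq_len(max(bc$n_beads))
  per_emulsion <- pooling == "per_emulsion" && "emulsion_id" %in% names(table)
  if (per_emulsion) {
    ids <- unique(bc$emulsion_id)
    mat <- vapply(ids, function(id) {
      k <- bc$n_beads[bc$emulsion_id == id]
      tabulate(k, nbins = max(support)) / length(k)
    }, numeric(length(support)))
    mat <- matrix(mat, nrow = length(support))
    frac <- rowMeans(mat)
    frac <- frac / sum(frac)  # guard against replicate-average drift
    sdv <- if (length(ids) > 1) apply(mat, 1, sd) else rep(NA_real_,
                                                           length(support))
    n_emulsions <- length(ids)
  } else {
    frac <- tabulate(bc$n_beads, nbins = max(support)) / nrow(bc)
    sdv <- rep(NA_real_, length(support))
    n_emulsions <- if ("emulsion_id" %in% names(table))
      length(unique(bc$emulsion_id)) else 1L
  }
  list(support = support, fraction = frac, sd = sdv,
       n_emulsions = n_emulsions, n_bead_containing = nrow(bc))
}

#' Analyse an emulsion measurement table
#'
#' The full occupancy analysis: droplet volumes from diameters under slab
#' confinement, the mean bead-containing droplet volume, observed occupancy
#' fractions (per replicate emulsion, averaged, with across-replicate
#' standard deviations), a least-squares zero-truncated Poisson fit
#' (`mu_hat`, SSE), the concentration-based expected rate and its SSE, and —
#' when the table includes empty droplets — the volume-binned Poisson
#' mixture prediction and its SSE.
#'
#' @param table droplet records (see [read_droplet_table()]): columns
#'   `diameter_um`, `n_beads`, optional `emulsion_id`.
#' @param config an [experiment_config()].
#' @return an object of class `emulsion_report`.
#' @examples
#' em <- simulate_emulsion(scale_params(simulation_params(seed = 3), 2e-4))
#' tab <- render_measurements(em, only_bead_containing = FALSE)
#' analyze_emulsion(tab, experiment_config(n_beads = em$params$n_beads,
#'                  aqueous_volume_ul = em$params$aqueous_volume_ul))
#' @export
analyze_emulsion <- function(table, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  if (!all(c("diameter_um", "n_beads") %in% names(table))) {
    stop("`table` needs columns `diameter_um` and `n_beads`", call. = FALSE)
  }
  if (!any(table$n_beads >= 1)) {
    stop("no bead-containing droplets in `table`", call. = FALSE)
  }
  geometry <- chamber_geometry(config$layer_height_um)
  vol <- volume_from_diameter(table$diameter_um, geometry)
  table$volume_pl <- vol$volume_pl
  table$shape_regime <- vol$shape_regime

  bc <- table$n_beads >= 1
  mean_bc_volume <- mean(table$volume_pl[bc])
  obs <- .observed_fractions(table, config$pooling)

  fit <- fit_truncated_poisson(
    data.frame(k = obs$support, fraction = obs$fraction),
    mu_bounds = c(config$mu_lower, config$mu_upper),
    truncated = config$truncated)

  dose <- bead_dose(config$n_beads, config$aqueous_volume_ul)
  exp_mu <- expected_mu(dose, mean_bc_volume)
  exp_model <- truncated_occupancy(obs$support, exp_mu)
  exp_sse <- sse(obs$fraction, exp_model)

  mixture <- NULL; mixture_pred <- NULL; mixture_sse <- NA_real_
  if (any(table$n_beads == 0)) {
    binning <- bin_droplet_volumes(table$volume_pl, config$bin_width_pl)
    mixture <- build_mixture(binning, dose)
    mixture_pred <- truncated_mixture_occupancy(mixture, obs$support)
    mixture_sse <- sse(obs$fraction, mixture_pred)
  }

  structure(list(n_droplets = nrow(table),
                 n_bead_containing = obs$n_bead_containing,
                 n_emulsions = obs$n_emulsions,
                 mean_bc_volume_pl = mean_bc_volume,
                 observed = data.frame(k = obs$support,
                                       fraction = obs$fraction,
                                       sd = obs$sd),
                 fit = fit,
                 expected_mu = exp_mu,
                 expected_model = exp_model,
                 expected_sse = exp_sse,
                 mixture = mixture,
                 mixture_prediction = mixture_pred,
                 mixture_sse = mixture_sse,
                 config = config),
            class = "emulsion_report")
}

#' @export
print.emulsion_report <- function(x, ...) {
  cat("Emulsion occupancy analysis\n")
  cat("  droplets analysed:", x$n_droplets,
      "(", x$n_bead_containing, "bead-containing,",
      x$n_emulsions, "emulsion(s) )\n")
  cat(sprintf("  mean bead-containing droplet volume: %.2f pL\n",
              x$mean_bc_volume_pl))
  cat(sprintf("  fitted mu = %.2g (SSE %.2g)\n", x$fit$mu, x$fit$sse))
  cat(sprintf("  expected mu (dose x mean volume) = %.2g (SSE %.2g)\n",
              x$expected_mu, x$expected_sse))
  if (!is.null(x$mixture)) {
    cat(sprintf("  volume-binned mixture SSE = %.2g (%d bins of %g pL)\n",
                x$mixture_sse, length(x$mixture$weights),
                x$config$bin_width_pl))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the fitted occupancy rate
#'
#' Nonparametric bootstrap over bead-containing droplets: rows are resampled
#' with replacement, the zero-truncated fit is repeated, and a percentile
#' interval for `mu_hat` is returned. Deterministic given `seed`.
#'
#' @param table droplet records with >= 10 bead-containing rows.
#' @param config an [experiment_config()].
#' @param n_boot number of bootstrap replicates, >= 100.
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @return a list with `mu_hat` (point fit on the full table), `interval`
#'   (percentile bounds), `n_boot` and `level`.
#' @export
bootstrap_mu <- function(table, config = experiment_config(), n_boot = 1000,
                         seed = 1L, level = 0.95) {
  stopifnot(inherits(config, "experiment_config"))
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  bc <- table[table$n_beads >= 1, , drop = FALSE]
  if (nrow(bc) < 10) {
    stop("need at least 10 bead-containing droplets to bootstrap",
         call. = FALSE)
  }
  fit_mu <- function(counts) {
    h <- tabulate_occupancy(counts)
    fit_truncated_poisson(h, mu_bounds = c(config$mu_lower, config$mu_upper),
                          truncated = config$truncated)$mu
  }
  mu_hat <- fit_mu(bc$n_beads)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      suppressWarnings(fit_mu(sample(bc$n_beads, replace = TRUE)))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  list(mu_hat = mu_hat,
       interval = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_boot = n_boot,
       level = level)
}

#' Serialise an analysis report to JSON
#'
#' Machine-readable counterpart of `print.emulsion_report`: all quantities at
#' full precision, including the observed/fitted fraction vectors from which
#' every reported SSE can be recomputed, plus the full configuration for
#' provenance. Byte-identical output for identical inputs.
#'
#' @param report an [analyze_emulsion()] result.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "emulsion_report"))
  payload <- list(
    n_droplets = report$n_droplets,
    n_bead_containing = report$n_bead_containing,
    n_emulsions = report$n_emulsions,
    mean_bc_volume_pl = report$mean_bc_volume_pl,
    observed = report$observed,
    fit = list(mu = report$fit$mu, sse = report$fit$sse,
               support = report$fit$support,
               observed = report$fit$observed, fitted = report$fit$fitted,
               truncated = report$fit$truncated, method = report$fit$method,
               boundary = report$fit$boundary),
    expected_mu = report$expected_mu,
    expected_model = report$expected_model,
    expected_sse = report$expected_sse,
    mixture = if (!is.null(report$mixture)) {
      list(weights = report$mixture$weights, rates = report$mixture$rates,
           representative_volume_pl = report$mixture$representative_volume_pl,
           bin_counts = report$mixture$bin_counts,
           weighting = report$mixture$weighting,
           prediction = report$mixture_prediction,
           sse = report$mixture_sse)
    },
    config = unclass(report$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
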