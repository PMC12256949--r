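#' Bin droplet volumes into uniform-width size classes
#'
#' The polydispersity correction starts by binning the full droplet volume
#' distribution — including empty droplets — into uniform bins (2 pL wide by
#' default). Bins are half-open `[m w, (m+1) w)` anchored at 0 pL, so a
#' volume exactly on an edge belongs to the upper bin; empty leading and
#' trailing bins are dropped, internal empty bins are kept with zero counts.
#' Both the bin midpoint and the within-bin mean of the raw volumes are
#' stored as candidate representative volumes.
#'
#' @param volumes_pl numeric vector of droplet volumes (pL), all positive.
#' @param bin_width_pl bin width (pL), default 2.
#' @return an object of class `volume_binning` with fields `bin_edges`
#'   (length nbins + 1), `bin_counts`, `bin_mid_pl`, `bin_mean_pl` (NA for
#'   empty internal bins) and `bin_width_pl`.
#' @examples
#' bin_droplet_volumes(c(1, 1, 3), bin_width_pl = 2)
#' @export
bin_droplet_volumes <- function(volumes_pl, bin_width_pl = 2) {
  if (!is.numeric(volumes_pl) || length(volumes_pl) == 0L ||
      any(!is.finite(volumes_pl)) || any(volumes_pl <= 0)) {
    stop("`volumes_pl` must be a non-empty vector of positive volumes",
         call. = FALSE)
  }
  .check_positive_scalar(bin_width_pl, "bin_width_pl")
  idx <- floor(volumes_pl / bin_width_pl)          # bin index m, from 0
  lo <- min(idx); hi <- max(idx)
  bins <- seq.int(lo, hi)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  means <- rep(NA_real_, length(bins))
  agg <- tapply(volumes_pl, idx, mean)
  means[match(as.integer(names(agg)), bins)] <- as.numeric(agg)
  structure(list(bin_edges = c(bins, hi + 1L) * bin_width_pl,
                 bin_counts = counts,
                 bin_mid_pl = (bins + 0.5) * bin_width_pl,
                 bin_mean_pl = means,
                 bin_width_pl = bin_width_pl),
            class = "volume_binning")
}

#' @export
print.volume_binning <- function(x, ...) {
  cat("Volume binning:", length(x$bin_counts), "bins of", x$bin_width_pl,
      "pL,", sum(x$bin_counts), "droplets\n")
  invisible(x)
}

#' Volume-binned mixture of Poisson occupancy distributions
#'
#' For each volume bin `i` with representative volume `V_i`, the local
#' encapsulation rate follows from the bin's share of the total aqueous
#' reagent volume: the bin holds `n_i V_i / sum_j n_j V_j` of the aqueous
#' phase and hence, in expectation, that share of the beads, giving
#' `mu_i = c V_i` beads per droplet with `c` the bead concentration implied
#' by the dose. The mixture weights are droplet-count shares,
#' `w_i = n_i / sum n_j`, which makes the (truncated) mixture the exact
#' occupancy distribution of a droplet drawn at random from the emulsion
#' under volume-proportional loading. An aqueous-volume-share weighting
#' (`w_i = n_i V_i / sum n_j V_j`, the occupancy seen from the perspective of
#' a volume element rather than a droplet) is available via
#' `weighting = "volume"` for comparison.
#'
#' @param binning a [bin_droplet_volumes()] result.
#' @param dose a [bead_dose()].
#' @param representative `"midpoint"` (default; deterministic given only
#'   binned counts) or `"mean"` (within-bin mean of the raw volumes, when
#'   they are available).
#' @param weighting `"count"` (droplet-count share, default) or `"volume"`
#'   (aqueous-volume share).
#' @return an object of class `poisson_mixture` with fields `weights`
#'   (summing to 1), `rates` (per-bin `mu_i`), `representative_volume_pl`,
#'   `bin_counts` and `weighting`.
#' @examples
#' b <- bin_droplet_volumes(c(rep(1, 100), rep(3, 100)), bin_width_pl = 2)
#' build_mixture(b, bead_dose(1e7, 200))
#' @export
build_mixture <- function(binning, dose,
                          representative = c("midpoint", "mean"),
                          weighting = c("count", "volume")) {
  stopifnot(inherits(binning, "volume_binning"), inherits(dose, "bead_dose"))
  representative <- match.arg(representative)
  weighting <- match.arg(weighting)
  if (all(binning$bin_counts == 0)) {
    stop("binning has no droplets", call. = FALSE)
  }
  v <- if (representative == "midpoint") binning$bin_mid_pl
       else ifelse(is.na(binning$bin_mean_pl), binning$bin_mid_pl,
                   binning$bin_mean_pl)
  n <- binning$bin_counts
  w <- if (weighting == "volume") n * v / sum(n * v) else n / sum(n)
  structure(list(weights = w,
                 rates = bead_concentration_per_pl(dose) * v,
                 representative_volume_pl = v,
                 bin_counts = n,
                 weighting = weighting),
            class = "poisson_mixture")
}

#' @export
print.poisson_mixture <- function(x, ...) {
  cat("Poisson mixture over", length(x$weights), "volume bins (",
      x$weighting, "-weighted )\n", sep = " ")
  cat("  mean rate sum(w_i mu_i) =", signif(sum(x$weights * x$rates), 4),
      "beads/droplet\n")
  invisible(x)
}

#' Occupancy probability under a volume-binned Poisson mixture
#'
#' Weighted sum of per-bin Poisson pmfs, `M(k) = sum_i w_i f(k; mu_i)` — the
#' predicted bead-count distribution across the whole polydisperse emulsion.
#'
#' @param mixture a [build_mixture()] result.
#' @param k integer vector of bead counts, `k >= 0`.
#' @return numeric vector of probabilities.
#' @export
mixture_occupancy <- function(mixture, k) {
  stopifnot(inherits(mixture, "poisson_mixture"))
  .check_k(k, min_k = 0)
  vapply(k, function(ki) sum(mixture$weights *
                               poisson_pmf(rep(ki, length(mixture$rates)),
                                           mixture$rates)),
         numeric(1))
}

#' Zero-truncated occupancy under a volume-binned Poisson mixture
#'
#' The mixture conditioned on droplets containing at least one bead:
#' `M(k) / (1 - M(0))` for `k >= 1`. Truncation is applied to the final
#' mixture (weight, then truncate), so the prediction is directly comparable
#' to observed fractions of bead-bearing droplets.
#'
#' @inheritParams mixture_occupancy
#' @param k integer vector of bead counts, `k >= 1`.
#' @return numeric vector of conditional probabilities.
#' @export
truncated_mixture_occupancy <- function(mixture, k) {
  stopifnot(inherits(mixture, "poisson_mixture"))
  .check_k(k, min_k = 1)
  m0 <- mixture_occupancy(mixture, 0)
  if (m0 >= 1 - 1e-15) {
    stop("mixture places all mass on empty droplets (all rates ~ 0); ",
         "truncated occupancy undefined", call. = FALSE)
  }
  mixture_occupancy(mixture, k) / (1 - m0)
}

#' Mean bead count implied by a mixture
#'
#' Law of total expectation: `sum_k k M(k) = sum_i w_i mu_i`.
#'
#' @inheritParams mixture_occupancy
#' @return expected beads per droplet across the emulsion.
#' @export
mixture_mean_rate <- function(mixture) {
  stopifnot(inherits(mixture, "poisson_mixture"))
  sum(mixture$weights * mixture$rates)
}
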