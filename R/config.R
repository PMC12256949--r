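#' Experiment configuration for an encapsulation analysis
#'
#' Bundles the measured chamber geometry, the bead dose and the analysis
#' options. Defaults reproduce the Abil EM 90 study condition: 8.4 um liquid
#' layer, 10^7 beads in 100 ul, 2 pL volume bins, zero-truncated fit on
#' `mu` in `[1e-6, 50]`, per-emulsion pooling of occupancy fractions.
#'
#' @param layer_height_um liquid layer height (um).
#' @param n_beads total beads dispersed.
#' @param aqueous_volume_ul total aqueous volume (ul).
#' @param bin_width_pl width of droplet-volume bins for the mixture (pL).
#' @param truncated fit the zero-truncated occupancy model.
#' @param mu_lower,mu_upper search bounds for the fitted rate.
#' @param pooling `"per_emulsion"` (observed fractions computed per emulsion
#'   then averaged, matching across-replicate error bars) or `"pooled"`
#'   (all droplets pooled).
#' @return an object of class `experiment_config`.
#' @examples
#' experiment_config()
#' experiment_config(layer_height_um = 7.2, aqueous_volume_ul = 200)
#' @export
experiment_config <- function(layer_height_um = 8.4,
                              n_beads = 1e7,
                              aqueous_volume_ul = 100,
                              bin_width_pl = 2,
                              truncated = TRUE,
                              mu_lower = 1e-6,
                              mu_upper = 50,
                              pooling = c("per_emulsion", "pooled")) {
  .check_positive_scalar(layer_height_um, "layer_height_um")
  .check_positive_scalar(n_beads, "n_beads")
  .check_positive_scalar(aqueous_volume_ul, "aqueous_volume_ul")
  .check_positive_scalar(bin_width_pl, "bin_width_pl")
  .check_positive_scalar(mu_upper, "mu_upper")
  .check_positive_scalar(mu_lower, "mu_lower")
  if (mu_lower >= mu_upper) stop("`mu_lower` must be below `mu_upper`",
                                 call. = FALSE)
  structure(list(layer_height_um = layer_height_um,
                 n_beads = n_beads,
                 aqueous_volume_ul = aqueous_volume_ul,
                 bin_width_pl = bin_width_pl,
                 truncated = isTRUE(truncated),
                 mu_lower = mu_lower,
                 mu_upper = mu_upper,
                 pooling = match.arg(pooling)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration\n")
  cat("  layer height:", x$layer_height_um, "um\n")
  cat("  dose:", format(x$n_beads, big.mark = ","), "beads in",
      x$aqueous_volume_ul, "ul\n")
  cat("  bins:", x$bin_width_pl, "pL | truncated fit:", x$truncated,
      "| mu in [", x$mu_lower, ",", x$mu_upper, "] | pooling:", x$pooling,
      "\n")
  invisible(x)
}

#' Read and write experiment configurations as flat key = value text
#'
#' The on-disk format is one `key = value` line per field; numeric values
#' round-trip exactly (the study layer heights 8.4 and 7.2 um are preserved
#' bit-for-bit).
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  fields <- vapply(config, function(v) {
    if (is.numeric(v)) formatC(v, digits = 15, format = "g") else as.character(v)
  }, character(1))
  writeLines(paste(names(config), "=", fields), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  get <- function(key, as = as.numeric) {
    i <- match(key, keys)
    if (is.na(i)) stop("config missing key `", key, "`", call. = FALSE)
    as(vals[i])
  }
  experiment_config(layer_height_um = get("layer_height_um"),
                    n_beads = get("n_beads"),
                    aqueous_volume_ul = get("aqueous_volume_ul"),
                    bin_width_pl = get("bin_width_pl"),
                    truncated = get("truncated", as.logical),
                    mu_lower = get("mu_lower"),
                    mu_upper = get("mu_upper"),
                    pooling = get("pooling", identity))
}
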