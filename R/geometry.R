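#' Slab-confinement chamber geometry
#'
#' When an emulsion aliquot is sandwiched between a slide and a coverslip, the
#' liquid layer height `h` sets the measurement geometry: droplets with
#' in-plane diameter `d <= h` sit undeformed as spheres, while larger droplets
#' are squished into (approximately) cylinders of height `h`. The two
#' oil-surfactant systems characterised with this package had layer heights of
#' 8.4 um (Abil EM 90 in mineral oil) and 7.2 um (FluoSurf in HFE 7500).
#'
#' @param layer_height_um liquid layer height between slide and coverslip, in
#'   micrometres. Must be a single positive number.
#' @return an object of class `chamber_geometry`.
#' @seealso [volume_from_diameter()], [diameter_from_volume()]
#' @examples
#' chamber_geometry(8.4)
#' @export
chamber_geometry <- function(layer_height_um) {
  .check_positive_scalar(layer_height_um, "layer_height_um")
  structure(list(layer_height_um = layer_height_um), class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("Slab-confinement geometry: layer height", x$layer_height_um, "um\n")
  invisible(x)
}

#' Droplet volume from measured in-plane diameter under slab confinement
#'
#' Applies the confined-droplet volume rule: droplets with diameter `d` at
#' most the layer height `h` are treated as spheres, `V = (pi/6) d^3`;
#' droplets wider than the layer are treated as cylinders of height `h`,
#' `V = pi (d/2)^2 h`. A droplet whose diameter equals the layer height
#' exactly fits the gap undeformed, so the tie is assigned to the sphere
#' regime. The rule is deliberately discontinuous at `d = h` (the cylinder
#' formula exceeds the sphere formula there by a factor 1.5); the regime is
#' returned alongside the volume so boundary cases can be audited.
#'
#' @param diameter_um numeric vector of in-plane droplet diameters (um), all
#'   positive.
#' @param geometry a [chamber_geometry()].
#' @return a data frame with columns `volume_pl` (droplet volume, pL) and
#'   `shape_regime` (`"sphere"` or `"cylinder"`), one row per diameter.
#' @examples
#' g <- chamber_geometry(7.2)
#' volume_from_diameter(c(5, 20), g)
#' @export
volume_from_diameter <- function(diameter_um, geometry) {
  if (!inherits(geometry, "chamber_geometry")) {
    stop("`geometry` must be a chamber_geometry object", call. = FALSE)
  }
  if (!is.numeric(diameter_um) || length(diameter_um) == 0L ||
      any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("`diameter_um` must be positive finite numbers", call. = FALSE)
  }
  h <- geometry$layer_height_um
  sphere <- diameter_um <= h
  v_um3 <- ifelse(sphere,
                  pi / 6 * diameter_um^3,
                  pi / 4 * diameter_um^2 * h)
  data.frame(volume_pl = um3_to_pl(v_um3),
             shape_regime = ifelse(sphere, "sphere", "cylinder"),
             stringsAsFactors = FALSE)
}

#' In-plane diameter from droplet volume (measurement model)
#'
#' Exact inverse of [volume_from_diameter()] under the same regime rule, used
#' by the simulator to render observed diameters from true droplet volumes.
#' Volumes up to the boundary sphere volume `(pi/6) h^3` invert through the
#' sphere formula; larger volumes invert through the cylinder formula. The
#' forward rule's discontinuity leaves a gap of volumes in
#' `((pi/6) h^3, (pi/4) h^3]` with no exact preimage; these are mapped through
#' the cylinder inverse (yielding a diameter just below `h`), mirroring how a
#' slightly-squished droplet of such a volume would present in-plane. Away
#' from the boundary the round trip `d -> V -> d` is exact to floating-point
#' precision.
#'
#' @param volume_pl numeric vector of droplet volumes (pL), all positive.
#' @param geometry a [chamber_geometry()].
#' @return numeric vector of in-plane diameters (um).
#' @examples
#' g <- chamber_geometry(7.2)
#' diameter_from_volume(2.261947, g)  # ~20 um, cylinder regime
#' @export
diameter_from_volume <- function(volume_pl, geometry) {
  if (!inherits(geometry, "chamber_geometry")) {
    stop("`geometry` must be a chamber_geometry object", call. = FALSE)
  }
  if (!is.numeric(volume_pl) || length(volume_pl) == 0L ||
      any(!is.finite(volume_pl)) || any(volume_pl <= 0)) {
    stop("`volume_pl` must be positive finite numbers", call. = FALSE)
  }
  h <- geometry$layer_height_um
  v_um3 <- pl_to_um3(volume_pl)
  v_sphere_max <- pi / 6 * h^3
  ifelse(v_um3 <= v_sphere_max,
         (6 * v_um3 / pi)^(1 / 3),
         2 * sqrt(v_um3 / (pi * h)))
}
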