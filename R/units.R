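# Canonical units: lengths in um, volumes in um^3 internally and pL at every
# public interface, doses in beads per ul. All conversions live here.

.UM3_PER_PL <- 1000    # 1 pL = 1000 um^3
.PL_PER_UL <- 1e6      # 1 ul = 10^6 pL
.AVOGADRO <- 6.02214076e23

#' Unit conversions between cubic micrometres, picolitres and microlitres
#'
#' A droplet measured in micrometres has a volume naturally expressed in
#' cubic micrometres; 1000 um^3 = 1 pL and 10^6 pL = 1 ul. These helpers are
#' the single place unit conversions happen in the package.
#'
#' @param x numeric vector of volumes.
#' @return numeric vector in the target unit.
#' @examples
#' um3_to_pl(1000)  # 1 pL
#' ul_to_pl(100)    # 1e8 pL
#' @export
um3_to_pl <- function(x) x / .UM3_PER_PL

#' @rdname um3_to_pl
#' @export
pl_to_um3 <- function(x) x * .UM3_PER_PL

#' @rdname um3_to_pl
#' @export
ul_to_pl <- function(x) x * .PL_PER_UL

.check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}
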