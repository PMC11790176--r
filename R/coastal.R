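# Shelf-inclination model of coastal territorial loss under sea-level rise.
#
# For a planar shelf of inclination theta, a unit rise of mean relative sea
# level submerges a strip of surface length 1/sin(theta): the shallower the
# shelf, the larger the territorial loss. The model reproduces the printed
# comparison of the Sao Paulo/Parana (25 deg), Santa Catarina (45 deg) and
# Rio de Janeiro (70 deg) submerged-platform profiles.

#' Relative territorial loss per unit sea-level rise
#'
#' `csc(theta) = 1 / sin(theta)` for a shelf of average inclination `theta`
#' between present sea level and the -100 m isopleth.
#'
#' @param inclination_deg inclination in degrees, in `(0, 90]`.
#' @return Dimensionless loss factor (1 at 90 degrees, 2 at 30 degrees).
#' @export
loss_per_rise <- function(inclination_deg) {
  if (any(!is.finite(inclination_deg)) ||
      any(inclination_deg <= 0 | inclination_deg > 90)) {
    stop("inclination must be in (0, 90] degrees")
  }
  1 / sin(inclination_deg * pi / 180)
}

#' Percentage increase in territorial loss relative to a reference shelf
#'
#' `100 * (loss(p) / loss(reference) - 1)`, rounded to the nearest integer
#' percent.
#'
#' @param inclination_deg shelf inclination, degrees.
#' @param reference_deg reference shelf inclination, degrees.
#' @return Integer percent.
#' @examples
#' loss_increase_pct(25, 70)  # 122
#' @export
loss_increase_pct <- function(inclination_deg, reference_deg) {
  ratio <- loss_per_rise(inclination_deg) / loss_per_rise(reference_deg)
  as.integer(round(100 * (ratio - 1)))
}
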