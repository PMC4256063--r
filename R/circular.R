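## Circular helpers. All angles are in degrees with 0 = vertical-upward and
## positive values clockwise (rightward of vertical); stored wrapped to
## (-180, 180].

#' Wrap angles to (-180, 180]
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(0, 180, -180, 190, 360))
#' @export
wrap_angle <- function(angle) {
  180 - ((180 - angle) %% 360)
}

#' Circular summary statistics for angles in degrees
#'
#' `circ_mean()` returns the direction of the mean resultant vector,
#' `circ_rho()` the mean resultant length, and `circ_sd()` the circular
#' standard deviation `sqrt(-2 log rho)` converted to degrees. For a wrapped
#' normal distribution the circular SD equals the standard deviation of the
#' generating normal, which is what makes it the natural scale for external
#' direction noise.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return A single number: mean direction in degrees in (-180, 180]
#'   (`circ_mean`), resultant length in \[0, 1\] (`circ_rho`), or circular SD
#'   in degrees (`circ_sd`).
#' @examples
#' x <- c(-10, 0, 10)
#' circ_mean(x)
#' circ_sd(x)
#' @export
circ_mean <- function(angle) {
  rad <- angle * pi / 180
  wrap_angle(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

#' @rdname circ_mean
#' @export
circ_rho <- function(angle) {
  rad <- angle * pi / 180
  sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
}

#' @rdname circ_mean
#' @export
circ_sd <- function(angle) {
  rho <- circ_rho(angle)
  if (rho <= 0) {
    return(Inf)
  }
  sqrt(-2 * log(rho)) * 180 / pi
}
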