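# Destruction-replenishment microbubble kinetics.
#
# After a high-energy destruction pulse clears microbubbles from the imaging
# plane, video intensity in a perfused compartment recovers towards a plateau.
# We model this with the standard mono-exponential replenishment curve
#   I(t) = baseline                                   for t <  t0
#   I(t) = baseline + A * (1 - exp(-beta * (t - t0))) for t >= t0
# where A is the plateau enhancement (video-intensity units on the 8-bit
# 0-255 scale), beta the replenishment rate (1/s) and t0 the time of the
# destruction pulse. The plateau A is what the MVE statistic estimates.

#' Replenishment kinetics parameters
#'
#' Bundle of parameters for the mono-exponential destruction-replenishment
#' curve of one tissue compartment.
#'
#' @param baseline Pre-contrast (background) video intensity, >= 0, on the
#'   0-255 scale.
#' @param amplitude Plateau enhancement A above baseline, >= 0.
#' @param rate Replenishment rate beta in 1/s, > 0.
#' @param onset_time Time of the destruction pulse t0 in seconds, >= 0.
#' @return An object of class `kinetics_params`.
#' @export
#' @examples
#' kp <- kinetics_params(baseline = 10, amplitude = 40, rate = 0.5)
#' replenishment_intensity(kp, c(0, 2, 100))
kinetics_params <- function(baseline, amplitude, rate, onset_time = 0) {
  if (!is_number(baseline) || baseline < 0)
    ceus_stop("baseline must be a single number >= 0", "invalid_parameter")
  if (!is_number(amplitude) || amplitude < 0)
    ceus_stop("amplitude must be a single number >= 0", "invalid_parameter")
  if (!is_number(rate) || rate <= 0)
    ceus_stop("rate must be a single number > 0", "invalid_parameter")
  if (!is_number(onset_time) || onset_time < 0)
    ceus_stop("onset_time must be a single number >= 0", "invalid_parameter")
  structure(
    list(baseline = baseline, amplitude = amplitude, rate = rate,
         onset_time = onset_time),
    class = "kinetics_params"
  )
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "Replenishment kinetics: baseline %.4g, amplitude %.4g, rate %.4g /s, onset %.4g s\n",
    x$baseline, x$amplitude, x$rate, x$onset_time))
  invisible(x)
}

#' Evaluate the replenishment curve
#'
#' Video intensity of a compartment at times `t`: the baseline before the
#' destruction pulse, then a mono-exponential rise towards
#' `baseline + amplitude`. The curve is monotone non-decreasing and bounded
#' by `baseline + amplitude`.
#'
#' @param params A [kinetics_params()] object.
#' @param t Numeric vector of times in seconds, all >= 0.
#' @return Numeric vector of video intensities, same length as `t`.
#' @export
replenishment_intensity <- function(params, t) {
  stopifnot(inherits(params, "kinetics_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    ceus_stop("t must be numeric, finite and >= 0", "invalid_parameter")
  dt <- pmax(t - params$onset_time, 0)
  params$baseline + params$amplitude * (1 - exp(-params$rate * dt))
}
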