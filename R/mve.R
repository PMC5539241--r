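# Maximal video-intensity enhancement (MVE) and its luminal normalization:
# the headline quantification. MVE is the peak of the (optionally smoothed)
# time-intensity curve minus the background video intensity; normalized MVE
# divides the adventitial MVE by the luminal MVE from a reference ROI drawn
# proximal to the lesion, giving a dimensionless proxy for vasa-vasorum
# density that is robust to gain settings.

#' Compute the maximal video-intensity enhancement of a TIC
#'
#' Peak intensity is the maximum of the curve; `peak_time` is the timestamp
#' of the earliest frame attaining it (deterministic tie-break). MVE is
#' `peak - background`. A negative MVE (background exceeding the peak, as
#' can happen in pure-noise curves) is reported as-is with a warning and a
#' `"negative_mve"` status rather than clamped, so the statistic's
#' distribution is not artificially truncated.
#'
#' @param x A [tic()].
#' @param background Background video intensity to subtract; usually from
#'   [estimate_background()].
#' @return An object of class `mve_result` with fields `roi_label`,
#'   `peak_intensity`, `background_intensity`, `mve`, `peak_time`,
#'   `status` and the TIC's smoothing descriptor.
#' @export
compute_mve <- function(x, background) {
  stopifnot(inherits(x, "tic"))
  if (!is_number(background))
    ceus_stop("background must be a single finite number", "invalid_input")
  if (length(x$intensities) < 1L)
    ceus_stop("TIC is empty", "invalid_input")
  k <- which.max(x$intensities) # earliest frame wins ties
  peak <- x$intensities[k]
  mve <- peak - background
  status <- "ok"
  if (mve < 0) {
    status <- "negative_mve"
    warning(sprintf("negative MVE (%.4g) in ROI '%s': background exceeds peak",
                    mve, x$roi_label), call. = FALSE)
  }
  structure(
    list(roi_label = x$roi_label, peak_intensity = peak,
         background_intensity = background, mve = mve,
         peak_time = x$times[k], status = status, smoothing = x$smoothing),
    class = "mve_result"
  )
}

#' @export
print.mve_result <- function(x, ...) {
  cat(sprintf("MVE ('%s'): peak %.4g at %.3g s, background %.4g -> MVE %.4g [%s]\n",
              x$roi_label, x$peak_intensity, x$peak_time,
              x$background_intensity, x$mve, x$status))
  invisible(x)
}

#' Background estimation plus MVE in one step
#'
#' Convenience wrapper: estimates the background from the curve's
#' pre-destruction (or pre-onset) frames, optionally smooths, then computes
#' the MVE.
#'
#' @param x A [tic()].
#' @param reference_window Optional background window passed to
#'   [estimate_background()].
#' @param smooth_window Odd moving-average width (1 = no smoothing).
#' @return An `mve_result`.
#' @export
mve_from_tic <- function(x, reference_window = NULL, smooth_window = 1L) {
  bg <- estimate_background(x, reference_window)
  if (smooth_window > 1L) x <- smooth_tic(x, smooth_window)
  compute_mve(x, bg)
}

#' Normalized maximal video-intensity enhancement
#'
#' The adventitial enhancement divided by the luminal enhancement of the
#' reference ROI. By default both numerator and denominator are
#' background-subtracted MVEs (`variant = "subtracted"`), so the ratio does
#' not depend on tissue baseline or global gain; `variant = "raw_max"`
#' instead forms the ratio of raw peak intensities, for sensitivity
#' analysis.
#'
#' @param adventitia,lumen `mve_result` objects for the two ROIs.
#' @param variant `"subtracted"` (default) or `"raw_max"`.
#' @return An object of class `normalized_mve` with fields `value`,
#'   `adventitia_mve`, `lumen_mve` and `variant`.
#' @export
normalized_mve <- function(adventitia, lumen,
                           variant = c("subtracted", "raw_max")) {
  stopifnot(inherits(adventitia, "mve_result"), inherits(lumen, "mve_result"))
  variant <- match.arg(variant)
  num <- if (variant == "subtracted") adventitia$mve else adventitia$peak_intensity
  den <- if (variant == "subtracted") lumen$mve else lumen$peak_intensity
  if (!is.finite(den) || den <= 0)
    ceus_stop("luminal enhancement is not positive: failed luminal reference",
              "degenerate_reference")
  structure(
    list(value = num / den, adventitia_mve = num, lumen_mve = den,
         variant = variant),
    class = "normalized_mve"
  )
}

#' @export
print.normalized_mve <- function(x, ...) {
  cat(sprintf("Normalized MVE (%s): %.4g (adventitia %.4g / lumen %.4g)\n",
              x$variant, x$value, x$adventitia_mve, x$lumen_mve))
  invisible(x)
}
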