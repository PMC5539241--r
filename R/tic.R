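# Time-intensity curves: mean video intensity within one ROI per frame.

#' Time-intensity curve container
#'
#' @param times Numeric vector of frame times in seconds.
#' @param intensities Mean video intensity per frame, within [0, 255].
#' @param roi_label Label of the ROI the curve was read from.
#' @param n_pixels Number of pixels in the rasterized ROI mask.
#' @param smoothing Smoothing descriptor: `"none"` or
#'   `"moving-average(w)"`.
#' @param destruction_time Destruction-pulse time carried over from the
#'   cine loop (`NA` when absent).
#' @return An object of class `tic`.
#' @export
tic <- function(times, intensities, roi_label, n_pixels,
                smoothing = "none", destruction_time = NA_real_) {
  if (length(times) != length(intensities) || length(times) < 1L)
    ceus_stop("times and intensities must be equal-length, non-empty",
              "invalid_parameter")
  if (any(!is.finite(intensities)) || min(intensities) < 0 || max(intensities) > 255)
    ceus_stop("TIC intensities must be finite and within [0, 255]",
              "invalid_parameter")
  if (!is_count(n_pixels))
    ceus_stop("n_pixels must be a positive integer", "invalid_parameter")
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         roi_label = roi_label, n_pixels = as.integer(n_pixels),
         smoothing = smoothing, destruction_time = destruction_time),
    class = "tic"
  )
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf(
    "Time-intensity curve ('%s', %d px, smoothing %s): %d frames, intensity %.4g-%.4g\n",
    x$roi_label, x$n_pixels, x$smoothing, length(x$times),
    min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
as.data.frame.tic <- function(x, ...) {
  data.frame(time_s = x$times, mean_intensity = x$intensities,
             roi_label = x$roi_label, n_pixels = x$n_pixels,
             smoothing = x$smoothing, stringsAsFactors = FALSE)
}

#' Extract the time-intensity curve of an ROI from a cine loop
#'
#' For each frame, the arithmetic mean of the video intensity over the
#' pixels of the rasterized ROI mask. Times are copied from the loop's
#' timestamps; no smoothing is applied.
#'
#' @param cine A [cine_loop()].
#' @param roi An [roi_polygon()].
#' @return A [tic()].
#' @export
#' @examples
#' geom <- phantom_geometry()
#' loop <- render_cine_loop(geom,
#'   kinetics_params(8, 120, 1.5, 2), kinetics_params(12, 60, 0.5, 2),
#'   noise_sd = 0, duration = 10)
#' lum <- extract_tic(loop, default_rois(geom)$lumen)
#' max(lum$intensities)
extract_tic <- function(cine, roi) {
  stopifnot(inherits(cine, "cine_loop"), inherits(roi, "roi_polygon"))
  d <- dim(cine$frames)
  mask <- rasterize_roi(roi, d[1:2])
  idx <- which(mask)
  fm <- matrix(cine$frames, d[1] * d[2], d[3])
  means <- colMeans(fm[idx, , drop = FALSE])
  tic(cine$timestamps, means, roi$label, length(idx),
      smoothing = "none", destruction_time = cine$destruction_time)
}

#' Smooth a time-intensity curve with a centered moving average
#'
#' Centered moving average of odd width `window`, with edge truncation:
#' near the boundaries the window shrinks to the frames actually available,
#' so the output has the same length as the input. `window = 1` is the
#' identity. The smoothing descriptor is recorded on the returned curve so
#' downstream peak statistics stay auditable.
#'
#' @param x A [tic()].
#' @param window Odd integer window width, `1 <= window <= length(x$times)`.
#' @return A [tic()] with updated intensities and smoothing metadata.
#' @export
smooth_tic <- function(x, window) {
  stopifnot(inherits(x, "tic"))
  n <- length(x$intensities)
  if (!is_count(window) || window %% 2 == 0 || window > n)
    ceus_stop("window must be an odd integer between 1 and the number of frames",
              "invalid_parameter")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x$intensities))
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  tic(x$times, sm, x$roi_label, x$n_pixels,
      smoothing = sprintf("moving-average(%d)", window),
      destruction_time = x$destruction_time)
}

#' Estimate the background video intensity of a TIC
#'
#' Mean TIC value over the frames whose timestamp falls in the half-open
#' reference window `[start, end)`. By default the window is everything
#' strictly before the destruction pulse; when the curve carries no
#' destruction time, frames before the first-enhancement onset are used
#' (onset = first frame exceeding the curve minimum by 10% of the curve's
#' dynamic range).
#'
#' @param x A [tic()].
#' @param reference_window Optional numeric `c(start, end)` in seconds.
#' @return A single background intensity value.
#' @export
estimate_background <- function(x, reference_window = NULL) {
  stopifnot(inherits(x, "tic"))
  if (is.null(reference_window)) {
    if (!is.na(x$destruction_time)) {
      keep <- x$times < x$destruction_time
      if (!any(keep))
        ceus_stop("no frames precede the destruction pulse; give an explicit reference_window",
                  "invalid_window")
    } else {
      rng <- range(x$intensities)
      thresh <- rng[1] + 0.1 * (rng[2] - rng[1])
      onset <- which(x$intensities > thresh)[1]
      if (is.na(onset) || onset == 1L)
        ceus_stop("cannot locate a pre-enhancement baseline; give an explicit reference_window",
                  "invalid_window")
      keep <- seq_along(x$times) < onset
    }
  } else {
    if (length(reference_window) != 2L || reference_window[1] >= reference_window[2])
      ceus_stop("reference_window must be c(start, end) with start < end",
                "invalid_window")
    keep <- x$times >= reference_window[1] & x$times < reference_window[2]
    if (!any(keep))
      ceus_stop("reference window contains no frames", "invalid_window")
  }
  mean(x$intensities[keep])
}

#' Write extracted TICs to CSV
#'
#' One row per frame with columns `time_s`, `mean_intensity`, `roi_label`,
#' `n_pixels`, `smoothing`; several curves may share one file.
#'
#' @param tics A [tic()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tic_csv <- function(tics, path) {
  if (inherits(tics, "tic")) tics <- list(tics)
  df <- do.call(rbind, lapply(tics, as.data.frame))
  df$time_s <- format_num(df$time_s)
  df$mean_intensity <- format_num(df$mean_intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read TICs written by [write_tic_csv()]
#'
#' @param path CSV path.
#' @return A named list of [tic()] objects, one per distinct `roi_label`.
#' @export
read_tic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$roi_label), function(d) {
    tic(d$time_s, d$mean_intensity, d$roi_label[1], d$n_pixels[1],
        smoothing = d$smoothing[1])
  })
  out
}
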