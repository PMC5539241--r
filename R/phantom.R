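# Long-axis vessel phantom: an idealized 2D long-axis view of a carotid
# artery as horizontal bands -- the echolucent lumen flanked above and below
# by adventitial bands (where the vasa vasorum lives), an optional plaque
# polygon protruding into the lumen, and surrounding tissue background at a
# constant grayscale level.

#' Vessel phantom geometry
#'
#' Compartment layout for the synthetic long-axis carotid phantom. Rows and
#' columns are 1-based inclusive pixel ranges. The two adventitia bands
#' flank the lumen band; the optional plaque polygon must lie inside the
#' lumen band and may not touch the adventitia.
#'
#' @param height,width Image size in pixels.
#' @param lumen_rows Integer `c(first, last)` rows of the lumen band.
#' @param adventitia_above,adventitia_below Row ranges of the two
#'   adventitial bands.
#' @param plaque_polygon Optional [roi_polygon()] with label `"plaque"`.
#' @param background_level Constant tissue grayscale level of all remaining
#'   pixels, in [0, 255].
#' @return An object of class `phantom_geometry` carrying precomputed
#'   logical compartment masks (`$masks`).
#' @export
#' @examples
#' geom <- phantom_geometry()
#' sapply(geom$masks, sum)
phantom_geometry <- function(height = 48, width = 64,
                             lumen_rows = c(21, 28),
                             adventitia_above = c(15, 20),
                             adventitia_below = c(29, 34),
                             plaque_polygon = NULL,
                             background_level = 20) {
  stopifnot(is_count(height), is_count(width))
  bands <- list(lumen = lumen_rows, adv_above = adventitia_above,
                adv_below = adventitia_below)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] > b[2] || b[1] < 1 || b[2] > height)
      ceus_stop(sprintf("band '%s' must be within image rows 1..%d", nm, height),
                "configuration_error")
  }
  rows_of <- function(b) seq.int(b[1], b[2])
  if (length(intersect(rows_of(lumen_rows), c(rows_of(adventitia_above),
                                              rows_of(adventitia_below)))) ||
      length(intersect(rows_of(adventitia_above), rows_of(adventitia_below))))
    ceus_stop("lumen and adventitia bands must be disjoint", "configuration_error")
  if (!is_number(background_level) || background_level < 0 || background_level > 255)
    ceus_stop("background_level must be within [0, 255]", "configuration_error")

  band_mask <- function(b) {
    m <- matrix(FALSE, height, width)
    m[rows_of(b), ] <- TRUE
    m
  }
  lumen <- band_mask(lumen_rows)
  adventitia <- band_mask(adventitia_above) | band_mask(adventitia_below)
  plaque <- matrix(FALSE, height, width)
  if (!is.null(plaque_polygon)) {
    stopifnot(inherits(plaque_polygon, "roi_polygon"))
    if (plaque_polygon$label != "plaque")
      ceus_stop("plaque_polygon must carry label 'plaque'", "configuration_error")
    plaque <- rasterize_roi(plaque_polygon, c(height, width))
    if (any(plaque & adventitia))
      ceus_stop("plaque region must not intersect the adventitia bands",
                "configuration_error")
    if (any(plaque & !lumen))
      ceus_stop("plaque region must lie inside the lumen band",
                "configuration_error")
    lumen <- lumen & !plaque
  }
  if (!any(lumen)) ceus_stop("lumen compartment is empty", "configuration_error")
  background <- !(lumen | adventitia | plaque)
  structure(
    list(height = height, width = width,
         lumen_rows = lumen_rows, adventitia_above = adventitia_above,
         adventitia_below = adventitia_below, plaque_polygon = plaque_polygon,
         background_level = background_level,
         masks = list(lumen = lumen, adventitia = adventitia,
                      plaque = plaque, background = background)),
    class = "phantom_geometry"
  )
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("Vessel phantom %d x %d px: lumen rows %d-%d, adventitia %d-%d / %d-%d%s\n",
              x$height, x$width, x$lumen_rows[1], x$lumen_rows[2],
              x$adventitia_above[1], x$adventitia_above[2],
              x$adventitia_below[1], x$adventitia_below[2],
              if (any(x$masks$plaque))
                sprintf(", plaque of %d px", sum(x$masks$plaque)) else ""))
  invisible(x)
}

#' Default measurement ROIs for a vessel phantom
#'
#' Rectangular ROIs mirroring how the measurement is drawn on real loops:
#' the adventitia ROI sits in the deeper (below-lumen) adventitial band, and
#' the luminal normalization ROI is drawn in the proximal (left) part of the
#' lumen, away from any plaque. ROI placement is always an input to the
#' pipeline; these are merely the phantom's canonical choices.
#'
#' @param geometry A [phantom_geometry()].
#' @return Named list with [roi_polygon()] elements `adventitia` and
#'   `lumen` (plus `plaque` when the phantom has one).
#' @export
default_rois <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  W <- geometry$width
  adv <- rect_roi("adventitia", geometry$adventitia_below,
                  c(max(1, round(W * 0.12)), round(W * 0.88)))
  lum <- rect_roi("lumen", geometry$lumen_rows,
                  c(max(1, round(W * 0.06)), round(W * 0.31)))
  out <- list(adventitia = adv, lumen = lum)
  if (!is.null(geometry$plaque_polygon)) out$plaque <- geometry$plaque_polygon
  out
}

#' Render a synthetic CEUS cine loop from a vessel phantom
#'
#' Every pixel's noiseless value at frame time t is its compartment's
#' replenishment curve evaluated at t (background pixels hold the constant
#' tissue level); independent additive Gaussian noise of standard deviation
#' `noise_sd` is then applied per pixel and frame and the result clipped to
#' the 8-bit range [0, 255]. Frames are taken at `0, 1/frame_rate, ...`
#' giving `floor(duration * frame_rate) + 1` frames.
#'
#' @param geometry A [phantom_geometry()].
#' @param lumen_kinetics,adventitia_kinetics [kinetics_params()] for the
#'   two vascular compartments.
#' @param plaque_kinetics Optional [kinetics_params()]; required when the
#'   geometry contains a plaque region.
#' @param noise_sd Additive Gaussian noise SD in video-intensity units.
#' @param frame_rate Frames per second.
#' @param duration Acquisition length in seconds (>= 0; 0 gives a single
#'   frame at t = 0).
#' @param seed Optional integer seed for the noise draws.
#' @param destruction_time Destruction-pulse time recorded in the loop;
#'   defaults to the lumen onset time.
#' @return A [cine_loop()].
#' @export
render_cine_loop <- function(geometry, lumen_kinetics, adventitia_kinetics,
                             plaque_kinetics = NULL, noise_sd = 0,
                             frame_rate = 5, duration = 22, seed = NULL,
                             destruction_time = lumen_kinetics$onset_time) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(lumen_kinetics, "kinetics_params"),
            inherits(adventitia_kinetics, "kinetics_params"))
  if (!is_number(duration) || duration < 0)
    ceus_stop("duration must be >= 0", "invalid_parameter")
  if (!is_number(frame_rate) || frame_rate <= 0)
    ceus_stop("frame_rate must be > 0", "invalid_parameter")
  if (!is_number(noise_sd) || noise_sd < 0)
    ceus_stop("noise_sd must be >= 0", "invalid_parameter")
  if (any(geometry$masks$plaque) && is.null(plaque_kinetics))
    ceus_stop("geometry has a plaque compartment but no plaque_kinetics given",
              "configuration_error")

  n_frames <- floor(duration * frame_rate) + 1L
  times <- (seq_len(n_frames) - 1L) / frame_rate
  H <- geometry$height; W <- geometry$width
  masks <- geometry$masks

  lumen_curve <- replenishment_intensity(lumen_kinetics, times)
  adv_curve <- replenishment_intensity(adventitia_kinetics, times)
  plq_curve <- if (!is.null(plaque_kinetics))
    replenishment_intensity(plaque_kinetics, times) else rep(0, n_frames)

  frames <- array(0, dim = c(H, W, n_frames))
  base <- matrix(geometry$background_level, H, W)
  for (k in seq_len(n_frames)) {
    f <- base
    f[masks$lumen] <- lumen_curve[k]
    f[masks$adventitia] <- adv_curve[k]
    if (any(masks$plaque)) f[masks$plaque] <- plq_curve[k]
    frames[, , k] <- f
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(frames), 0, noise_sd))
    frames <- frames + array(noise, dim = dim(frames))
  }
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255
  dt <- if (destruction_time >= times[1] && destruction_time <= times[n_frames])
    destruction_time else NA_real_
  cine_loop(frames, times, dt)
}
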