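# Synthetic graded-atherosclerosis cohort.
#
# Six groups mirror the rabbit-model design: group 0 controls on normal
# chow, groups 1-3 on a high-fat diet for increasing durations, group 4
# accelerated (diet + endothelial injury) with small plaque, and group 5
# accelerated with a large, near-occlusive plaque. A latent adventitial
# vasa-vasorum density d >= 0 increases across groups and drives both the
# adventitial CEUS enhancement (amplitude = gain * d * per-animal lognormal
# multiplier) and the expected CD31/VEGF microvessel counts
# (lambda = a + b * d, two independent Poisson observers averaged). Group 5
# is imaged but, as in the underlying study design, no normalized MVE is
# computed for it: it exists for direct observation and histology only.

#' Group specification for the cohort simulator
#'
#' @param group_id Integer 0-5.
#' @param n_animals Animals in the group.
#' @param vv_density Latent adventitial vasa-vasorum density d >= 0
#'   (dimensionless). Under the default gain calibration, d equals the
#'   expected normalized MVE of the group.
#' @param lumen_amplitude Luminal plateau enhancement in video-intensity
#'   units.
#' @param plaque_present,plaque_occlusive Plaque flags; only groups 4 and 5
#'   carry plaque, and only group 5 an occlusive one.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(group_id, n_animals, vv_density,
                       lumen_amplitude = 120,
                       plaque_present = FALSE, plaque_occlusive = FALSE) {
  if (!is_number(group_id) || group_id < 0 || group_id > 5 ||
      group_id != floor(group_id))
    ceus_stop("group_id must be an integer 0..5", "configuration_error")
  if (!is_count(n_animals))
    ceus_stop("n_animals must be a positive integer", "configuration_error")
  if (!is_number(vv_density) || vv_density < 0)
    ceus_stop("vv_density must be >= 0", "configuration_error")
  if (plaque_present && !group_id %in% c(4, 5))
    ceus_stop("plaque_present is reserved for groups 4 and 5",
              "configuration_error")
  if (plaque_occlusive && group_id != 5)
    ceus_stop("plaque_occlusive is reserved for group 5", "configuration_error")
  structure(list(group_id = as.integer(group_id),
                 n_animals = as.integer(n_animals),
                 vv_density = vv_density, lumen_amplitude = lumen_amplitude,
                 plaque_present = isTRUE(plaque_present),
                 plaque_occlusive = isTRUE(plaque_occlusive)),
            class = "group_spec")
}

#' Default six-group design
#'
#' Latent densities are calibrated so that, with the default amplitude gain,
#' the expected normalized MVE per group equals
#' 0.146, 0.278, 0.435, 0.660, 0.660 for groups 0-4 (group 5, with density
#' 1.2, is histology-only). Densities are non-decreasing in group id.
#'
#' @param n_per_group Animals per group (recycled to length 6).
#' @param include_group5 Keep the histology-only occlusive-plaque group.
#' @return List of [group_spec()]s.
#' @export
default_group_specs <- function(n_per_group = 10, include_group5 = TRUE) {
  dens <- c(0.146, 0.278, 0.435, 0.660, 0.660, 1.2)
  n <- rep_len(n_per_group, 6)
  specs <- lapply(0:5, function(g) {
    group_spec(g, n[g + 1], dens[g + 1],
               plaque_present = g %in% c(4, 5), plaque_occlusive = g == 5)
  })
  if (!include_group5) specs <- specs[1:5]
  specs
}

#' Cohort simulator configuration
#'
#' All free parameters of the synthetic cohort in one validated object.
#' The density-to-amplitude gain defaults to the luminal amplitude, so the
#' expected adventitia/lumen amplitude ratio of an animal equals its group's
#' latent density. `biological_gsd` is the log-SD of the per-animal
#' lognormal multiplier on adventitial amplitude (mean 1, so group means are
#' unchanged). Histology linkage gives the expected per-marker count as
#' `a + b * density`.
#'
#' @param groups List of [group_spec()]s (densities must be non-decreasing
#'   in group id).
#' @param noise_sd Additive imaging noise SD, video-intensity units.
#' @param frame_rate Frames per second.
#' @param duration Acquisition seconds (with `frame_rate`, >= 2 frames).
#' @param density_to_amplitude_gain Video-intensity units per density unit.
#' @param lumen_rate,adventitia_rate Replenishment rates (1/s): fast
#'   luminal refill, slower adventitial microvascular refill.
#' @param lumen_baseline,adventitia_baseline Pre-contrast intensities.
#' @param onset_time Destruction-pulse time (s); frames before it provide
#'   the background window.
#' @param biological_gsd Log-SD of the per-animal amplitude multiplier.
#' @param histology Per-marker linkage: named list with elements `cd31`
#'   and `vegf`, each `c(a = intercept, b = slope)` in expected counts.
#' @param geometry A [phantom_geometry()].
#' @param cache_tics If `TRUE`, skip pixel rendering and simulate ROI-level
#'   TICs directly (noise SD scaled by sqrt of ROI pixel count); if
#'   `FALSE`, render full cine loops and extract TICs from pixels.
#' @param seed Integer seed; identical seed and config reproduce the cohort
#'   bit-identically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_group_specs(),
                          noise_sd = 4, frame_rate = 5, duration = 22,
                          density_to_amplitude_gain = 120,
                          lumen_rate = 1.5, adventitia_rate = 0.5,
                          lumen_baseline = 8, adventitia_baseline = 12,
                          onset_time = 2, biological_gsd = 0.35,
                          histology = list(cd31 = c(a = 0, b = 13.57),
                                           vegf = c(a = 0.232, b = 7.315)),
                          geometry = phantom_geometry(),
                          cache_tics = FALSE, seed = 1L) {
  if (!is.list(groups) || length(groups) == 0L ||
      !all(vapply(groups, inherits, TRUE, "group_spec")))
    ceus_stop("groups must be a non-empty list of group_spec objects",
              "configuration_error")
  gid <- vapply(groups, function(g) g$group_id, 1L)
  dens <- vapply(groups, function(g) g$vv_density, 1)
  o <- order(gid)
  if (anyDuplicated(gid))
    ceus_stop("duplicate group ids", "configuration_error")
  if (any(diff(dens[o]) < 0))
    ceus_stop("vv_density must be non-decreasing in group_id",
              "configuration_error")
  if (!is_number(noise_sd) || noise_sd < 0)
    ceus_stop("noise_sd must be >= 0", "configuration_error")
  if (floor(duration * frame_rate) + 1 < 2)
    ceus_stop("duration x frame_rate must give at least 2 frames",
              "configuration_error")
  if (!is_number(density_to_amplitude_gain) || density_to_amplitude_gain < 0)
    ceus_stop("density_to_amplitude_gain must be >= 0", "configuration_error")
  for (mk in c("cd31", "vegf")) {
    hp <- histology[[mk]]
    if (is.null(hp) || length(hp) != 2L || any(hp < 0))
      ceus_stop(sprintf("histology$%s must be c(a, b) with a, b >= 0", mk),
                "configuration_error")
  }
  if (!is_number(onset_time) || onset_time <= 0 || onset_time >= duration)
    ceus_stop("onset_time must lie strictly inside (0, duration) so a background window exists",
              "configuration_error")
  structure(list(groups = groups[o], noise_sd = noise_sd,
                 frame_rate = frame_rate, duration = duration,
                 density_to_amplitude_gain = density_to_amplitude_gain,
                 lumen_rate = lumen_rate, adventitia_rate = adventitia_rate,
                 lumen_baseline = lumen_baseline,
                 adventitia_baseline = adventitia_baseline,
                 onset_time = onset_time, biological_gsd = biological_gsd,
                 histology = histology, geometry = geometry,
                 cache_tics = isTRUE(cache_tics), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate two-observer immunohistochemistry microvessel counts
#'
#' Each observer's count of marker-positive microvessels per cross-section
#' is an independent Poisson draw with mean `lambda = a + b * vv_density`;
#' the analysis value is the arithmetic mean of the observer counts,
#' mirroring the two-independent-observers counting rule.
#'
#' @param vv_density Latent density d >= 0.
#' @param a,b Linkage intercept and slope (expected counts), both >= 0.
#' @param n_observers Number of independent observers (default 2).
#' @param seed Optional seed.
#' @return List with `counts` (per observer) and `mean`.
#' @export
simulate_histology_counts <- function(vv_density, a, b, n_observers = 2L,
                                      seed = NULL) {
  if (!is_number(vv_density) || vv_density < 0)
    ceus_stop("vv_density must be >= 0", "invalid_parameter")
  if (!is_number(a) || a < 0 || !is_number(b) || b < 0)
    ceus_stop("linkage parameters a and b must be >= 0", "invalid_parameter")
  if (!is_count(n_observers))
    ceus_stop("n_observers must be a positive integer", "invalid_parameter")
  lambda <- a + b * vv_density
  counts <- with_seed(seed, stats::rpois(n_observers, lambda))
  list(counts = counts, mean = mean(counts), lambda = lambda)
}

# Kinetics of one simulated animal given its group spec and multiplier.
animal_kinetics <- function(config, spec, multiplier) {
  adv_amp <- config$density_to_amplitude_gain * spec$vv_density * multiplier
  list(
    lumen = kinetics_params(config$lumen_baseline, spec$lumen_amplitude,
                            config$lumen_rate, config$onset_time),
    adventitia = kinetics_params(config$adventitia_baseline, adv_amp,
                                 config$adventitia_rate, config$onset_time),
    plaque = if (spec$plaque_present)
      kinetics_params(config$lumen_baseline, 0.3 * adv_amp,
                      config$adventitia_rate, config$onset_time)
      else NULL,
    adv_amplitude = adv_amp,
    lumen_amplitude = spec$lumen_amplitude
  )
}

# Phantom for one animal: plaque added for groups 4/5 (occlusive plaque
# fills most of the lumen band).
animal_geometry <- function(config, spec) {
  g <- config$geometry
  if (!spec$plaque_present) return(g)
  lr <- g$lumen_rows
  rows <- if (spec$plaque_occlusive) lr + c(0L, 0L) else c(lr[1] + 1L, lr[2] - 1L)
  cols <- if (spec$plaque_occlusive) c(round(g$width * 0.35), round(g$width * 0.95))
          else c(round(g$width * 0.62), round(g$width * 0.9))
  plaque <- rect_roi("plaque", rows, cols)
  phantom_geometry(g$height, g$width, g$lumen_rows, g$adventitia_above,
                   g$adventitia_below, plaque_polygon = plaque,
                   background_level = g$background_level)
}

# Direct ROI-level TIC simulation used when cache_tics = TRUE: the ROI mean
# of iid Gaussian pixel noise is Gaussian with SD noise_sd / sqrt(n_pixels).
simulate_cached_tic <- function(curve, times, label, n_pixels, noise_sd,
                                destruction_time) {
  v <- curve + stats::rnorm(length(times), 0, noise_sd / sqrt(n_pixels))
  v[v < 0] <- 0; v[v > 255] <- 255
  tic(times, v, label, n_pixels, destruction_time = destruction_time)
}

#' Simulate a full graded-atherosclerosis cohort
#'
#' Generates, per animal: a synthetic cine loop (or cached ROI-level TICs),
#' two-observer CD31 and VEGF counts, and ground truth. The measurement
#' pipeline (TIC extraction, pre-destruction background, MVE, luminal
#' normalization) is then applied to produce the per-animal normalized MVE
#' -- except for group 5, whose records carry histology only. Identical
#' config and seed reproduce the output bit-identically.
#'
#' @param config A [cohort_config()].
#' @param keep_loops Keep the rendered `cine_loop` objects in the result
#'   (memory-heavy for large cohorts; TICs are always kept).
#' @return A list of class `ceus_cohort` with elements `cohort` (a
#'   [build_cohort_table()] data.frame), `truth` (per-animal ground truth),
#'   `tics` (per-animal adventitia/lumen TICs), `loops` (optional), `rois`,
#'   and `config`.
#' @export
simulate_cohort <- function(config, keep_loops = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$groups) == 0L)
    ceus_stop("group list is empty", "configuration_error")
  rois <- default_rois(config$geometry)
  shape <- c(config$geometry$height, config$geometry$width)
  n_adv <- sum(rasterize_roi(rois$adventitia, shape))
  n_lum <- sum(rasterize_roi(rois$lumen, shape))
  n_frames <- floor(config$duration * config$frame_rate) + 1L
  times <- (seq_len(n_frames) - 1L) / config$frame_rate
  sdl <- config$biological_gsd

  records <- list(); truth <- list(); tics <- list(); loops <- list()
  with_seed(config$seed, {
    aid <- 0L
    for (spec in config$groups) {
      for (i in seq_len(spec$n_animals)) {
        aid <- aid + 1L
        id <- sprintf("R%03d", aid)
        # mean-1 lognormal biological multiplier on adventitial amplitude
        mult <- stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
        kin <- animal_kinetics(config, spec, mult)
        if (config$cache_tics) {
          adv_tic <- simulate_cached_tic(
            replenishment_intensity(kin$adventitia, times), times,
            "adventitia", n_adv, config$noise_sd, config$onset_time)
          lum_tic <- simulate_cached_tic(
            replenishment_intensity(kin$lumen, times), times,
            "lumen", n_lum, config$noise_sd, config$onset_time)
        } else {
          geom <- animal_geometry(config, spec)
          loop <- render_cine_loop(geom, kin$lumen, kin$adventitia,
                                   plaque_kinetics = kin$plaque,
                                   noise_sd = config$noise_sd,
                                   frame_rate = config$frame_rate,
                                   duration = config$duration,
                                   destruction_time = config$onset_time)
          adv_tic <- extract_tic(loop, rois$adventitia)
          lum_tic <- extract_tic(loop, rois$lumen)
          if (keep_loops) loops[[id]] <- loop
        }
        tics[[id]] <- list(adventitia = adv_tic, lumen = lum_tic)

        nmve <- NA_real_
        if (spec$group_id != 5L) {
          adv_mve <- compute_mve(adv_tic, estimate_background(adv_tic))
          lum_mve <- compute_mve(lum_tic, estimate_background(lum_tic))
          nmve <- normalized_mve(adv_mve, lum_mve)$value
        }
        cd31 <- simulate_histology_counts(spec$vv_density,
                                          config$histology$cd31[["a"]],
                                          config$histology$cd31[["b"]])
        vegf <- simulate_histology_counts(spec$vv_density,
                                          config$histology$vegf[["a"]],
                                          config$histology$vegf[["b"]])
        records[[aid]] <- data.frame(
          animal_id = id, group_id = spec$group_id, nmve = nmve,
          cd31_mean = cd31$mean, vegf_mean = vegf$mean,
          stringsAsFactors = FALSE)
        truth[[aid]] <- data.frame(
          animal_id = id, group_id = spec$group_id,
          true_density = spec$vv_density,
          true_adv_amplitude = kin$adv_amplitude,
          true_lumen_amplitude = kin$lumen_amplitude,
          true_ratio = kin$adv_amplitude / kin$lumen_amplitude,
          lambda_cd31 = cd31$lambda, lambda_vegf = vegf$lambda,
          stringsAsFactors = FALSE)
      }
    }
  })
  structure(
    list(cohort = build_cohort_table(do.call(rbind, records)),
         truth = do.call(rbind, truth), tics = tics,
         loops = if (keep_loops) loops else NULL,
         rois = rois, config = config),
    class = "ceus_cohort")
}

#' @export
print.ceus_cohort <- function(x, ...) {
  tab <- table(x$cohort$group_id)
  cat(sprintf("Synthetic CEUS cohort: %d animals in %d groups (%s)\n",
              nrow(x$cohort), length(tab),
              paste(sprintf("g%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
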