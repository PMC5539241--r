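test_that("MVE is peak minus background with earliest-frame tie-break", {
  x <- tic(0:4, c(12, 30, 60, 60, 40), "adventitia", 10)
  m <- compute_mve(x, background = 12)
  expect_equal(m$mve, 48)
  expect_equal(m$peak_intensity, 60)
  expect_equal(m$peak_time, 2) # first frame attaining the tie

  const <- tic(0:3, rep(15, 4), "lumen", 10)
  expect_equal(compute_mve(const, 15)$mve, 0)
})

test_that("negative MVE is reported with a warning, not clamped", {
  x <- tic(0:3, c(9, 10, 9, 8), "adventitia", 5)
  expect_warning(m <- compute_mve(x, background = 12), "negative MVE")
  expect_equal(m$mve, -2)
  expect_identical(m$status, "negative_mve")
})

test_that("noiseless replenishment recovers the closed-form MVE", {
  geom <- phantom_geometry(height = 16, width = 16, lumen_rows = c(7, 10),
                           adventitia_above = c(4, 6),
                           adventitia_below = c(11, 13))
  # both compartments: baseline 10, amplitude 40 / 80, rate 0.5, onset 0;
  # background window given explicitly since enhancement starts at t = 0
  adv <- kinetics_params(10, 40, 0.5, 0)
  lum <- kinetics_params(10, 80, 0.5, 0)
  loop <- render_cine_loop(geom, lum, adv, noise_sd = 0, frame_rate = 5,
                           duration = 20)
  at <- extract_tic(loop, default_rois(geom)$adventitia)
  m <- compute_mve(at, background = 10)
  expect_equal(m$mve, 40 * (1 - exp(-10)), tolerance = 1e-6)
  # normalized MVE equals the configured amplitude ratio (rates equal, so
  # the saturation factors cancel exactly)
  lt <- extract_tic(loop, default_rois(geom)$lumen)
  nm <- normalized_mve(m, compute_mve(lt, background = 10))
  expect_equal(nm$value, 40 / 80, tolerance = 1e-6)
})

test_that("normalized MVE arithmetic and degenerate reference", {
  adv <- compute_mve(tic(0:2, c(10, 15, 22), "adventitia", 5), 10)
  lum <- compute_mve(tic(0:2, c(10, 40, 70), "lumen", 5), 10)
  expect_equal(normalized_mve(adv, lum)$value, 12 / 60)
  expect_equal(normalized_mve(lum, lum)$value, 1)

  flat <- compute_mve(tic(0:2, rep(10, 3), "lumen", 5), 10)
  expect_error(normalized_mve(adv, flat), class = "degenerate_reference")

  # raw-max sensitivity variant divides raw peaks
  raw <- normalized_mve(adv, lum, variant = "raw_max")
  expect_equal(raw$value, 22 / 70)
})

test_that("normalized MVE is invariant to global affine gain", {
  geom <- phantom_geometry()
  loop <- render_cine_loop(geom, kinetics_params(8, 120, 1.5, 2),
                           kinetics_params(12, 55, 0.5, 2),
                           noise_sd = 3, duration = 22, seed = 77)
  rois <- default_rois(geom)
  tics <- list(adv = extract_tic(loop, rois$adventitia),
               lum = extract_tic(loop, rois$lumen))
  nm0 <- normalized_mve(compute_mve(tics$adv, estimate_background(tics$adv)),
                        compute_mve(tics$lum, estimate_background(tics$lum)))
  affine <- function(x, a, b)
    tic(x$times, a * x$intensities + b, x$roi_label, x$n_pixels,
        destruction_time = x$destruction_time)
  for (ab in list(c(1.4, 6), c(0.55, 2.5))) {
    ta <- affine(tics$adv, ab[1], ab[2]); tl <- affine(tics$lum, ab[1], ab[2])
    nm <- normalized_mve(compute_mve(ta, estimate_background(ta)),
                         compute_mve(tl, estimate_background(tl)))
    expect_equal(nm$value, nm0$value, tolerance = 1e-9)
  }
})

test_that("noiseless normalized MVE is strictly increasing in vv density", {
  geom <- phantom_geometry()
  rois <- default_rois(geom)
  vals <- sapply(c(0.1, 0.25, 0.4, 0.6, 0.9), function(d) {
    loop <- render_cine_loop(geom, kinetics_params(8, 120, 1.5, 2),
                             kinetics_params(12, 120 * d, 0.5, 2),
                             noise_sd = 0, duration = 42)
    at <- extract_tic(loop, rois$adventitia)
    lt <- extract_tic(loop, rois$lumen)
    normalized_mve(compute_mve(at, estimate_background(at)),
                   compute_mve(lt, estimate_background(lt)))$value
  })
  expect_true(all(diff(vals) > 0))
  # with duration >= 20 / rate past onset, recovery is exact to 1e-6
  expect_equal(vals, c(0.1, 0.25, 0.4, 0.6, 0.9), tolerance = 1e-6)
})
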