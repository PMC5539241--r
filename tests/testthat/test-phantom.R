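small_geom <- function() {
  phantom_geometry(height = 16, width = 16, lumen_rows = c(7, 10),
                   adventitia_above = c(4, 6), adventitia_below = c(11, 13),
                   background_level = 20)
}

test_that("noiseless loops reproduce the compartment kinetics exactly", {
  geom <- small_geom()
  lum <- kinetics_params(8, 40, 0.5, 0)
  adv <- kinetics_params(12, 25, 0.3, 0)
  loop <- render_cine_loop(geom, lum, adv, noise_sd = 0, frame_rate = 4,
                           duration = 6)
  expect_identical(dim(loop$frames)[3], 25L) # floor(duration * fps) + 1
  for (k in c(1L, 5L, 25L)) {
    t <- loop$timestamps[k]
    f <- loop$frames[, , k]
    expect_identical(max(abs(f[geom$masks$lumen] -
                             replenishment_intensity(lum, t))), 0)
    expect_identical(max(abs(f[geom$masks$adventitia] -
                             replenishment_intensity(adv, t))), 0)
    expect_true(all(f[geom$masks$background] == 20))
  }
})

test_that("zero duration gives a single all-baseline frame", {
  geom <- small_geom()
  loop <- render_cine_loop(geom, kinetics_params(8, 40, 0.5, 1),
                           kinetics_params(12, 25, 0.3, 1),
                           noise_sd = 0, duration = 0)
  expect_identical(dim(loop$frames)[3], 1L)
  f <- loop$frames[, , 1]
  expect_true(all(f[geom$masks$lumen] == 8))
  expect_true(all(f[geom$masks$adventitia] == 12))
})

test_that("noisy ROI means track the noiseless curve within the CLT bound", {
  geom <- phantom_geometry(height = 64, width = 64, lumen_rows = c(25, 40),
                           adventitia_above = c(17, 24),
                           adventitia_below = c(41, 48))
  lum <- kinetics_params(30, 120, 0.8, 2)
  loop <- render_cine_loop(geom, lum, kinetics_params(30, 60, 0.4, 2),
                           noise_sd = 5, frame_rate = 5, duration = 19.8,
                           seed = 99)
  expect_identical(dim(loop$frames)[3], 100L)
  n_px <- sum(geom$masks$lumen)
  idx <- which(geom$masks$lumen)
  fm <- matrix(loop$frames, 64 * 64, 100)
  means <- colMeans(fm[idx, , drop = FALSE])
  truth <- replenishment_intensity(lum, loop$timestamps)
  expect_true(all(abs(means - truth) <= 3 * 5 / sqrt(n_px)))
})

test_that("noise draws are seed-reproducible", {
  geom <- small_geom()
  args <- list(geom, kinetics_params(8, 40, 0.5, 0),
               kinetics_params(12, 25, 0.3, 0))
  l1 <- do.call(render_cine_loop,
                c(args, noise_sd = 3, duration = 4, seed = 5))
  l2 <- do.call(render_cine_loop,
                c(args, noise_sd = 3, duration = 4, seed = 5))
  l3 <- do.call(render_cine_loop,
                c(args, noise_sd = 3, duration = 4, seed = 6))
  expect_identical(l1$frames, l2$frames)
  expect_false(identical(l1$frames, l3$frames))
})

test_that("invalid geometries are rejected", {
  expect_error(phantom_geometry(lumen_rows = c(21, 60)),
               class = "configuration_error")
  expect_error(phantom_geometry(lumen_rows = c(18, 28)), # overlaps adventitia
               class = "configuration_error")
  # plaque touching the adventitia band
  plq <- roi_polygon("plaque", rbind(c(10, 20), c(30, 20), c(30, 30), c(10, 30)))
  expect_error(phantom_geometry(plaque_polygon = plq),
               class = "configuration_error")
  # plaque present but no plaque kinetics at render time
  plq2 <- roi_polygon("plaque", rbind(c(30, 21), c(50, 21), c(50, 26), c(30, 26)))
  geom <- phantom_geometry(plaque_polygon = plq2)
  expect_error(render_cine_loop(geom, kinetics_params(8, 40, 0.5, 0),
                                kinetics_params(12, 25, 0.3, 0)),
               class = "configuration_error")
})
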