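test_that("TIC extraction reduces constant and single-pixel cases exactly", {
  frames <- array(10, dim = c(6, 6, 4))
  cine <- cine_loop(frames, timestamps = 0:3)
  roi <- roi_polygon("lumen", rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5)))
  expect_equal(extract_tic(cine, roi)$intensities, rep(10, 4))

  frames2 <- array(runif(6 * 6 * 4, 0, 255), dim = c(6, 6, 4))
  cine2 <- cine_loop(frames2, timestamps = 0:3)
  onepx <- roi_polygon("plaque", rbind(c(2, 3), c(3, 3), c(3, 4), c(2, 4)))
  got <- extract_tic(cine2, onepx)
  expect_identical(got$n_pixels, 1L)
  expect_equal(got$intensities, frames2[4, 3, ]) # 0-based (3,2) -> [4,3]
})

test_that("full-frame mean of 0..8 is 4", {
  frames <- array(0:8, dim = c(3, 3, 1))
  cine <- cine_loop(frames, timestamps = 0)
  roi <- roi_polygon("background", rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3)))
  expect_equal(extract_tic(cine, roi)$intensities, 4)
})

test_that("extraction matches the per-pixel double-loop oracle", {
  set.seed(31)
  for (i in 1:5) {
    cine <- random_cine(16, 16, 10)
    nv <- sample(3:6, 1)
    roi <- roi_polygon("adventitia", random_star_polygon(nv, 8, 8, 2, 7))
    mask <- tryCatch(rasterize_roi(roi, c(16, 16)), error = function(e) NULL)
    if (is.null(mask)) next
    got <- extract_tic(cine, roi)
    expect_equal(got$intensities, oracle_tic_means(cine$frames, mask),
                 tolerance = 1e-12)
    # mean is bounded by the per-frame extremes over the mask
    idx <- which(mask)
    fm <- matrix(cine$frames, 256, 10)
    expect_true(all(got$intensities >= apply(fm[idx, , drop = FALSE], 2, min) &
                    got$intensities <= apply(fm[idx, , drop = FALSE], 2, max)))
  }
})

test_that("moving-average smoothing truncates at the edges", {
  x <- tic(0:2, c(0, 10, 0), "lumen", 4)
  sm <- smooth_tic(x, 3)
  expect_equal(sm$intensities, c(5, 10 / 3, 5))
  expect_identical(sm$smoothing, "moving-average(3)")

  expect_identical(smooth_tic(x, 1), x) # identity
  const <- tic(0:4, rep(7, 5), "lumen", 4)
  expect_equal(smooth_tic(const, 5)$intensities, rep(7, 5))

  set.seed(32)
  y <- tic(0:19, runif(20, 0, 255), "adventitia", 9)
  for (w in c(3, 7, 19)) {
    sm <- smooth_tic(y, w)
    expect_true(all(sm$intensities >= min(y$intensities) &
                    sm$intensities <= max(y$intensities)))
  }
  expect_error(smooth_tic(y, 4), class = "invalid_parameter")
  expect_error(smooth_tic(y, 21), class = "invalid_parameter")
})

test_that("background estimation averages the reference window", {
  x <- tic(0:3, rep(10, 4), "lumen", 4)
  expect_equal(estimate_background(x, c(0, 4)), 10)

  two <- tic(c(0, 1, 2, 3), c(8, 12, 50, 80), "lumen", 4)
  expect_equal(estimate_background(two, c(0, 2)), 10) # frames 8 and 12 only

  # default window: frames strictly before the destruction pulse
  geom <- phantom_geometry(height = 16, width = 16, lumen_rows = c(7, 10),
                           adventitia_above = c(4, 6),
                           adventitia_below = c(11, 13))
  loop <- render_cine_loop(geom, kinetics_params(10, 60, 0.5, 5),
                           kinetics_params(10, 30, 0.5, 5),
                           noise_sd = 0, frame_rate = 2, duration = 15,
                           destruction_time = 5)
  lt <- extract_tic(loop, default_rois(geom)$lumen)
  expect_identical(estimate_background(lt), 10)

  # no destruction time: fall back to pre-onset frames
  lt2 <- tic(lt$times, lt$intensities, "lumen", lt$n_pixels)
  expect_identical(estimate_background(lt2), 10)

  expect_error(estimate_background(two, c(10, 20)), class = "invalid_window")
  expect_error(estimate_background(two, c(3, 1)), class = "invalid_window")
})
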