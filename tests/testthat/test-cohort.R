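test_that("cohort rows, group-5 handling and determinism", {
  cfg <- cohort_config(groups = default_group_specs(3), cache_tics = TRUE,
                       seed = 9)
  sim <- simulate_cohort(cfg)
  expect_s3_class(sim$cohort, "cohort_table")
  expect_identical(nrow(sim$cohort), 18L)
  expect_true(all(is.na(sim$cohort$nmve[sim$cohort$group_id == 5])))
  expect_true(all(!is.na(sim$cohort$nmve[sim$cohort$group_id != 5])))

  # groups 0-4 only: every row carries a normalized MVE
  cfg04 <- cohort_config(groups = default_group_specs(2, include_group5 = FALSE),
                         cache_tics = TRUE, seed = 9)
  sim04 <- simulate_cohort(cfg04)
  expect_identical(nrow(sim04$cohort), 10L)
  expect_true(all(!is.na(sim04$cohort$nmve)))

  # identical seed + config reproduce the cohort bit-identically
  again <- simulate_cohort(cfg)
  expect_identical(sim$cohort, again$cohort)
  expect_identical(sim$truth, again$truth)

  # changing only the seed changes the noise but not the design structure
  cfg2 <- cfg; cfg2$seed <- 10L
  other <- simulate_cohort(cfg2)
  expect_identical(other$truth$true_density, sim$truth$true_density)
  expect_identical(other$truth$group_id, sim$truth$group_id)
  expect_false(identical(other$cohort$nmve, sim$cohort$nmve))
})

test_that("rendered-loop and cached-TIC routes estimate the same quantity", {
  specs <- default_group_specs(4, include_group5 = FALSE)[c(1, 4)]
  est <- sapply(c(FALSE, TRUE), function(cache) {
    cfg <- cohort_config(groups = specs, cache_tics = cache, seed = 13,
                         noise_sd = 2)
    mean(simulate_cohort(cfg)$cohort$nmve -
         simulate_cohort(cfg)$truth$true_ratio)
  })
  # both routes are nearly unbiased for the true amplitude ratio
  expect_true(all(abs(est) < 0.03))
})

test_that("ground truth links amplitudes, ratios and count intensities", {
  cfg <- cohort_config(groups = default_group_specs(3), cache_tics = TRUE,
                       seed = 15)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  expect_equal(tr$true_ratio,
               tr$true_adv_amplitude / tr$true_lumen_amplitude)
  expect_equal(tr$lambda_vegf,
               cfg$histology$vegf[["a"]] + cfg$histology$vegf[["b"]] * tr$true_density)
  # per-group mean of true ratios is centred on the latent density
  rel <- as.vector(tapply(tr$true_ratio / tr$true_density, tr$group_id,
                          function(x) abs(mean(x) - 1) < 0.6))
  expect_equal(rel, rep(TRUE, 6))
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(groups = list()), class = "configuration_error")
  bad <- list(group_spec(0, 3, 0.5), group_spec(1, 3, 0.2)) # decreasing density
  expect_error(cohort_config(groups = bad), class = "configuration_error")
  expect_error(group_spec(2, 3, 0.4, plaque_present = TRUE),
               class = "configuration_error")
  expect_error(group_spec(4, 3, 0.6, plaque_occlusive = TRUE),
               class = "configuration_error")
  expect_error(cohort_config(duration = 0.05, frame_rate = 5),
               class = "configuration_error")
  expect_error(cohort_config(onset_time = 0), class = "configuration_error")
})
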