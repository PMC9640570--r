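test_that("spatial threshold is recovered on clean profiles and absent on ramps", {
  cfg <- quick_cfg()
  pos <- seq(0, 300, by = 5)
  prof <- dspike_profile(pos, cfg)           # no hot spot
  est <- estimate_spatial_threshold(pos, prof)
  expect_equal(est$threshold_um, 133.24, tolerance = 2)

  # invariance to amplitude scaling and offset
  est2 <- estimate_spatial_threshold(pos, 5 * prof + 0.7)
  expect_equal(est2$threshold_um, est$threshold_um, tolerance = 0.5)

  # a pure linear ramp has no inflection
  ramp <- estimate_spatial_threshold(pos, 0.002 * pos + 0.05)
  expect_true(is.na(ramp$threshold_um))
  flat <- estimate_spatial_threshold(pos, rep(1, length(pos)))
  expect_true(is.na(flat$threshold_um))
  expect_error(estimate_spatial_threshold(1:4, 1:4), "6 bins")
})

test_that("proximal linear fit recovers exact lines below the threshold", {
  pos <- seq(0, 300, by = 25)
  fit <- proximal_linear_fit(pos, 0.001 * pos + 0.01, threshold_um = 133)
  expect_equal(fit$slope, 0.001, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-9)

  flat <- proximal_linear_fit(pos, rep(0.3, length(pos)), 133)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.3, tolerance = 1e-12)

  expect_null(proximal_linear_fit(pos, 0.001 * pos, threshold_um = 30))
})

test_that("hot spots are found on temporal-integral profiles with correct FWHM", {
  cfg <- quick_cfg(duration = 6, event_rate = 10, imaging_rate = 308,
                   group_mix = c(0, 1, 0), seed = 3)
  truth <- schedule_events(cfg)
  truth$dspikes$hotspot_um <- 180
  img <- compute_dff(simulate_dendrite(cfg, truth, 1))
  resp <- detect_responses(img)
  hs <- detect_hotspots(img, resp[1, ])
  expect_equal(nrow(hs), 1)
  expect_equal(hs$center_um, 180, tolerance = cfg$position_step)
  expect_equal(hs$fwhm_um, 5.41, tolerance = cfg$position_step)

  # two bumps 30 um apart on a flat background
  flat_img <- img
  pos <- img$positions
  prof <- 0.2 + exp(-0.5 * ((pos - 100) / 3)^2) + exp(-0.5 * ((pos - 130) / 3)^2)
  flat_img$values <- outer(prof, ca_kernel((seq_len(600) - 1) / 308 - 0.5))
  r2 <- data.frame(t3_s = 0.5, t4_s = 1.5)
  hs2 <- detect_hotspots(flat_img, r2)
  expect_equal(nrow(hs2), 2)
  expect_equal(hs2$center_um, c(100, 130), tolerance = 1)

  # flat profile: no hot spots
  flat_img$values <- outer(rep(1, length(pos)), ca_kernel((seq_len(600) - 1) / 308 - 0.5))
  expect_equal(nrow(detect_hotspots(flat_img, r2)), 0)
})

test_that("onset maps reproduce the configured delay map with sub-frame accuracy", {
  cfg <- quick_cfg(duration = 6, event_rate = 10, imaging_rate = 308,
                   group_mix = c(0, 1, 0), seed = 3)
  truth <- schedule_events(cfg)
  truth$dspikes$hotspot_um <- 150
  img <- compute_dff(simulate_dendrite(cfg, truth, 1))
  resp <- detect_responses(img)
  om <- onset_map(img, resp[1, ])
  ic <- which(img$positions == 150)
  rel <- (om - om[ic]) * 1000
  expected <- propagation_delay_map(img$positions, 150, cfg)
  half_frame <- 1000 / 308 / 2
  expect_lt(max(abs(rel - expected), na.rm = TRUE), half_frame)

  # synchronous response: zero onset variance
  sync <- img
  sync$values <- outer(rep(1, length(img$positions)),
                       ca_kernel((seq_len(600) - 1) / 308 - 0.5))
  oms <- onset_map(sync, data.frame(t3_s = 0.5, t4_s = 1.5))
  expect_lt(stats::var(oms), 1e-18)

  # a position with no response has no onset
  quiet <- sync
  quiet$values[5, ] <- 0
  omq <- onset_map(quiet, data.frame(t3_s = 0.5, t4_s = 1.5))
  expect_true(is.na(omq[5]))
})

test_that("propagation statistics recover lead and speed, with censoring rules", {
  cfg <- quick_cfg(duration = 6, event_rate = 10, imaging_rate = 308,
                   group_mix = c(0, 1, 0), seed = 3)
  truth <- schedule_events(cfg)
  truth$dspikes$hotspot_um <- 150
  img <- compute_dff(simulate_dendrite(cfg, truth, 1))
  resp <- detect_responses(img)
  om <- onset_map(img, resp[1, ])
  ps <- propagation_stats(om, img$positions, 150)
  half_frame_ms <- 1000 / 308 / 2
  expect_lt(abs(ps$onset_lead_ms - 13.83), half_frame_ms)
  expect_equal(ps$speed_centripetal, 6.60, tolerance = 0.05)
  expect_equal(ps$speed_centrifugal, 6.60, tolerance = 0.05)

  # synchronous onsets: infinite speed sentinel
  sync <- rep(1.0, 301)
  pss <- propagation_stats(sync, 0:300, 150)
  expect_true(is.infinite(pss$speed_centripetal))
  expect_true(is.infinite(pss$speed_centrifugal))

  # one-sided hot spot at the segment end: distal side has no estimate
  edge <- propagation_stats(om, img$positions, max(img$positions))
  expect_true(is.na(edge$speed_centrifugal))
})

test_that("branch correlation handles exact, degenerate and random inputs", {
  expect_equal(branch_correlation(c(10, 50, 90, 130), c(10, 50, 90, 130)), 1)
  expect_true(is.na(branch_correlation(c(10, 50, 90), rep(42, 3))))
  expect_true(is.na(branch_correlation(c(1, 2), c(3, 4))))

  set.seed(7)
  thr <- runif(11, 100, 200)
  br <- runif(11, 100, 200)
  r <- branch_correlation(thr, br)
  # direct Pearson formula as the oracle
  oracle <- sum((thr - mean(thr)) * (br - mean(br))) /
    sqrt(sum((thr - mean(thr))^2) * sum((br - mean(br))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_lt(abs(r), 0.6)
})
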