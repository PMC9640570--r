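test_that("configuration invariants are enforced with named errors", {
  expect_error(sim_config(group_mix = c(0.5, 0.5, 0.1)), "group_mix")
  expect_error(sim_config(spatial_threshold = 400, dendrite_length = 300),
               "spatial_threshold")
  expect_error(sim_config(decay_tau = -1), "decay_tau")
  expect_error(sim_config(event_rate = 0), "event_rate")
  expect_error(sim_config(dspike_prob = 1.2), "dspike_prob")
  expect_silent(validate_sim_config(sim_config()))
})

test_that("event schedule honours mixture, refractory period and seed", {
  # degenerate mixture: every complex is a doublet
  cfg <- quick_cfg(duration = 70, event_rate = 10, group_mix = c(0, 0, 1))
  truth <- schedule_events(cfg)
  expect_true(all(truth$events$kind == "doublet"))
  expect_true(all(is.finite(truth$events$gap_s)))
  # doublet sub-event span below 300 ms; singlet has one sub-event
  expect_true(all(truth$events$gap_s + truth$events$dur2_s < 0.32))

  # determinism: identical config and seed give identical schedules
  truth2 <- schedule_events(cfg)
  expect_identical(truth, truth2)

  # complexes respect the 500 ms refractory period and the 1 s lead-in
  cfg3 <- quick_cfg(duration = 120, event_rate = 25)
  ev <- schedule_events(cfg3)$events
  ends <- ifelse(ev$kind == "doublet", ev$onset2_s + ev$dur2_s,
                 ev$onset_s + ev$dur1_s)
  expect_true(all(ev$onset_s[-1] - ends[-nrow(ev)] >= 0.5))
  expect_true(min(ev$onset_s) >= 1)

  # a duration too short for the requested rate fails loudly
  expect_error(schedule_events(quick_cfg(duration = 5, event_rate = 120)),
               "refractory")
})

test_that("doublet draw count matches the mixture within binomial error", {
  cfg <- quick_cfg(duration = 3000, event_rate = 10,
                   group_mix = c(0.4, 0.4, 0.2), seed = 11)
  ev <- schedule_events(cfg)$events
  n <- nrow(ev)
  expect_equal(n, 500)
  n_doublet <- sum(ev$kind == "doublet")
  sd_binom <- sqrt(n * 0.2 * 0.8)
  expect_lt(abs(n_doublet - n * 0.2), 3 * sd_binom)
})

test_that("zero-noise LFP is exactly zero outside event support and scales linearly", {
  cfg <- quick_cfg(duration = 20, event_rate = 3, group_mix = c(0, 1, 0),
                   amp_jitter_log = 0, seed = 4)
  truth <- schedule_events(cfg)
  rec <- simulate_lfp(cfg, truth)
  ev <- truth$events
  tt <- (seq_len(nrow(rec$data)) - 1) / rec$rate
  # support: wavelet +/- 2.5 sigma and sharp wave +/- 3 * 20 ms around center
  centers <- ev$onset_s + ev$dur1_s / 2
  in_support <- rep(FALSE, length(tt))
  for (k in seq_along(centers)) {
    half <- max(2.5 * ev$dur1_s[k] / 4, 3 * 0.020) + 2 / rec$rate
    in_support <- in_support | (tt >= centers[k] - half & tt <= centers[k] + half)
  }
  expect_true(all(rec$data[!in_support, 1] == 0))
  # conservation: one contiguous nonzero segment per sub-event
  runs <- rle(rec$data[, 1] != 0)
  expect_equal(sum(runs$values), nrow(ev))

  # doubling the ripple amplitude doubles the in-band peak-to-peak
  cfg2 <- quick_cfg(duration = 20, event_rate = 3, group_mix = c(0, 1, 0),
                    amp_jitter_log = 0, seed = 4,
                    ripple_amp_high = 2 * cfg$ripple_amp_high,
                    sharpwave_amp = cfg$sharpwave_amp)
  rec2 <- simulate_lfp(cfg2, schedule_events(cfg2))
  f1 <- bandpass_difference(rec$data[, 1], rec$rate)
  f2 <- bandpass_difference(rec2$data[, 1], rec2$rate)
  # the (unscaled) sharp-wave leak through the band filter bounds the error
  expect_equal(max(f2) - min(f2), 2 * (max(f1) - min(f1)), tolerance = 1e-4)
})

test_that("injected wavelet duration is recovered within one smoothing window", {
  rate <- 5000
  n <- rate * 4
  tt <- (seq_len(n) - 1) / rate
  dur <- 0.040
  sig <- dur / 4
  x <- exp(-0.5 * ((tt - 2) / sig)^2) * sin(2 * pi * 200 * (tt - 2)) * 50
  x[abs(tt - 2) > 2.5 * sig] <- 0
  env <- ripple_power_envelope(bandpass_difference(x, rate), rate, smooth_ms = 5)
  iv <- detect_events(env, rate,
                      baseline = list(center = 0, spread = 0, n_s = 4))
  expect_equal(nrow(iv), 1)
  # 0.2%-of-peak crossing of the squared Gaussian envelope: half width
  # sigma * sqrt(ln 500)
  analytic <- 2 * sig * sqrt(log(500))
  expect_lt(abs((iv$t2_s - iv$t1_s) - analytic), 0.005)
})

test_that("dendrite forward model reproduces profiles, delays and determinism", {
  cfg <- quick_cfg(duration = 8, event_rate = 8, group_mix = c(0, 1, 0),
                   ca_jitter_log = 0, amp_jitter_log = 0, seed = 2)
  truth <- schedule_events(cfg)
  truth$dspikes$hotspot_um <- 180      # pin the hot spot
  img <- simulate_dendrite(cfg, truth, 1, raw = FALSE)

  # dSpike mode: amplitude at 200 um exceeds amplitude at 50 um
  peak_at <- function(um) max(img$values[which(img$positions == um), ])
  expect_gt(peak_at(200), peak_at(50))

  # movie reproduces the configured spatial profile at sample points
  profile <- truth$events$ca_scale[1] * dspike_profile(img$positions, cfg, 180)
  movie_peaks <- apply(img$values, 1, max)
  expect_equal(movie_peaks, profile, tolerance = 0.02)

  # propagation delay map: 66 um from the center at 6.6 um/ms lags 10 ms
  expect_equal(propagation_delay_map(246, 180, cfg), 10, tolerance = 1e-9)
  # ... and saturates at the configured lead beyond the invasion radius
  expect_equal(propagation_delay_map(300, 180, cfg), cfg$hotspot_lead)

  # bAP mode: soma amplitude exceeds the 300 um tip
  cfgb <- quick_cfg(duration = 8, event_rate = 8, dspike_prob = 0,
                    bap_rate = 8, seed = 2)
  truthb <- schedule_events(cfgb)
  expect_gt(nrow(truthb$baps), 0)
  imgb <- simulate_dendrite(cfgb, truthb, 1, raw = FALSE)
  expect_gt(max(imgb$values[1, ]), max(imgb$values[nrow(imgb$values), ]))

  # bit-identical reruns for a fixed (cfg, seed), noise included
  cfgn <- quick_cfg(duration = 10, event_rate = 6, lfp_noise_sd = 10,
                    imaging_noise_sd = 0.0461, seed = 33)
  s1 <- simulate_session(cfgn)
  s2 <- simulate_session(cfgn)
  expect_identical(s1$lfp$data, s2$lfp$data)
  expect_identical(s1$dendrites[[1]]$values, s2$dendrites[[1]]$values)
})
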