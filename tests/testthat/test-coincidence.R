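mk_resp <- function(t3, t_peak, t4 = t_peak + 0.5, dendrite = 1L) {
  data.frame(response_id = seq_along(t3), dendrite_id = dendrite, t3_s = t3,
             t4_s = t4, t_peak_s = t_peak, peak_amp_dff = 1, area_dffs = 0.3)
}

mk_rip <- function(t1, t2, t_zero = (t1 + t2) / 2, kind = "singlet") {
  data.frame(event_id = seq_along(t1), t1_s = t1, t2_s = t2, t21_s = NA,
             t22_s = NA, t_end_s = t2, kind = kind, t_zero_s = t_zero,
             duration_ms = (t2 - t1) * 1000, rejected = FALSE)
}

test_that("responses match ripples by interval overlap with nearest time zero", {
  rip <- mk_rip(c(10, 20), c(10.04, 20.04))
  # response inside the ripple window: matched
  m1 <- match_events(mk_resp(10.01, 10.03), rip)
  expect_equal(m1$matched_event_id, 1L)
  expect_equal(m1$jitter_ms, (10.03 - 10.02) * 1000)

  # response starting 1 s after the ripple end: unmatched
  m2 <- match_events(mk_resp(11.04, 11.2), rip)
  expect_true(is.na(m2$matched_event_id))

  # two qualifying ripples: nearest time zero wins
  rip3 <- mk_rip(c(10, 10.1), c(10.06, 10.16))
  m3 <- match_events(mk_resp(10.05, 10.14), rip3)
  expect_equal(m3$matched_event_id, 2L)

  # matching is invariant under a joint clock shift of both streams
  shift <- 3.21
  rip_s <- rip
  rip_s[, c("t1_s", "t2_s", "t_end_s", "t_zero_s")] <-
    rip_s[, c("t1_s", "t2_s", "t_end_s", "t_zero_s")] + shift
  m4 <- match_events(mk_resp(10.01 + shift, 10.03 + shift), rip_s)
  expect_equal(m4$matched_event_id, m1$matched_event_id)
  expect_equal(m4$jitter_ms, m1$jitter_ms, tolerance = 1e-9)

  # non-overlapping recording spans are a clock mismatch
  expect_error(match_events(mk_resp(500, 500.3), rip), "clock")
})

test_that("jitter equals the configured onset delay plus the kernel rise", {
  # fast near-impulse kernel so the calcium peak tracks the onset; the
  # onset delay keeps T3 inside the ripple window so everything matches
  cfg <- quick_cfg(duration = 40, lfp_rate = 5000, event_rate = 10,
                   imaging_rate = 308, rise_tau = 2, decay_tau = 30,
                   ca_onset_delay_ms = 5, hotspot_lead = 1,
                   group_mix = c(0, 1, 0), seed = 12)
  truth <- schedule_events(cfg)
  img <- compute_dff(simulate_dendrite(cfg, truth, 1))
  rip <- detect_ripples(simulate_lfp(cfg, truth))
  m <- match_events(detect_responses(img), rip)
  jit <- m$jitter_ms[!is.na(m$matched_event_id)]
  expect_gt(length(jit), 3)
  # peak lags onset by the (fast) kernel rise; quantization is one frame
  peak_lag <- 1000 * log(30 / 2) * (0.002 * 0.030) / (0.030 - 0.002)
  expect_lt(abs(mean(jit) - (5 + peak_lag)), 2 * 1000 / 308)

  # the jitter convention itself: a calcium peak 30 ms after time zero
  # reads out as +30 ms
  rip30 <- mk_rip(10, 10.06)                 # time zero at 10.03
  m30 <- match_events(mk_resp(10.02, 10.06), rip30)
  expect_equal(m30$jitter_ms, 30)
})

test_that("spatial profiles separate local dendritic spikes from global bAPs", {
  cfg <- quick_cfg(duration = 8, event_rate = 8, group_mix = c(0, 1, 0), seed = 2)
  pos <- seq(0, 300)
  dsp <- classify_mode(dspike_profile(pos, cfg, 200), pos)
  expect_equal(dsp$mode, "local_dspike")
  expect_gt(dsp$slope, 0)

  bap <- classify_mode(bap_profile(pos, cfg), pos)
  expect_equal(bap$mode, "global_bap")
  expect_lt(bap$slope, 0)

  flat <- classify_mode(rep(0.4, length(pos)), pos)
  expect_equal(flat$mode, "unclassified")

  few <- classify_mode(rep(0.4, 5), c(0, 5, 10, 160, 170))
  expect_equal(few$mode, "unclassified")
  expect_match(few$reason, "fewer than 4")
})

test_that("mode classification stays accurate at the default imaging noise", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- quick_cfg(duration = 8, event_rate = 8, imaging_noise_sd = 0.0461,
                     group_mix = c(0, 1, 0), seed = s)
    truth <- schedule_events(cfg)
    img <- compute_dff(simulate_dendrite(cfg, truth, 1))
    resp <- detect_responses(img)
    if (nrow(resp) == 0) next
    amp <- per_position_amplitudes(img, resp[which.max(resp$peak_amp_dff), ])
    total <- total + 1
    if (classify_mode(amp, img$positions)$mode == "local_dspike") hits <- hits + 1

    cfgb <- quick_cfg(duration = 8, event_rate = 8, dspike_prob = 0,
                      imaging_noise_sd = 0.0461, bap_rate = 8, seed = s)
    truthb <- schedule_events(cfgb)
    imgb <- compute_dff(simulate_dendrite(cfgb, truthb, 1))
    respb <- detect_responses(imgb, region = "all")
    if (nrow(respb) == 0) next
    ampb <- per_position_amplitudes(imgb, respb[which.max(respb$peak_amp_dff), ])
    total <- total + 1
    if (classify_mode(ampb, imgb$positions)$mode == "global_bap") hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("activation ratios reduce to simple count ratios with sane edge cases", {
  ev <- data.frame(mode = c(rep("local_dspike", 85), rep("global_bap", 10)),
                   matched_event_id = c(seq_len(85), rep(NA, 10)),
                   dendrite_id = c(rep(1:12, length.out = 85), rep(1, 10)))
  r <- activation_ratios(ev, n_ripples = 307, n_dendrites = 58)
  expect_equal(r$total_ratio, 85 / 307)
  expect_equal(r$per_dendrite_active_fraction, 12 / 58)

  none <- activation_ratios(ev[0, ], n_ripples = 50, n_dendrites = 5)
  expect_equal(none$total_ratio, 0)
  expect_equal(none$n_dspikes, 0)

  undef <- activation_ratios(ev, n_ripples = 0, n_dendrites = 5)
  expect_true(is.na(undef$total_ratio))
})
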