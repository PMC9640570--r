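test_that("difference-of-Gaussian filter nulls DC and matches its closed-form gain", {
  rate <- 5000
  # constant input: both low-pass kernels pass DC equally
  expect_lt(max(abs(bandpass_difference(rep(3.7, 2000), rate))), 1e-9)

  gain_at <- function(f) {
    tt <- (0:(2 * rate) - 1) / rate
    y <- bandpass_difference(sin(2 * pi * f * tt), rate)
    mid <- seq(round(0.25 * length(y)), round(0.75 * length(y)))
    max(abs(y[mid]))
  }
  g200 <- exp(-0.5 * (200 / 500)^2) - exp(-0.5 * (200 / 150)^2)
  expect_equal(gain_at(200), g200, tolerance = 0.05)
  expect_lt(gain_at(10), 0.05)

  expect_error(bandpass_difference(rnorm(100), rate = 800), "rate")
  expect_error(bandpass_difference(rnorm(100), 5000, low_cut = 600), "low_cut")
})

test_that("power envelope is non-negative, quadratic, and averages sin^2 to one half", {
  rate <- 5000
  expect_true(all(ripple_power_envelope(numeric(1000), rate) == 0))
  x <- rnorm(5000)
  e1 <- ripple_power_envelope(x, rate)
  e3 <- ripple_power_envelope(3 * x, rate)
  expect_equal(e3, 9 * e1, tolerance = 1e-12)
  expect_true(all(e1 >= 0))
  tt <- (0:9999) / rate
  env <- ripple_power_envelope(sin(2 * pi * 250 * tt), rate, smooth_ms = 5)
  plateau <- env[2000:8000]
  expect_equal(mean(plateau), 0.5, tolerance = 0.02)
  expect_lt(diff(range(plateau)), 0.02)
})

test_that("event detection segments rectangular pulses and rejects brief crossings", {
  rate <- 1000
  base <- list(center = 1, spread = 0.5, n_s = 10)   # threshold at 3
  env <- rep(1, 10000)
  env[3001:3100] <- 10
  iv <- detect_events(env, rate, threshold_sd = 4, baseline = base)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$t1_s, 3.000)
  expect_equal(iv$t2_s, 3.100)

  env[5001:5050] <- 10                               # second pulse
  iv2 <- detect_events(env, rate, threshold_sd = 4, baseline = base)
  expect_equal(nrow(iv2), 2)

  env[7001:7005] <- 10                               # 5 ms: below minimum
  iv3 <- detect_events(env, rate, threshold_sd = 4, baseline = base)
  expect_equal(nrow(iv3), 2)
})

test_that("false-event rate on pure pink noise stays below 1 per 10 s", {
  rate <- 5000
  set.seed(42)
  noise <- pink_noise(30 * rate, rate, sd = 10)
  env <- ripple_power_envelope(bandpass_difference(noise, rate), rate)
  iv <- detect_events(env, rate)
  expect_lt(nrow(iv), 3)
})

test_that("complex merging follows the strict 300 ms rule and is idempotent", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(t1_s = m[, 1], t2_s = m[, 2])
  }
  # two intervals spanning 190 ms: one doublet
  d <- merge_into_complexes(iv(0, 0.040, 0.150, 0.190))
  expect_equal(d$kind, "doublet")
  expect_equal(d$duration_ms, 190)
  expect_equal(d$t21_s, 0.150)
  expect_equal(d$t22_s, 0.190)

  # well-separated intervals: two singlets of 40 ms
  s <- merge_into_complexes(iv(0, 0.040, 0.350, 0.390))
  expect_equal(s$kind, c("singlet", "singlet"))
  expect_equal(s$duration_ms, c(40, 40))

  # a span of exactly 300 ms does not merge (strict inequality)
  b <- merge_into_complexes(iv(0, 0.040, 0.260, 0.300))
  expect_equal(b$kind, c("singlet", "singlet"))

  # three intervals within the window: one flagged multi complex
  m <- merge_into_complexes(iv(0, 0.040, 0.150, 0.190, 0.250, 0.290))
  expect_equal(m$kind, "multi")
  expect_equal(m$n_sub, 3)

  # idempotence: re-merging the complex spans leaves the spans unchanged
  spans <- data.frame(t1_s = d$t1_s, t2_s = d$t_end_s)
  again <- merge_into_complexes(spans)
  expect_equal(again$t1_s, d$t1_s)
  expect_equal(again$t_end_s, d$t_end_s)
})

test_that("ripple features scale correctly and measure a known sinusoid", {
  rate <- 10000
  tt <- (0:(rate / 2)) / rate
  x <- sin(2 * pi * 180 * tt)
  cx <- merge_into_complexes(data.frame(t1_s = 0.1, t2_s = 0.15))
  f1 <- compute_features(cx, x, rate)
  # 9 cycles in 50 ms: frequency within one cycle-count quantum (20 Hz)
  expect_lt(abs(f1$frequency_hz - 180), 20 + 1e-9)
  expect_equal(f1$peak_to_peak_uv, 2, tolerance = 1e-3)

  f3 <- compute_features(cx, 3 * x, rate)
  expect_equal(f3$area_uvs, 3 * f1$area_uvs, tolerance = 1e-12)
  expect_equal(f3$power_uv2s, 9 * f1$power_uv2s, tolerance = 1e-12)
  expect_equal(f3$peak_to_peak_uv, 3 * f1$peak_to_peak_uv, tolerance = 1e-12)
  expect_equal(f3$frequency_hz, f1$frequency_hz)
  expect_equal(f3$t_zero_s, f1$t_zero_s)
})

test_that("event features are invariant to a DC offset on the raw trace", {
  cfg <- quick_cfg(duration = 20, event_rate = 6, seed = 9)
  truth <- schedule_events(cfg)
  rec <- simulate_lfp(cfg, truth)
  ev1 <- detect_ripples(rec)
  rec$data <- rec$data + 250
  ev2 <- detect_ripples(rec)
  expect_equal(ev1$t1_s, ev2$t1_s, tolerance = 1e-9)
  expect_equal(ev1$area_uvs, ev2$area_uvs, tolerance = 1e-6)
  expect_equal(ev1$peak_to_peak_uv, ev2$peak_to_peak_uv, tolerance = 1e-6)
})

test_that("channel selection maximizes band power with deterministic tie-breaks", {
  rate <- 5000
  n <- rate * 5
  tt <- (seq_len(n) - 1) / rate
  ripple <- exp(-0.5 * ((tt - 2.5) / 0.01)^2) * sin(2 * pi * 180 * tt)
  mk <- function(traces, roles) {
    structure(list(data = do.call(cbind, traces), rate = rate, roles = roles,
                   start_time = 0), class = "swr_lfp")
  }
  # the channel with injected ripples wins over noise channels
  set.seed(1)
  rec <- mk(list(rnorm(n, 0, 0.5), 30 * ripple + rnorm(n, 0, 0.5),
                 rnorm(n, 0, 0.5)), c("local_hc", "local_hc", "local_hc"))
  expect_equal(select_channel(rec), 2)

  # identical channels: lowest index wins
  z <- sin(2 * pi * 200 * tt)
  rec2 <- mk(list(z, z, z), rep("local_hc", 3))
  expect_equal(select_channel(rec2), 1)

  # band powers (3, 7, 5) in arbitrary units -> the 7
  rec3 <- mk(list(sqrt(3) * z, sqrt(7) * z, sqrt(5) * z), rep("local_hc", 3))
  expect_equal(select_channel(rec3), 2)

  rec4 <- mk(list(z), "contralateral")
  expect_error(select_channel(rec4), "local_hc")
})

test_that("contralateral screening rejects shared artifacts and keeps local events", {
  # 10 scheduled complexes, 3 with bilateral artifacts -> 7 retained
  cfg <- quick_cfg(duration = 60, event_rate = 10, artifact_rate = 3,
                   group_mix = c(0.5, 0.5, 0), seed = 6)
  truth <- schedule_events(cfg)
  expect_equal(nrow(truth$events), 10)
  expect_equal(nrow(truth$artifacts), 3)
  rec <- simulate_lfp(cfg, truth)
  ev <- detect_ripples(rec)
  expect_equal(sum(ev$rejected), 3)
  expect_equal(sum(!ev$rejected), 7)
  expect_true(all(ev$reject_reason[ev$rejected] == "contralateral"))

  # with a silent contralateral channel everything is retained
  cfg0 <- quick_cfg(duration = 60, event_rate = 10,
                    group_mix = c(0.5, 0.5, 0), seed = 6)
  ev0 <- detect_ripples(simulate_lfp(cfg0, schedule_events(cfg0)))
  expect_true(all(!ev0$rejected))
})

test_that("zero-noise synthesis is recalled perfectly with matching kinds", {
  cfg <- quick_cfg(duration = 60, event_rate = 10, seed = 21)
  truth <- schedule_events(cfg)
  ev <- detect_ripples(simulate_lfp(cfg, truth))
  expect_equal(nrow(ev), nrow(truth$events))
  # onsets align within the envelope smoothing window
  expect_lt(max(abs(sort(ev$t1_s) - sort(truth$events$onset_s))), 0.01)
  expect_equal(ev$kind[order(ev$t1_s)],
               truth$events$kind[order(truth$events$onset_s)])
})
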