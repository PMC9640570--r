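# Small, fast simulation configurations used across the suite.

quick_cfg <- function(...) {
  defaults <- list(duration = 30, lfp_rate = 5000, event_rate = 12,
                   n_dendrites = 1, dspike_prob = 1, bap_rate = 0,
                   lfp_noise_sd = 0, imaging_noise_sd = 0, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Double-exponential kernel on a dense grid -- independent of ca_kernel()
# sampling choices; used as the analytic oracle for summation tests.
dense_kernel <- function(t, rise_ms = 20, decay_ms = 340) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  h <- ifelse(t >= 0, exp(-t / td) - exp(-t / tr), 0)
  tp <- log(td / tr) * tr * td / (td - tr)
  h / (exp(-tp / td) - exp(-tp / tr))
}

# 60 ms window-mean peak on a dense uniform grid (oracle version).
dense_peak60 <- function(y, dt, window_s = 0.06) {
  w <- max(1L, round(window_s / dt))
  max(stats::filter(y, rep(1 / w, w), sides = 2), na.rm = TRUE)
}
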