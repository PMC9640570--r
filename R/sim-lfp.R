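#' 1/f ("pink") noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with a 1/sqrt(f)
#' amplitude envelope (flat below 1 Hz) and rescaled to the requested
#' standard deviation, giving the 1/f power spectrum typical of LFP
#' background activity.
#'
#' @param n number of samples
#' @param rate sampling rate, samples/s
#' @param sd target standard deviation (same units as the output)
#' @return numeric vector of length `n`
#' @export
pink_noise <- function(n, rate, sd = 1) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  shape <- 1 / sqrt(pmax(abs(freq), 1))
  shape[1] <- 0                          # remove DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Gaussian-windowed sinusoid (ripple wavelet) added in place.
# Window sd = dur/4, truncated at +/- 2.5 sd; the slow sharp-wave
# deflection is a negative Gaussian of 20 ms sd under the ripple.
add_ripple_wavelet <- function(x, rate, onset_s, dur_s, amp_uv,
                               carrier_hz, sharpwave_uv = 0) {
  tc <- onset_s + dur_s / 2
  sig <- dur_s / 4
  i0 <- max(1L, floor((tc - 2.5 * sig) * rate) + 1L)
  i1 <- min(length(x), ceiling((tc + 2.5 * sig) * rate) + 1L)
  if (i1 <= i0) return(x)
  tt <- (seq(i0, i1) - 1) / rate
  x[i0:i1] <- x[i0:i1] +
    amp_uv * exp(-0.5 * ((tt - tc) / sig)^2) * sin(2 * pi * carrier_hz * (tt - tc))
  if (sharpwave_uv > 0) {
    sw_sig <- 0.020
    j0 <- max(1L, floor((tc - 3 * sw_sig) * rate) + 1L)
    j1 <- min(length(x), ceiling((tc + 3 * sw_sig) * rate) + 1L)
    tt <- (seq(j0, j1) - 1) / rate
    x[j0:j1] <- x[j0:j1] - sharpwave_uv * exp(-0.5 * ((tt - tc) / sw_sig)^2)
  }
  x
}

#' Simulate the multichannel LFP of a scheduled session
#'
#' Four local hippocampal channels carry, at every scheduled sub-event, a
#' Gaussian-windowed ripple-band sinusoid superposed on a slow sharp-wave
#' deflection; channel gains decrease with channel index so that channel
#' selection by band power is well defined. The contralateral channel and
#' the reference channel carry background noise only, except for shared
#' artifacts flagged in the ground truth, which appear on both local and
#' contralateral channels. Background is 1/f noise on every channel.
#'
#' @param cfg an [sim_config()] object
#' @param truth the matching [schedule_events()] ground truth
#' @return an `swr_lfp` object: list with `data` (samples x channels
#'   matrix, uV), `rate`, `roles` (4x "local_hc", "contralateral",
#'   "reference") and `start_time`
#' @export
simulate_lfp <- function(cfg, truth) {
  validate_sim_config(cfg)
  n <- round(cfg$duration * cfg$lfp_rate)
  roles <- c(rep("local_hc", 4), "contralateral", "reference")
  gains <- c(1, 0.85, 0.7, 0.55)
  ev <- truth$events
  clean <- numeric(n)
  for (k in seq_len(nrow(ev))) {
    clean <- add_ripple_wavelet(clean, cfg$lfp_rate, ev$onset_s[k],
                                ev$dur1_s[k], ev$amp1_uv[k],
                                cfg$ripple_carrier, cfg$sharpwave_amp)
    if (ev$kind[k] == "doublet") {
      clean <- add_ripple_wavelet(clean, cfg$lfp_rate, ev$onset2_s[k],
                                  ev$dur2_s[k], ev$amp2_uv[k],
                                  cfg$ripple_carrier, cfg$sharpwave_amp)
    }
  }
  artifact <- numeric(n)
  if (nrow(truth$artifacts) > 0) {
    for (t0 in truth$artifacts$onset_s) {
      artifact <- add_ripple_wavelet(artifact, cfg$lfp_rate, t0 + 0.002,
                                     0.030, 1.2 * cfg$ripple_amp_high, 200)
    }
  }
  data <- with_seed(derive_seed(cfg$seed, "lfp"), {
    m <- matrix(0, nrow = n, ncol = length(roles))
    for (ch in seq_along(roles)) {
      m[, ch] <- pink_noise(n, cfg$lfp_rate, cfg$lfp_noise_sd)
    }
    m
  })
  for (ch in 1:4) data[, ch] <- data[, ch] + gains[ch] * clean + artifact
  data[, 5] <- data[, 5] + artifact
  rec <- list(data = data, rate = cfg$lfp_rate, roles = roles, start_time = 0)
  class(rec) <- "swr_lfp"
  rec
}
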