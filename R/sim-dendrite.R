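#' Double-exponential calcium indicator kernel
#'
#' `h(t) = exp(-t/decay) - exp(-t/rise)` for `t >= 0`, normalised to unit
#' peak. This is the phenomenological GCaMP6f-like impulse response used by
#' the forward model.
#'
#' @param t time from kernel onset, s (vector; negative values give 0)
#' @param rise_tau,decay_tau time constants, ms
#' @return kernel values, unit peak
#' @export
ca_kernel <- function(t, rise_tau = 20, decay_tau = 340) {
  tr <- rise_tau / 1000
  td <- decay_tau / 1000
  h <- ifelse(t >= 0, exp(-t / td) - exp(-t / tr), 0)
  tp <- log(td / tr) * tr * td / (td - tr)
  h / (exp(-tp / td) - exp(-tp / tr))
}

# Time (s) from kernel onset to kernel peak.
ca_kernel_peak_time <- function(rise_tau = 20, decay_tau = 340) {
  tr <- rise_tau / 1000
  td <- decay_tau / 1000
  log(td / tr) * tr * td / (td - tr)
}

#' Spatial amplitude profile of a dendritic spike
#'
#' Baseline ramp plus sigmoid centered at the spatial threshold, plus
#' Gaussian hot-spot bumps of the configured FWHM.
#'
#' @param positions distances from the soma, um
#' @param cfg an [sim_config()] object
#' @param hotspot_um hot-spot center(s), um (may be empty)
#' @return dF/F amplitude per position (unit event scale)
#' @export
dspike_profile <- function(positions, cfg, hotspot_um = numeric(0)) {
  amp <- cfg$dspike_base + cfg$dspike_ramp * positions +
    cfg$dspike_amp / (1 + exp(-(positions - cfg$spatial_threshold) / cfg$dspike_slope))
  sig <- cfg$hotspot_fwhm / (2 * sqrt(2 * log(2)))
  for (h in hotspot_um[!is.na(hotspot_um)]) {
    amp <- amp + cfg$hotspot_amp * exp(-0.5 * ((positions - h) / sig)^2)
  }
  amp
}

#' Spatial amplitude profile of a global (backpropagating AP) event
#'
#' Monotonically decreasing exponential from the soma.
#'
#' @inheritParams dspike_profile
#' @return dF/F amplitude per position
#' @export
bap_profile <- function(positions, cfg) {
  cfg$bap_amp * exp(-positions / cfg$bap_lambda)
}

#' Per-position onset delay of a propagating dendritic spike
#'
#' The spike initiates at the hot-spot center and propagates laterally at
#' the configured speed; beyond the radius `speed * lead` the remaining
#' dendrite activates synchronously at the full initiation lead (the spike
#' has fully invaded the segment).
#'
#' @param positions distances from the soma, um
#' @param center_um hot-spot center, um
#' @param cfg an [sim_config()] object
#' @return delay per position, ms (0 at the center)
#' @export
propagation_delay_map <- function(positions, center_um, cfg) {
  pmin(abs(positions - center_um) / cfg$propagation_speed, cfg$hotspot_lead)
}

#' Simulate the fluorescence movie of one dendritic segment
#'
#' Builds the (position x time) dF/F matrix of one dendrite from the
#' ground-truth schedule: dendritic spike events follow the sigmoidal
#' distance profile with hot-spot bumps and the propagation delay map;
#' global events follow the soma-dominant exponential profile with
#' synchronous onset; doublet second responses are scaled by the doublet
#' gain; every response uses the double-exponential indicator kernel.
#' Additive Gaussian imaging noise is applied in dF/F space; the matrix is
#' then optionally converted to raw fluorescence `F = F0 * (1 + dF/F)`.
#'
#' @param cfg an [sim_config()] object
#' @param truth matching ground truth
#' @param dendrite_id which dendrite to render
#' @param raw emit raw fluorescence (default) or dF/F directly
#' @return an `swr_dendrite` object: list with `values` (positions x
#'   frames), `positions` (um), `frame_rate`, `dendrite_id`, `cell_id`,
#'   `is_dff`, and `soma_trace` (the row at 0 um)
#' @export
simulate_dendrite <- function(cfg, truth, dendrite_id = 1, raw = TRUE) {
  validate_sim_config(cfg)
  positions <- seq(0, cfg$dendrite_length, by = cfg$position_step)
  n_frames <- floor(cfg$duration * cfg$imaging_rate)
  tt <- (seq_len(n_frames) - 1) / cfg$imaging_rate
  dff <- matrix(0, nrow = length(positions), ncol = n_frames)

  frame_ms <- 1000 / cfg$imaging_rate
  if (frame_ms > cfg$hotspot_lead) {
    warning(sprintf(
      "simulate_dendrite: imaging rate %.1f Hz (frame %.1f ms) cannot resolve the %.2f ms hot-spot lead",
      cfg$imaging_rate, frame_ms, cfg$hotspot_lead))
  }

  assign_rows <- truth$dspikes[truth$dspikes$dendrite_id == dendrite_id, ]
  ev <- truth$events

  add_response <- function(dff, onset_by_pos, amp_by_pos) {
    for (i in seq_along(positions)) {
      sel <- tt >= onset_by_pos[i]
      if (any(sel)) {
        dff[i, sel] <- dff[i, sel] +
          amp_by_pos[i] * ca_kernel(tt[sel] - onset_by_pos[i],
                                    cfg$rise_tau, cfg$decay_tau)
      }
    }
    dff
  }

  for (k in seq_len(nrow(assign_rows))) {
    if (!assign_rows$dspike[k]) next
    e <- ev[ev$event_id == assign_rows$event_id[k], ]
    center <- assign_rows$hotspot_um[k]
    amp <- e$ca_scale * dspike_profile(positions, cfg, center)
    delay_s <- propagation_delay_map(positions, center, cfg) / 1000
    # ripple peak (time zero) sits at the sub-event center
    t_zero1 <- e$onset_s + e$dur1_s / 2
    onset1 <- t_zero1 + cfg$ca_onset_delay_ms / 1000 + delay_s
    dff <- add_response(dff, onset1, amp)
    if (e$kind == "doublet") {
      t_zero2 <- e$onset2_s + e$dur2_s / 2
      onset2 <- t_zero2 + cfg$ca_onset_delay_ms / 1000 + delay_s
      dff <- add_response(dff, onset2, e$gain * amp)
    }
  }

  if (nrow(truth$baps) > 0) {
    amp <- bap_profile(positions, cfg)
    for (t0 in truth$baps$onset_s) {
      dff <- add_response(dff, rep(t0, length(positions)), amp)
    }
  }

  if (cfg$imaging_noise_sd > 0) {
    dff <- dff + with_seed(derive_seed(cfg$seed, paste0("imaging", dendrite_id)),
                           matrix(stats::rnorm(length(dff), 0, cfg$imaging_noise_sd),
                                  nrow = nrow(dff)))
  }

  values <- if (raw) cfg$f0_baseline * (1 + dff) else dff
  img <- list(values = values, positions = positions,
              frame_rate = cfg$imaging_rate, dendrite_id = dendrite_id,
              cell_id = 1L, is_dff = !raw, soma_trace = values[1, ])
  class(img) <- "swr_dendrite"
  img
}

#' Simulate a full session (ground truth, LFP and all dendrites)
#'
#' @param cfg an [sim_config()] object
#' @return list with `cfg`, `truth`, `lfp`, and `dendrites` (list of
#'   `swr_dendrite`)
#' @export
simulate_session <- function(cfg) {
  truth <- schedule_events(cfg)
  lfp <- simulate_lfp(cfg, truth)
  dendrites <- lapply(seq_len(cfg$n_dendrites), function(d) {
    simulate_dendrite(cfg, truth, d)
  })
  list(cfg = cfg, truth = truth, lfp = lfp, dendrites = dendrites)
}

#' Feature-level forward model for classification studies
#'
#' Emits per-event ripple and calcium features directly from the scheduled
#' ground truth, bypassing signal synthesis: durations, amplitude-derived
#' peak-to-peak / area / power, ripple frequency, and calcium areas from
#' the event's calcium scaling (doublets contribute both sub-responses).
#' This path shares the schedule's amplitude jitters, so the separation
#' structure of the classes (>= 3 SD between singlet amplitude classes at
#' the default jitters) is identical to the signal-level model, at a cost
#' that allows hundreds of events.
#'
#' @param cfg an [sim_config()] object
#' @param truth matching ground truth
#' @return data.frame of event features (one row per complex):
#'   event_id, kind, group, duration_ms, peak_to_peak_uv, area_uvs,
#'   power_uv2s, frequency_hz, ca_area_dffs
#' @export
simulate_event_features <- function(cfg, truth) {
  ev <- truth$events
  dur_ms <- ifelse(ev$kind == "doublet",
                   (ev$gap_s + ev$dur2_s) * 1000, ev$dur1_s * 1000)
  # mean |sin| = 2/pi over the Gaussian-windowed wavelet support
  env_int1 <- ev$amp1_uv * ev$dur1_s * sqrt(2 * pi) / 4 * (2 / pi)
  env_int2 <- ifelse(ev$kind == "doublet",
                     ev$amp2_uv * ev$dur2_s * sqrt(2 * pi) / 4 * (2 / pi), 0)
  pow1 <- ev$amp1_uv^2 * ev$dur1_s * sqrt(pi) / 4 / 2
  pow2 <- ifelse(ev$kind == "doublet",
                 ev$amp2_uv^2 * ev$dur2_s * sqrt(pi) / 4 / 2, 0)
  # calcium area ~ kernel integral x event scale (+ gained second response)
  kern_int <- (cfg$decay_tau - cfg$rise_tau) / 1000
  ca_area <- ev$ca_scale * kern_int *
    ifelse(ev$kind == "doublet", 1 + ev$gain, 1)
  data.frame(
    event_id = ev$event_id, kind = ev$kind, group = ev$group,
    duration_ms = dur_ms,
    peak_to_peak_uv = 2 * ifelse(ev$kind == "doublet",
                                 pmax(ev$amp1_uv, ev$amp2_uv), ev$amp1_uv),
    area_uvs = env_int1 + env_int2,
    power_uv2s = pow1 + pow2,
    frequency_hz = cfg$ripple_carrier,
    ca_area_dffs = ca_area,
    stringsAsFactors = FALSE
  )
}
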