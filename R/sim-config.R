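#' Configuration of the coupled LFP / dendritic-imaging forward model
#'
#' Returns a validated configuration for the synthetic session generator.
#' Defaults encode the population statistics that define the study
#' conditions: ripple singlet duration 35.6 ms, doublet inter-event delay
#' 145.76 +/- 18.77 ms, dendritic spatial threshold at 133.24 um, hot-spot
#' FWHM 5.41 um, initiation lead 13.83 ms, propagation speed 6.60 um/ms,
#' GCaMP6f-like decay of 340 ms, doublet gain 2.92 and imaging noise SD
#' 0.0461 dF/F.
#'
#' @param duration recording length, s
#' @param lfp_rate LFP sampling rate, samples/s
#' @param imaging_rate imaging frame rate, frames/s
#' @param n_dendrites number of simulated dendritic segments
#' @param position_step spatial sampling along the dendrite, um
#' @param dendrite_length dendrite length from the soma, um
#' @param event_rate SPW-R complex rate, events/min
#' @param group_mix proportions of (low-ripple, high-ripple, doublet)
#'   complexes; must sum to 1
#' @param ripple_carrier ripple oscillation frequency, Hz
#' @param ripple_cycles nominal cycles per ripple (informational; the
#'   wavelet support is set by the drawn duration)
#' @param singlet_duration_mean,singlet_duration_sd per-event ripple
#'   duration distribution, ms
#' @param doublet_gap_mean,doublet_gap_sd onset-to-onset delay of the two
#'   events of a doublet, ms
#' @param sharpwave_amp amplitude of the slow sharp-wave deflection, uV
#' @param ripple_amp_low,ripple_amp_high ripple wavelet amplitudes of the
#'   two singlet classes, uV
#' @param amp_jitter_log SD of the per-event lognormal amplitude jitter
#'   (log scale); the default keeps the two singlet classes >= 3 SD apart
#' @param spatial_threshold sigmoid midpoint of the dendritic spike
#'   amplitude profile, um
#' @param hotspot_fwhm full width at half maximum of hot spots, um
#' @param hotspot_lead initiation lead of hot-spot centers over lateral
#'   dendrite, ms
#' @param propagation_speed dendritic spike propagation speed, um/ms
#' @param decay_tau,rise_tau double-exponential indicator kernel time
#'   constants, ms
#' @param doublet_gain amplitude scaling of the second calcium response of
#'   a doublet relative to linear summation
#' @param gain_decay_tau e-fold time of the doublet gain as a function of
#'   the inter-event delay, ms; `Inf` keeps the gain constant
#' @param imaging_noise_sd additive imaging noise SD, dF/F
#' @param lfp_noise_sd broadband (pink) LFP noise SD, uV
#' @param ca_scale_low,ca_scale_high calcium response scaling of low- and
#'   high-ripple events (dF/F multiplier of the unit spatial profile)
#' @param ca_jitter_log SD of the per-event lognormal calcium amplitude
#'   jitter (log scale)
#' @param ca_onset_delay_ms delay from the ripple peak (time zero) to the
#'   calcium kernel onset at the hot-spot center, ms
#' @param dspike_amp sigmoid amplitude of the dendritic spike profile, dF/F
#' @param dspike_base,dspike_ramp proximal baseline intercept (dF/F) and
#'   slope (dF/F per um) of the dendritic spike profile
#' @param dspike_slope sigmoid steepness, um
#' @param hotspot_amp amplitude of the Gaussian hot-spot bump, dF/F
#' @param n_hotspots hot spots per dendritic spike event
#' @param dspike_prob probability that a given dendrite fires a dendritic
#'   spike during a given SPW-R complex
#' @param bap_rate rate of SPW-R-independent global (backpropagating AP)
#'   events, events/min
#' @param bap_amp,bap_lambda somatic amplitude (dF/F) and exponential
#'   length constant (um) of the global activation profile
#' @param f0_baseline baseline fluorescence used when emitting raw
#'   fluorescence, arbitrary units
#' @param artifact_rate rate of shared (bilateral) artifacts injected on
#'   local and contralateral channels, events/min
#' @param seed master seed; sub-streams are derived per stage
#' @return an object of class `swr_sim_config`
#' @export
sim_config <- function(duration = 120,
                       lfp_rate = 20000,
                       imaging_rate = 64,
                       n_dendrites = 3,
                       position_step = 1,
                       dendrite_length = 300,
                       event_rate = 10,
                       group_mix = c(low = 0.4, high = 0.4, doublet = 0.2),
                       ripple_carrier = 180,
                       ripple_cycles = 6,
                       singlet_duration_mean = 35.6,
                       singlet_duration_sd = 8,
                       doublet_gap_mean = 145.76,
                       doublet_gap_sd = 18.77,
                       sharpwave_amp = 100,
                       ripple_amp_low = 30,
                       ripple_amp_high = 60,
                       amp_jitter_log = 0.2,
                       spatial_threshold = 133.24,
                       hotspot_fwhm = 5.41,
                       hotspot_lead = 13.83,
                       propagation_speed = 6.60,
                       decay_tau = 340,
                       rise_tau = 20,
                       doublet_gain = 2.92,
                       gain_decay_tau = Inf,
                       imaging_noise_sd = 0.0461,
                       lfp_noise_sd = 10,
                       ca_scale_low = 0.33,
                       ca_scale_high = 1,
                       ca_jitter_log = 0.3,
                       ca_onset_delay_ms = 0,
                       dspike_amp = 0.8,
                       dspike_base = 0.15,
                       dspike_ramp = 0.001,
                       dspike_slope = 8,
                       hotspot_amp = 0.5,
                       n_hotspots = 1,
                       dspike_prob = 0.28,
                       bap_rate = 2,
                       bap_amp = 0.6,
                       bap_lambda = 150,
                       f0_baseline = 100,
                       artifact_rate = 0,
                       seed = 1L) {
  cfg <- list(
    duration = duration, lfp_rate = lfp_rate, imaging_rate = imaging_rate,
    n_dendrites = n_dendrites, position_step = position_step,
    dendrite_length = dendrite_length, event_rate = event_rate,
    group_mix = group_mix, ripple_carrier = ripple_carrier,
    ripple_cycles = ripple_cycles,
    singlet_duration_mean = singlet_duration_mean,
    singlet_duration_sd = singlet_duration_sd,
    doublet_gap_mean = doublet_gap_mean, doublet_gap_sd = doublet_gap_sd,
    sharpwave_amp = sharpwave_amp, ripple_amp_low = ripple_amp_low,
    ripple_amp_high = ripple_amp_high, amp_jitter_log = amp_jitter_log,
    spatial_threshold = spatial_threshold, hotspot_fwhm = hotspot_fwhm,
    hotspot_lead = hotspot_lead, propagation_speed = propagation_speed,
    decay_tau = decay_tau, rise_tau = rise_tau, doublet_gain = doublet_gain,
    gain_decay_tau = gain_decay_tau, imaging_noise_sd = imaging_noise_sd,
    lfp_noise_sd = lfp_noise_sd, ca_scale_low = ca_scale_low,
    ca_scale_high = ca_scale_high, ca_jitter_log = ca_jitter_log,
    ca_onset_delay_ms = ca_onset_delay_ms, dspike_amp = dspike_amp,
    dspike_base = dspike_base, dspike_ramp = dspike_ramp,
    dspike_slope = dspike_slope, hotspot_amp = hotspot_amp,
    n_hotspots = n_hotspots, dspike_prob = dspike_prob,
    bap_rate = bap_rate, bap_amp = bap_amp, bap_lambda = bap_lambda,
    f0_baseline = f0_baseline, artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "swr_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks strict positivity of rates, durations, time constants and
#' amplitudes, that the group mixture is a probability vector, and that the
#' spatial threshold lies inside the dendrite.
#'
#' @param cfg an `swr_sim_config`
#' @return `cfg`, invisibly, or an error naming the failing constraint
#' @export
validate_sim_config <- function(cfg) {
  pos <- c("duration", "lfp_rate", "imaging_rate", "n_dendrites",
           "position_step", "dendrite_length", "event_rate",
           "ripple_carrier", "singlet_duration_mean", "doublet_gap_mean",
           "sharpwave_amp", "ripple_amp_low", "ripple_amp_high",
           "spatial_threshold", "hotspot_fwhm", "hotspot_lead",
           "propagation_speed", "decay_tau", "rise_tau", "doublet_gain",
           "f0_baseline")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop(sprintf("sim_config: field '%s' must be a single positive number", f))
    }
  }
  nonneg <- c("imaging_noise_sd", "lfp_noise_sd", "doublet_gap_sd",
              "singlet_duration_sd", "amp_jitter_log", "ca_jitter_log",
              "bap_rate", "artifact_rate")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("sim_config: field '%s' must be non-negative", f))
    }
  }
  gm <- cfg$group_mix
  if (length(gm) != 3 || any(gm < 0) || abs(sum(gm) - 1) > 1e-9) {
    stop("sim_config: group_mix must be 3 non-negative proportions summing to 1 (within 1e-9)")
  }
  if (cfg$spatial_threshold >= cfg$dendrite_length) {
    stop("sim_config: spatial_threshold must be smaller than dendrite_length")
  }
  if (cfg$dspike_prob < 0 || cfg$dspike_prob > 1) {
    stop("sim_config: dspike_prob must lie in [0, 1]")
  }
  invisible(cfg)
}
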