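#' Schedule SPW-R complexes, dendritic spike assignments and ground truth
#'
#' Draws the event schedule of a synthetic session: SPW-R complex onsets on
#' a jittered grid with a 500 ms refractory period between complexes, group
#' labels (low-ripple / high-ripple / doublet) from the configured mixture,
#' per-event ripple amplitudes and calcium scalings with lognormal jitter,
#' doublet inter-event delays, per-dendrite dendritic spike assignments
#' with hot-spot centers, and SPW-R-independent global (bAP) events placed
#' between complexes. The first second of the session is kept event-free so
#' that downstream baselines (2 SD rule over the first 100-500 ms) are
#' clean.
#'
#' Doublet second events draw their ripple amplitude from the low class,
#' mirroring the observation that the second event of a doublet belongs
#' statistically to the low-ripple group, while their calcium response is
#' the high-class response scaled by the doublet gain.
#'
#' @param cfg an [sim_config()] object
#' @return an object of class `swr_ground_truth`: a list with
#'   `events` (data.frame: event_id, onset_s, kind, group, sub-event onset
#'   and duration columns, gap_s, ripple amplitudes, ca_scale, gain),
#'   `dspikes` (data.frame: event_id, dendrite_id, dspike, hotspot_um),
#'   `baps` (data.frame of global-event onsets), `artifacts` (onsets of
#'   shared bilateral artifacts), and `threshold_position` (um)
#' @export
schedule_events <- function(cfg) {
  validate_sim_config(cfg)
  n_events <- round(cfg$event_rate * cfg$duration / 60)
  span_max <- 0.35                           # worst-case complex span, s
  refractory <- 0.5
  lead_in <- 1.0
  usable <- cfg$duration - lead_in - 1.0
  if (n_events < 1 || usable / max(1, n_events) < refractory + span_max) {
    stop(sprintf(
      paste0("schedule_events: duration %.1f s is too short to place %d events ",
             "at %.1f events/min with a %.0f ms refractory period between complexes"),
      cfg$duration, n_events, cfg$event_rate, 1000 * refractory))
  }
  with_seed(derive_seed(cfg$seed, "schedule"), {
    slot <- usable / n_events
    onsets <- lead_in + (seq_len(n_events) - 1) * slot +
      stats::runif(n_events, 0, max(0, slot - refractory - span_max))
    groups <- sample(c("low", "high", "doublet"), n_events, replace = TRUE,
                     prob = cfg$group_mix)
    kind <- ifelse(groups == "doublet", "doublet", "singlet")

    dur1 <- pmin(pmax(stats::rnorm(n_events, cfg$singlet_duration_mean,
                                   cfg$singlet_duration_sd), 20), 60) / 1000
    dur2 <- pmin(pmax(stats::rnorm(n_events, cfg$singlet_duration_mean,
                                   cfg$singlet_duration_sd), 20), 60) / 1000
    gap <- pmin(pmax(stats::rnorm(n_events, cfg$doublet_gap_mean,
                                  cfg$doublet_gap_sd), 60), 250) / 1000
    gap[kind != "doublet"] <- NA_real_
    dur2[kind != "doublet"] <- NA_real_

    amp_class1 <- ifelse(groups == "low", cfg$ripple_amp_low, cfg$ripple_amp_high)
    amp1 <- amp_class1 * exp(stats::rnorm(n_events, 0, cfg$amp_jitter_log))
    amp2 <- ifelse(kind == "doublet",
                   cfg$ripple_amp_low * exp(stats::rnorm(n_events, 0, cfg$amp_jitter_log)),
                   NA_real_)

    ca_class <- ifelse(groups == "low", cfg$ca_scale_low, cfg$ca_scale_high)
    ca_scale <- ca_class * exp(stats::rnorm(n_events, 0, cfg$ca_jitter_log))
    gain <- ifelse(kind == "doublet",
                   cfg$doublet_gain *
                     if (is.finite(cfg$gain_decay_tau)) {
                       exp(-(gap * 1000 - cfg$doublet_gap_mean) / cfg$gain_decay_tau)
                     } else 1,
                   NA_real_)

    events <- data.frame(
      event_id = seq_len(n_events), onset_s = onsets, kind = kind,
      group = c(low = "low_ripple", high = "high_ripple",
                doublet = "doublet")[groups],
      dur1_s = dur1, onset2_s = onsets + gap, dur2_s = dur2, gap_s = gap,
      amp1_uv = amp1, amp2_uv = amp2, ca_scale = ca_scale, gain = gain,
      stringsAsFactors = FALSE
    )

    # dendritic spike assignments + hot-spot centers (distal, inside margins)
    grid <- expand.grid(event_id = events$event_id,
                        dendrite_id = seq_len(cfg$n_dendrites))
    grid$dspike <- stats::runif(nrow(grid)) < cfg$dspike_prob
    lo <- min(cfg$spatial_threshold + 20, cfg$dendrite_length - 30)
    hi <- cfg$dendrite_length - 20
    grid$hotspot_um <- ifelse(grid$dspike, stats::runif(nrow(grid), lo, hi),
                              NA_real_)

    # global (bAP) events in the gaps between complexes
    n_bap <- round(cfg$bap_rate * cfg$duration / 60)
    bap_onsets <- numeric(0)
    if (n_bap > 0) {
      cand <- stats::runif(20 * n_bap, lead_in, cfg$duration - 1.5)
      busy <- vapply(cand, function(t0) {
        any(t0 > onsets - 0.6 & t0 < onsets + span_max + 0.6)
      }, logical(1))
      cand <- cand[!busy]
      cand <- cand[c(TRUE, diff(sort(cand)) > refractory)][seq_len(min(n_bap, length(cand)))]
      bap_onsets <- sort(cand[!is.na(cand)])
    }

    n_art <- round(cfg$artifact_rate * cfg$duration / 60)
    art_onsets <- numeric(0)
    if (n_art > 0) {
      # artifacts ride on a subset of scheduled complexes so that the
      # contralateral rejection rule has true positives to remove
      art_onsets <- sort(sample(onsets, min(n_art, n_events)))
    }

    truth <- list(events = events, dspikes = grid,
                  baps = data.frame(onset_s = bap_onsets),
                  artifacts = data.frame(onset_s = art_onsets),
                  threshold_position = cfg$spatial_threshold)
    class(truth) <- "swr_ground_truth"
    truth
  })
}

#' Ground-truth sidecar table
#'
#' Flattens a ground truth object into one long table
#' (event_id, onset_s, kind, group, amp, dendrite_id, dspike, hotspot_um)
#' suitable for CSV export next to a written session.
#'
#' @param truth an `swr_ground_truth`
#' @return a data.frame
#' @export
truth_table <- function(truth) {
  ev <- truth$events[, c("event_id", "onset_s", "kind", "group", "amp1_uv")]
  names(ev)[names(ev) == "amp1_uv"] <- "amp"
  merge(ev, truth$dspikes, by = "event_id", sort = TRUE)
}
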