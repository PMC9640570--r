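#' Match calcium responses to SPW-R events
#'
#' A response and a ripple complex are simultaneous when the response's
#' `[T3, Tpeak]` interval overlaps the complex span `[T1, T2]` (for
#' doublets, `[T1, T22]`). When several complexes qualify, the one whose
#' time zero (peak of |filtered LFP|) is nearest the calcium peak wins; a
#' response overlapping both sub-events of a doublet is one matched
#' doublet response, not two. The jitter is `t_peak(Ca) - t_zero(ripple)`
#' in ms, positive when the calcium peak follows the ripple peak.
#'
#' @param responses data.frame from [detect_responses()]
#' @param ripples event table from [detect_ripples()] (rejected events are
#'   ignored)
#' @return data.frame: response columns plus `matched_event_id`,
#'   `jitter_ms`
#' @export
match_events <- function(responses, ripples) {
  ripples <- ripples[!isTRUE(ripples$rejected) & !(ripples$rejected %in% TRUE), , drop = FALSE]
  if (nrow(responses) > 0 && nrow(ripples) > 0) {
    span_resp <- range(c(responses$t3_s, responses$t_peak_s))
    span_rip <- range(c(ripples$t1_s, ripples$t_end_s))
    if (span_resp[1] > span_rip[2] || span_rip[1] > span_resp[2]) {
      stop("match_events: imaging and LFP streams do not overlap in time (clock mismatch?)")
    }
  }
  responses$matched_event_id <- NA_integer_
  responses$jitter_ms <- NA_real_
  for (i in seq_len(nrow(responses))) {
    a0 <- responses$t3_s[i]
    a1 <- responses$t_peak_s[i]
    hit <- which(ripples$t1_s <= a1 & ripples$t_end_s >= a0)
    if (length(hit) == 0) next
    if (length(hit) > 1) {
      hit <- hit[which.min(abs(ripples$t_zero_s[hit] - responses$t_peak_s[i]))]
    }
    responses$matched_event_id[i] <- ripples$event_id[hit]
    responses$jitter_ms[i] <- (responses$t_peak_s[i] - ripples$t_zero_s[hit]) * 1000
  }
  responses
}

#' Classify a dendritic response as local dSpike or global bAP
#'
#' Local dendritic spikes show distally dominant amplitudes (positive
#' amplitude-distance slope, distal/proximal mean ratio above `r_min`);
#' global backpropagating APs show the antagonistic proximally dominant
#' profile (negative slope, ratio below `1/r_min`). Anything else,
#' including flat profiles or profiles with too few samples on either
#' side, is left unclassified.
#'
#' @param per_position_amp amplitude vector
#' @param positions distances, um
#' @param proximal_cut proximal region upper edge, um
#' @param distal_cut distal region lower edge, um
#' @param r_min distal/proximal dominance ratio required for a call
#' @return list with `mode` ("local_dspike", "global_bap", or
#'   "unclassified"), `slope` (dF/F per um), `ratio` (distal/proximal),
#'   and `reason` when unclassified
#' @export
classify_mode <- function(per_position_amp, positions, proximal_cut = 20,
                          distal_cut = 150, r_min = 2) {
  prox <- positions <= proximal_cut
  dist <- positions >= distal_cut
  if (sum(prox) < 4 || sum(dist) < 4) {
    return(list(mode = "unclassified", slope = NA_real_, ratio = NA_real_,
                reason = "fewer than 4 positions in the proximal or distal range"))
  }
  slope <- unname(stats::coef(stats::lm(per_position_amp ~ positions))[2])
  pm <- mean(per_position_amp[prox])
  dm <- mean(per_position_amp[dist])
  ratio <- if (pm > 0) dm / pm else Inf * sign(dm)
  mode <- if (slope > 0 && is.finite(ratio) && ratio > r_min) "local_dspike"
  else if (slope < 0 && is.finite(ratio) && ratio < 1 / r_min) "global_bap"
  else "unclassified"
  list(mode = mode, slope = slope, ratio = ratio,
       reason = if (mode == "unclassified") "ambiguous spatial profile" else "")
}

#' Classify all matched responses of a session
#'
#' Runs [classify_mode()] on the per-position amplitudes of each detected
#' response and merges the verdicts with the matching information.
#'
#' @param responses matched responses ([match_events()] output)
#' @param images named list of dF/F `swr_dendrite` objects indexed by
#'   dendrite id
#' @param ... passed to [classify_mode()]
#' @return `responses` with `mode`, `slope`, `distal_proximal_ratio`
#' @export
classify_responses <- function(responses, images, ...) {
  responses$mode <- "unclassified"
  responses$slope <- NA_real_
  responses$distal_proximal_ratio <- NA_real_
  for (i in seq_len(nrow(responses))) {
    img <- images[[responses$dendrite_id[i]]]
    amp <- per_position_amplitudes(img, responses[i, ])
    cl <- classify_mode(amp, img$positions, ...)
    responses$mode[i] <- cl$mode
    responses$slope[i] <- cl$slope
    responses$distal_proximal_ratio[i] <- cl$ratio
  }
  responses
}

#' Activation ratios of dendritic spikes over SPW-R events
#'
#' `total_ratio` = matched local dSpikes / SPW-R events;
#' `per_dendrite_active_fraction` = dendrites with at least one dSpike /
#' all dendrites; `per_cell_mean_ratio` = mean over cells of their own
#' dSpike/ripple ratio. With zero ripple events the ratios are undefined
#' and reported as `NA`, not zero.
#'
#' @param events classified responses (with `mode`, `matched_event_id`,
#'   `dendrite_id` and optionally `cell_id`)
#' @param n_ripples number of accepted SPW-R events
#' @param n_dendrites number of recorded dendrites
#' @return list with the three ratios (fractions in [0, 1]) and the
#'   underlying counts
#' @export
activation_ratios <- function(events, n_ripples, n_dendrites) {
  ds <- events[events$mode == "local_dspike" & !is.na(events$matched_event_id), , drop = FALSE]
  n_dspikes <- nrow(ds)
  total <- if (n_ripples > 0) n_dspikes / n_ripples else NA_real_
  active <- length(unique(ds$dendrite_id))
  frac <- if (n_dendrites > 0) active / n_dendrites else NA_real_
  per_cell <- if (n_ripples > 0 && "cell_id" %in% names(events)) {
    cells <- unique(events$cell_id)
    mean(vapply(cells, function(cl) {
      sum(ds$cell_id == cl) / n_ripples
    }, numeric(1)))
  } else total
  list(total_ratio = total, per_dendrite_active_fraction = frac,
       per_cell_mean_ratio = per_cell,
       n_dspikes = n_dspikes, n_ripples = n_ripples,
       n_active_dendrites = active, n_dendrites = n_dendrites)
}
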