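#' Relative fluorescence change dF/F
#'
#' `dF/F = (F - F0) / F0` elementwise, with the baseline `F0` estimated
#' per position as a percentile (default the 20th) of that position's
#' trace over the baseline window. The percentile baseline is robust to
#' sparse transients riding on the trace.
#'
#' @param img an `swr_dendrite` with raw fluorescence (`is_dff = FALSE`)
#' @param baseline_window time window used for `F0`, s (default the whole
#'   trace)
#' @param percentile baseline percentile, in (0, 100)
#' @return the image with `values` replaced by dF/F and `is_dff = TRUE`
#' @export
compute_dff <- function(img, baseline_window = NULL, percentile = 20) {
  if (isTRUE(img$is_dff)) stop("compute_dff: image is already dF/F")
  n_frames <- ncol(img$values)
  tt <- (seq_len(n_frames) - 1) / img$frame_rate
  sel <- if (is.null(baseline_window)) rep(TRUE, n_frames) else {
    tt >= baseline_window[1] & tt < baseline_window[2]
  }
  if (!any(sel)) stop("compute_dff: empty baseline window")
  f0 <- apply(img$values[, sel, drop = FALSE], 1, stats::quantile,
              probs = percentile / 100, names = FALSE)
  bad <- which(f0 <= 0)
  if (length(bad) > 0) {
    stop(sprintf("compute_dff: baseline F0 <= 0 at position %.1f um",
                 img$positions[bad[1]]))
  }
  img$values <- sweep(sweep(img$values, 1, f0, "-"), 1, f0, "/")
  img$is_dff <- TRUE
  img$f0 <- f0
  img$soma_trace <- img$values[1, ]
  img
}

# Spatially averaged detection trace over a region of the dendrite.
region_trace <- function(img, region = c("distal_third", "all", "proximal")) {
  region <- match.arg(region)
  pos <- img$positions
  sel <- switch(region,
                distal_third = pos >= max(pos) * 2 / 3,
                all = rep(TRUE, length(pos)),
                proximal = pos <= 20)
  colMeans(img$values[sel, , drop = FALSE])
}

# Split one supra-threshold interval at troughs that fall below half the
# smaller of two flanking peaks, provided the second peak rises clearly
# above the trough (a genuine new event, not a noise wiggle on a decay
# tail); keeps compound (doublet) responses whole while separating
# well-spaced events.
split_interval <- function(trace, i0, i1, thr, min_rise = 0) {
  seg <- trace[i0:i1]
  n <- length(seg)
  if (n < 5) return(list(c(i0, i1)))
  peaks <- which(diff(sign(diff(seg))) < 0) + 1L
  peaks <- peaks[seg[peaks] > thr]
  if (length(peaks) < 2) return(list(c(i0, i1)))
  cuts <- integer(0)
  last_peak <- peaks[1]
  for (p in peaks[-1]) {
    trough_idx <- last_peak + which.min(seg[last_peak:p]) - 1L
    rise_floor <- max(min_rise, 0.5 * seg[trough_idx])
    if (seg[trough_idx] < 0.5 * min(seg[last_peak], seg[p]) &&
        (seg[p] - seg[trough_idx]) >= rise_floor) {
      cuts <- c(cuts, trough_idx)
      last_peak <- p
    } else if (seg[p] > seg[last_peak]) last_peak <- p
  }
  if (length(cuts) == 0) return(list(c(i0, i1)))
  bounds <- c(i0, i0 + cuts - 1L, i1)
  lapply(seq_len(length(bounds) - 1L), function(k) c(bounds[k], bounds[k + 1L]))
}

#' Detect calcium responses with the 2 SD rule
#'
#' A response exists wherever the spatially averaged dF/F exceeds the
#' baseline mean by `threshold_sd` baseline SDs; the SD is computed from
#' an early event-free window (default the first 100-500 ms). `T3`/`T4`
#' are the threshold crossings (sub-frame interpolated), the peak
#' amplitude is the mean over a 60 ms window centered at the peak, and
#' the area is the integral over `[T3, T4]`. A candidate is accepted only
#' when its 60 ms peak-window mean itself clears the `threshold_sd`
#' criterion and the crossing persists for at least two frames, so that
#' single-frame noise excursions are not counted as responses. Supra-threshold intervals containing well-separated peaks
#' (trough below half the smaller peak) are split so that distinct events
#' with slow indicator tails are not fused; compound doublet responses,
#' whose inter-event trough stays shallow, are kept whole. With a
#' degenerate zero-SD baseline the threshold falls back to 1% of the
#' trace maximum.
#'
#' @param img an `swr_dendrite` with dF/F values
#' @param threshold_sd threshold in baseline SDs (default 2)
#' @param sd_window window for the baseline SD, s (default `c(0.1, 0.5)`)
#' @param region spatial averaging region for detection (the distal third
#'   by default, for dendritic-spike sensitivity)
#' @param peak_window_ms averaging window around the peak, ms
#' @return data.frame of responses: `response_id`, `dendrite_id`, `t3_s`,
#'   `t4_s`, `t_peak_s`, `peak_amp_dff`, `area_dffs`
#' @export
detect_responses <- function(img, threshold_sd = 2, sd_window = c(0.1, 0.5),
                             region = "distal_third", peak_window_ms = 60) {
  if (!isTRUE(img$is_dff)) stop("detect_responses: image must be dF/F (run compute_dff)")
  trace <- region_trace(img, region)
  rate <- img$frame_rate
  n <- length(trace)
  tt <- (seq_len(n) - 1) / rate
  if (max(tt) <= sd_window[2]) {
    stop(sprintf("detect_responses: trace (%.2f s) shorter than the sd_window end (%.2f s)",
                 max(tt), sd_window[2]))
  }
  base_sel <- tt >= sd_window[1] & tt < sd_window[2]
  base_mean <- mean(trace[base_sel])
  base_sd <- stats::sd(trace[base_sel])
  thr <- if (base_sd > 0) base_mean + threshold_sd * base_sd else {
    base_mean + 0.01 * (max(trace) - base_mean)
  }
  above <- trace > thr
  if (!any(above)) {
    return(data.frame(response_id = integer(0), dendrite_id = integer(0),
                      t3_s = numeric(0), t4_s = numeric(0),
                      t_peak_s = numeric(0), peak_amp_dff = numeric(0),
                      area_dffs = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  raw_iv <- Map(c, starts[r$values], ends[r$values])
  # hysteresis: sub-threshold gaps shorter than 150 ms are threshold
  # flutter on a decaying transient, not separate events (well-separated
  # events that rise out of a shared interval are split again below)
  max_gap <- round(0.15 * rate)
  merged_iv <- list(raw_iv[[1]])
  for (b in raw_iv[-1]) {
    last <- merged_iv[[length(merged_iv)]]
    if (b[1] - last[2] <= max_gap) {
      merged_iv[[length(merged_iv)]] <- c(last[1], b[2])
    } else {
      merged_iv[[length(merged_iv) + 1]] <- b
    }
  }
  iv <- do.call(c, lapply(merged_iv, function(b) {
    split_interval(trace, b[1], b[2], thr, min_rise = 6 * base_sd)
  }))

  half_w <- max(1L, round(peak_window_ms / 1000 * rate / 2))
  rows <- lapply(iv, function(b) {
    seg <- trace[b[1]:b[2]]
    ip <- b[1] + which.max(seg) - 1L
    w0 <- max(1L, ip - half_w)
    w1 <- min(n, ip + half_w)
    if (w0 == 1L || w1 == n) {
      # peak window clipped at the trace edge; note and continue
      message(sprintf("detect_responses: %d ms peak window clipped at trace edge (t = %.2f s)",
                      peak_window_ms, tt[ip]))
    }
    # sub-frame interpolation of the threshold crossings
    t3 <- tt[b[1]]
    if (b[1] > 1L && trace[b[1]] > trace[b[1] - 1L]) {
      t3 <- tt[b[1] - 1L] + (thr - trace[b[1] - 1L]) /
        (trace[b[1]] - trace[b[1] - 1L]) / rate
    }
    t4 <- tt[b[2]]
    if (b[2] < n && trace[b[2]] > trace[b[2] + 1L]) {
      t4 <- tt[b[2]] + (trace[b[2]] - thr) /
        (trace[b[2]] - trace[b[2] + 1L]) / rate
    }
    data.frame(t3_s = t3, t4_s = t4, t_peak_s = tt[ip],
               peak_amp_dff = mean(trace[w0:w1]) - base_mean,
               area_dffs = trapz_uniform(trace[b[1]:b[2]] - base_mean, 1 / rate))
  })
  out <- do.call(rbind, rows)
  # acceptance rule: the 60 ms peak-window mean must itself clear the
  # 2 SD criterion, and the crossing must persist for >= 2 frames --
  # single-frame noise excursions are not responses
  n_frames <- vapply(iv, function(b) b[2] - b[1] + 1L, integer(1))
  keep <- n_frames >= 2L &
    (base_sd == 0 | out$peak_amp_dff > threshold_sd * base_sd)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    return(data.frame(response_id = integer(0), dendrite_id = integer(0),
                      t3_s = numeric(0), t4_s = numeric(0),
                      t_peak_s = numeric(0), peak_amp_dff = numeric(0),
                      area_dffs = numeric(0)))
  }
  cbind(response_id = seq_len(nrow(out)),
        dendrite_id = img$dendrite_id %||% NA_integer_, out)
}

#' Per-position peak amplitudes of one response
#'
#' For each dendritic position, the mean dF/F over a 60 ms window centered
#' at that position's own local peak inside `[T3, T4]`.
#'
#' @param img an `swr_dendrite` with dF/F values
#' @param resp one row of [detect_responses()] output
#' @param peak_window_ms averaging window, ms
#' @return numeric vector of amplitudes, one per position
#' @export
per_position_amplitudes <- function(img, resp, peak_window_ms = 60) {
  rate <- img$frame_rate
  n <- ncol(img$values)
  i0 <- max(1L, round(resp$t3_s * rate) + 1L)
  i1 <- min(n, round(resp$t4_s * rate) + 1L)
  half_w <- max(1L, round(peak_window_ms / 1000 * rate / 2))
  vapply(seq_along(img$positions), function(i) {
    seg <- img$values[i, i0:i1]
    ip <- i0 + which.max(seg) - 1L
    mean(img$values[i, max(1L, ip - half_w):min(n, ip + half_w)])
  }, numeric(1))
}

#' Bin amplitudes by distance from the soma
#'
#' Half-open bins `[k*bin, (k+1)*bin)`; empty bins are reported with
#' `n = 0` and `NA` means.
#'
#' @param amplitudes amplitude vector
#' @param positions matching distances, um
#' @param bin_um bin width, um (default 25)
#' @return data.frame: `bin_center_um`, `mean_amp`, `sem_amp`, `n`
#' @export
bin_by_distance <- function(amplitudes, positions, bin_um = 25) {
  if (bin_um <= 0) stop("bin_by_distance: bin_um must be positive")
  k <- floor(positions / bin_um)
  kk <- seq(0, max(k))
  rows <- lapply(kk, function(b) {
    sel <- k == b
    n <- sum(sel)
    data.frame(bin_center_um = (b + 0.5) * bin_um,
               mean_amp = if (n > 0) mean(amplitudes[sel]) else NA_real_,
               sem_amp = if (n > 1) stats::sd(amplitudes[sel]) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, rows)
}
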