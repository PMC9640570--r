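#' Estimate the dendritic spatial threshold (profile inflection)
#'
#' Fits a linear-baseline-plus-logistic model
#' `amp ~ b0 + b1 * x + A / (1 + exp(-(x - m) / s))` to a spatial
#' amplitude profile; the threshold is the logistic midpoint `m`. When
#' the fit does not converge the estimate falls back to the position of
#' the maximum of a smoothed second derivative of the profile. Profiles
#' with no inflection (monotone-flat, or a logistic amplitude that is not
#' distinguishable from the baseline ramp) yield an absent threshold, not
#' zero. The estimate is invariant to amplitude scaling and offsets.
#'
#' @param bin_centers positions, um
#' @param mean_amp amplitude per position, dF/F
#' @return list with `threshold_um` (`NA_real_` when absent), `method`
#'   ("logistic", "second_derivative", or "none"), and `residual_sd`
#' @export
estimate_spatial_threshold <- function(bin_centers, mean_amp) {
  ok <- is.finite(bin_centers) & is.finite(mean_amp)
  x <- bin_centers[ok]
  y <- mean_amp[ok]
  if (length(x) < 6) stop("estimate_spatial_threshold: need at least 6 bins")
  rng <- diff(range(y))
  if (rng <= 0) return(list(threshold_um = NA_real_, method = "none",
                            residual_sd = 0))
  # crude midpoint start: first crossing of the half range
  half <- min(y) + rng / 2
  m0 <- x[which(y >= half)[1]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b0 + b1 * x + A / (1 + exp(-(x - m) / s)),
      start = list(b0 = min(y), b1 = 0, A = rng, m = m0, s = diff(range(x)) / 30),
      lower = c(-Inf, -Inf, 0, min(x), 0.5),
      upper = c(Inf, Inf, Inf, max(x), diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    res_sd <- stats::sd(stats::residuals(fit))
    # the jump must dominate the linear trend and be genuinely sigmoidal
    # (a very shallow logistic mimics a line, not an inflection)
    ramp_span <- abs(cf["b1"]) * diff(range(x))
    steep_enough <- cf["s"] < diff(range(x)) / 10
    if (cf["A"] > 0.1 * rng && cf["A"] > 0.5 * max(ramp_span, 1e-12) &&
        steep_enough && cf["m"] > min(x) && cf["m"] < max(x)) {
      return(list(threshold_um = unname(cf["m"]), method = "logistic",
                  residual_sd = res_sd))
    }
    if (cf["A"] <= 0.1 * rng || cf["A"] <= 0.5 * ramp_span || !steep_enough) {
      return(list(threshold_um = NA_real_, method = "none",
                  residual_sd = res_sd))
    }
  }
  # fallback: maximum of the smoothed second derivative, accepted only
  # when the curvature clearly exceeds what a straight profile would show
  sm <- stats::smooth.spline(x, y, spar = 0.6)
  xx <- seq(min(x), max(x), length.out = 256)
  d2 <- stats::predict(sm, xx, deriv = 2)$y
  res_sd <- stats::sd(y - stats::predict(sm, x)$y)
  curv_floor <- 0.5 * rng / (diff(range(x)) / 4)^2
  if (max(d2) < curv_floor) {
    return(list(threshold_um = NA_real_, method = "none",
                residual_sd = res_sd))
  }
  list(threshold_um = xx[which.max(d2)], method = "second_derivative",
       residual_sd = res_sd)
}

#' Linear fit to the proximal (sub-threshold) profile
#'
#' Least-squares line on bins strictly below the spatial threshold.
#'
#' @param bin_centers positions, um
#' @param mean_amp amplitudes
#' @param threshold_um spatial threshold, um
#' @return list with `slope` (dF/F per um) and `intercept`, or `NULL`
#'   when fewer than 3 bins lie below the threshold
#' @export
proximal_linear_fit <- function(bin_centers, mean_amp, threshold_um) {
  sel <- bin_centers < threshold_um & is.finite(mean_amp)
  if (sum(sel) < 3) return(NULL)
  cf <- stats::coef(stats::lm(mean_amp[sel] ~ bin_centers[sel]))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

# Prominence of a local maximum: height above the higher of the two
# minima separating it from higher terrain (or the series edge).
peak_prominence <- function(y, peak) {
  n <- length(y)
  left <- if (peak > 1) {
    higher <- which(y[seq_len(peak - 1)] > y[peak])
    lo <- if (length(higher) > 0) max(higher) + 1L else 1L
    min(y[lo:(peak - 1L)])
  } else y[peak]
  right <- if (peak < n) {
    higher <- which(y[(peak + 1L):n] > y[peak])
    hi <- if (length(higher) > 0) peak + min(higher) - 1L else n
    min(y[(peak + 1L):hi])
  } else y[peak]
  y[peak] - max(left, right)
}

# Width at a given height around a peak, by linear interpolation.
width_at_height <- function(x, y, peak, height) {
  n <- length(y)
  li <- peak
  while (li > 1 && y[li] > height) li <- li - 1L
  xl <- if (y[li] <= height && li < peak) {
    x[li] + (height - y[li]) / (y[li + 1L] - y[li]) * (x[li + 1L] - x[li])
  } else x[1]
  ri <- peak
  while (ri < n && y[ri] > height) ri <- ri + 1L
  xr <- if (y[ri] <= height && ri > peak) {
    x[ri - 1L] + (y[ri - 1L] - height) / (y[ri - 1L] - y[ri]) * (x[ri] - x[ri - 1L])
  } else x[n]
  c(xl, xr)
}

#' Detect dendritic hot spots on the temporal integral profile
#'
#' Computes the temporal integral of the dF/F response per position over
#' `[T3, T4]` and finds local maxima with prominence at least
#' `prominence_frac` of the profile's dynamic range and mutual separation
#' of at least `2 * fwhm_expected` (the higher peak wins). The FWHM of
#' each hot spot is measured at half prominence with linear
#' interpolation.
#'
#' @param img an `swr_dendrite` with dF/F values
#' @param resp one response row (for `t3_s` / `t4_s`)
#' @param fwhm_expected expected hot-spot FWHM, um (separation criterion)
#' @param prominence_frac minimum prominence as a fraction of the
#'   profile's dynamic range
#' @return data.frame (possibly empty): `center_um`, `fwhm_um`,
#'   `prominence`, `integral`
#' @export
detect_hotspots <- function(img, resp, fwhm_expected = 5.41,
                            prominence_frac = 0.25) {
  rate <- img$frame_rate
  i0 <- max(1L, round(resp$t3_s * rate) + 1L)
  i1 <- min(ncol(img$values), round(resp$t4_s * rate) + 1L)
  profile <- apply(img$values[, i0:i1, drop = FALSE], 1, trapz_uniform,
                   dt = 1 / rate)
  x <- img$positions
  rng <- diff(range(profile))
  empty <- data.frame(center_um = numeric(0), fwhm_um = numeric(0),
                      prominence = numeric(0), integral = numeric(0))
  if (rng <= 0) return(empty)
  cand <- which(diff(sign(diff(profile))) < 0) + 1L
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(p) peak_prominence(profile, p), numeric(1))
  keep <- prom >= prominence_frac * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  o <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (i in o) {
    if (all(abs(x[cand[i]] - x[cand[chosen]]) >= 2 * fwhm_expected) ||
        length(chosen) == 0) {
      chosen <- c(chosen, i)
    }
  }
  cand <- cand[chosen]; prom <- prom[chosen]
  rows <- lapply(seq_along(cand), function(i) {
    w <- width_at_height(x, profile, cand[i], profile[cand[i]] - prom[i] / 2)
    data.frame(center_um = x[cand[i]], fwhm_um = w[2] - w[1],
               prominence = prom[i], integral = profile[cand[i]])
  })
  res <- do.call(rbind, rows)
  res[order(res$center_um), , drop = FALSE]
}

#' Per-position onset times of a response
#'
#' Onset at each position is the first crossing of `onset_frac` (default
#' 50%) of that position's peak amplitude within `[T3, T4]`, with
#' sub-frame linear interpolation. Positions whose peak stays below
#' `min_peak_frac` of the strongest position's peak get no onset (`NA`).
#'
#' @param img an `swr_dendrite` with dF/F values
#' @param resp one response row
#' @param onset_frac crossing fraction of the local peak (0.2-0.8 sensible)
#' @param min_peak_frac responsiveness floor relative to the maximum peak
#' @return numeric vector of onset times, s (`NA` where absent)
#' @export
onset_map <- function(img, resp, onset_frac = 0.5, min_peak_frac = 0.05) {
  rate <- img$frame_rate
  i0 <- max(1L, round(resp$t3_s * rate) + 1L)
  i1 <- min(ncol(img$values), round(resp$t4_s * rate) + 1L)
  tt <- (seq(i0, i1) - 1) / rate
  peaks <- apply(img$values[, i0:i1, drop = FALSE], 1, max)
  floor_amp <- min_peak_frac * max(peaks)
  vapply(seq_along(img$positions), function(i) {
    if (peaks[i] < floor_amp || peaks[i] <= 0) return(NA_real_)
    y <- img$values[i, i0:i1]
    thr <- onset_frac * peaks[i]
    k <- which(y >= thr)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1) return(tt[1])
    tt[k - 1L] + (thr - y[k - 1L]) / (y[k] - y[k - 1L]) / rate
  }, numeric(1))
}

#' Initiation lead and propagation speed around a hot spot
#'
#' The onset at the hot-spot center leads the lateral dendrite; onsets
#' rise linearly with distance while the spike propagates and plateau
#' once it has invaded the rest of the segment. Per side, the plateau
#' delay (median onset delay over the outer 30% of the side's extent)
#' estimates the initiation lead, and the inverse slope of onset against
#' distance below the plateau knee (95% of the plateau) estimates the
#' propagation speed: centripetal toward the soma, centrifugal away from
#' it. A synchronous side (zero slope) reports an infinite speed; a side
#' with fewer than 3 onsets reports `NA`.
#'
#' @param onsets onset times per position, s (from [onset_map()])
#' @param positions distances from the soma, um
#' @param center_um hot-spot center, um
#' @return list: `onset_lead_ms`, `speed_centripetal`,
#'   `speed_centrifugal` (um/ms)
#' @export
propagation_stats <- function(onsets, positions, center_um) {
  ic <- which.min(abs(positions - center_um))
  t0 <- onsets[ic]
  if (is.na(t0)) {
    return(list(onset_lead_ms = NA_real_, speed_centripetal = NA_real_,
                speed_centrifugal = NA_real_))
  }
  side_stats <- function(sel) {
    d <- abs(positions[sel] - center_um)
    r <- (onsets[sel] - t0) * 1000           # delay, ms
    ok <- is.finite(r) & d > 0
    d <- d[ok]; r <- r[ok]
    if (length(d) < 3) return(list(speed = NA_real_, lead = NA_real_))
    o <- order(d)
    d <- d[o]; r <- r[o]
    if (max(r) <= 0) return(list(speed = Inf, lead = 0))
    # two-segment fit: delay rises as d / v through the origin up to a
    # knee, then plateaus at the initiation lead; the knee is chosen by
    # least squares over the observed distances
    n <- length(d)
    best <- list(sse = Inf, k = n, slope = NA_real_, level = NA_real_)
    for (k in seq(2L, n)) {
      ramp <- seq_len(k)
      slope <- sum(d[ramp] * r[ramp]) / sum(d[ramp]^2)
      sse <- sum((r[ramp] - slope * d[ramp])^2)
      if (k < n) {
        level <- mean(r[(k + 1L):n])
        sse <- sse + sum((r[(k + 1L):n] - level)^2)
      } else level <- NA_real_
      if (sse < best$sse) best <- list(sse = sse, k = k, slope = slope,
                                       level = level)
    }
    speed <- if (is.finite(best$slope) && best$slope > 1e-6) 1 / best$slope else Inf
    # the lead is the plateau delay, read off the outer 30% of the side
    # (robust to knee placement); a knee near the segment end means the
    # spike was still propagating there (censored side): no lead
    outer <- d >= stats::quantile(d, 0.7)
    lead <- if (d[best$k] <= 0.7 * max(d) && sum(outer) >= 2) {
      stats::median(r[outer])
    } else NA_real_
    list(speed = speed, lead = lead)
  }
  toward <- side_stats(positions < center_um)
  away <- side_stats(positions > center_um)
  leads <- c(toward$lead, away$lead)
  list(onset_lead_ms = if (all(is.na(leads))) NA_real_ else mean(leads, na.rm = TRUE),
       speed_centripetal = toward$speed,
       speed_centrifugal = away$speed)
}

#' Correlation between spatial thresholds and branch points
#'
#' Pearson correlation between each dendrite's spatial threshold and its
#' nearest branch-point position. Absent (`NA`) with fewer than 3 pairs
#' or when either vector is constant.
#'
#' @param threshold_positions thresholds, um, one per dendrite
#' @param branch_positions nearest branch-point positions, um
#' @return correlation coefficient or `NA_real_`
#' @export
branch_correlation <- function(threshold_positions, branch_positions) {
  ok <- is.finite(threshold_positions) & is.finite(branch_positions)
  x <- threshold_positions[ok]
  y <- branch_positions[ok]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
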