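#' Extract ripple-aligned calcium transients
#'
#' Cuts a window around each matched ripple's time zero from the
#' spatially averaged (or per-region) dF/F trace and resamples it onto a
#' common time grid by linear interpolation, so that transients from
#' different events share one time base aligned at time zero.
#'
#' @param img an `swr_dendrite` with dF/F values
#' @param t_zeros ripple time zeros, s
#' @param window window around time zero, s (default `c(-0.2, 1.2)`)
#' @param region spatial region ("distal_third", "all", "proximal"), see
#'   [detect_responses()]
#' @return list with `time` (window grid, s) and `traces` (events x time
#'   matrix)
#' @export
extract_aligned_transients <- function(img, t_zeros, window = c(-0.2, 1.2),
                                       region = "distal_third") {
  trace <- region_trace(img, region)
  tt <- (seq_along(trace) - 1) / img$frame_rate
  grid <- seq(window[1], window[2], by = 1 / img$frame_rate)
  traces <- t(vapply(t_zeros, function(tz) {
    stats::approx(tt - tz, trace, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
  list(time = grid, traces = traces)
}

#' Average transient of a group (mean and SEM)
#'
#' @param traces events x time matrix on a common grid
#' @return list with `mean` and `sem` traces, or `NULL` for fewer than 2
#'   traces
#' @export
group_average_transient <- function(traces) {
  if (is.null(traces) || nrow(traces) < 2) return(NULL)
  list(mean = colMeans(traces),
       sem = apply(traces, 2, stats::sd) / sqrt(nrow(traces)))
}

#' Mathematical sum of two transients with a temporal shift
#'
#' `first + shift(second, delay)`; the shifted trace is zero-padded at
#' the left edge. With the high-ripple average in both slots this is the
#' "high + high" construction; substituting the low-ripple average for
#' the second slot gives the "high + low" variant.
#'
#' @param first,second transients on a common grid
#' @param delay_ms shift applied to `second`, ms (>= 0)
#' @param rate grid sampling rate, 1/s
#' @return summed trace, same length
#' @export
math_sum <- function(first, second, delay_ms, rate) {
  if (delay_ms < 0) stop("math_sum: delay must be non-negative")
  grid <- (seq_along(second) - 1) / rate
  shifted <- stats::approx(grid + delay_ms / 1000, second, xout = grid,
                           yleft = 0, rule = 2)$y
  first + shifted
}

# Peak amplitude as the maximum of the running mean over a 60 ms window.
peak_window_amp <- function(trace, rate, window_ms = 60) {
  max(running_mean(trace, max(1, round(window_ms / 1000 * rate))))
}

#' Supralinearity ratio of measured versus summed transients
#'
#' `ratio = 100 * peak(summed) / peak(measured)`, with peaks measured as
#' the 60 ms peak-window mean; a ratio of 100% means linear summation and
#' values below 100% mean the measured compound response exceeds the
#' arithmetic sum. `gain` is the inverse (measured / summed).
#'
#' @param measured measured compound (doublet) transient
#' @param summed mathematical sum transient on the same grid
#' @param rate grid sampling rate, 1/s
#' @param window_ms peak window, ms
#' @return list with `ratio_percent` and `gain`, or `NULL` when the
#'   measured peak is not positive
#' @export
supralinearity_ratio <- function(measured, summed, rate, window_ms = 60) {
  pm <- peak_window_amp(measured, rate, window_ms)
  ps <- peak_window_amp(summed, rate, window_ms)
  if (pm <= 0) return(NULL)
  list(ratio_percent = 100 * ps / pm, gain = pm / ps)
}

#' Regional group statistics with pairwise t-tests
#'
#' Box-plot statistics (median, quartiles, whiskers, 1.5 IQR outliers)
#' per region and group, plus two-sample Student t-tests between groups
#' within each region with the conventional star coding (* p < 0.05,
#' ** p < 0.01, *** p < 0.001). Zero-variance comparisons are skipped
#' with a flag.
#'
#' @param amp data.frame with columns `amp`, `group`, `region`
#' @return list with `stats` (per region x group) and `tests` (pairwise)
#' @export
region_compare <- function(amp) {
  combos <- unique(amp[, c("region", "group")])
  stats_rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- amp$region == combos$region[i] & amp$group == combos$group[i]
    x <- amp$amp[sel]
    bs <- grDevices::boxplot.stats(x)
    data.frame(region = combos$region[i], group = combos$group[i],
               n = length(x), median = bs$stats[3], q1 = bs$stats[2],
               q3 = bs$stats[4], whisker_lo = bs$stats[1],
               whisker_hi = bs$stats[5], n_outliers = length(bs$out))
  })
  tests <- list()
  for (reg in unique(amp$region)) {
    gs <- unique(amp$group[amp$region == reg])
    if (length(gs) < 2) next
    prs <- utils::combn(sort(gs), 2, simplify = FALSE)
    for (pr in prs) {
      a <- amp$amp[amp$region == reg & amp$group == pr[1]]
      b <- amp$amp[amp$region == reg & amp$group == pr[2]]
      if (length(a) < 2 || length(b) < 2) next
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        tests[[length(tests) + 1]] <- data.frame(
          region = reg, group1 = pr[1], group2 = pr[2], p = NA_real_,
          stars = "", skipped = TRUE)
        next
      }
      p <- stats::t.test(a, b, var.equal = TRUE)$p.value
      stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
      tests[[length(tests) + 1]] <- data.frame(
        region = reg, group1 = pr[1], group2 = pr[2], p = p, stars = stars,
        skipped = FALSE)
    }
  }
  list(stats = do.call(rbind, stats_rows),
       tests = if (length(tests) > 0) do.call(rbind, tests) else NULL)
}

#' Per-doublet gain by template subtraction
#'
#' The first response of each doublet is modelled by the (scaled)
#' high-ripple template; subtracting it isolates the second response,
#' whose 60 ms peak amplitude relative to the template peak is the
#' per-doublet gain. Exact for noise-free traces composed by the
#' generator's superposition rule.
#'
#' @param traces doublet transients (events x time) aligned at the first
#'   ripple's time zero
#' @param template average high-ripple transient on the same grid
#' @param rate grid sampling rate, 1/s
#' @return numeric gain per doublet
#' @export
estimate_doublet_gains <- function(traces, template, rate) {
  ipk <- which.max(template)
  apply(traces, 1, function(tr) {
    scale <- max(tr[seq_len(ipk)]) / template[ipk]
    if (scale <= 0) return(NA_real_)
    resid <- tr - scale * template
    peak_window_amp(resid, rate) / (scale * peak_window_amp(template, rate))
  })
}

#' Temporal dependence of doublet summation
#'
#' Bins per-doublet gains by the inter-event delay, reports the Spearman
#' rank correlation (a negative sign indicates the decrease of
#' supralinearity with delay), and fits an exponential decay
#' `gain = g0 * exp(-delay / tau)` by least squares on the log gains.
#'
#' @param gains per-doublet gains
#' @param delays_ms inter-event delays, ms
#' @param bin_ms delay bin width, ms
#' @return list with `bins` (data.frame delay_ms, mean_gain, n),
#'   `rank_correlation`, `decay_tau_ms` (`NA` when the fit is not
#'   defined), or `NULL` with fewer than 5 doublets or a single bin
#' @export
temporal_dependence <- function(gains, delays_ms, bin_ms = 25) {
  ok <- is.finite(gains) & is.finite(delays_ms) & gains > 0
  gains <- gains[ok]; delays_ms <- delays_ms[ok]
  if (length(gains) < 5) return(NULL)
  b <- floor(delays_ms / bin_ms)
  if (length(unique(b)) < 2) return(NULL)
  bins <- do.call(rbind, lapply(sort(unique(b)), function(k) {
    sel <- b == k
    data.frame(delay_ms = (k + 0.5) * bin_ms, mean_gain = mean(gains[sel]),
               n = sum(sel))
  }))
  rc <- if (stats::sd(gains) > 0) {
    suppressWarnings(stats::cor(delays_ms, gains, method = "spearman"))
  } else 0
  tau <- NA_real_
  if (stats::sd(log(gains)) > 0) {
    slope <- unname(stats::coef(stats::lm(log(gains) ~ delays_ms))[2])
    if (slope < 0) tau <- -1 / slope
  }
  list(bins = bins, rank_correlation = rc, decay_tau_ms = tau)
}
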