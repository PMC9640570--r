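#' Two-Gaussian decomposition of a spectral histogram
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) to
#' the values and keeps the two-component fit only when it is supported:
#' the verdict is single-mode when BIC prefers one component or when the
#' two component means collapse within `0.1 * pooled SD`. The group
#' boundary is the valley of the fitted mixture density between the two
#' component means (the midpoint of the minimal-density plateau, which
#' reduces to the midpoint of the means for well-separated or degenerate
#' components).
#'
#' @param values numeric vector (>= 20 values)
#' @return list with `single_mode` (logical), `means`, `sds`, `weights`
#'   (ordered by mean), and `boundary` (`NA` for a single mode)
#' @export
two_gaussian_split <- function(values) {
  if (length(values) < 20) stop("two_gaussian_split: need at least 20 values")
  u <- sort(unique(values))
  if (length(u) == 2) {
    # two point masses: degenerate mixture, boundary at the midpoint
    w <- as.numeric(table(factor(values, levels = u)) / length(values))
    return(list(single_mode = FALSE, means = u, sds = c(0, 0), weights = w,
                boundary = mean(u)))
  }
  # Mclust resolves mclustBIC in the caller's frame; bind it locally so
  # the call works with the namespace loaded but not attached
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(values, G = 1:2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    # zero-variance degeneracy (e.g. point masses): split by unique values
    u <- sort(unique(values))
    if (length(u) == 2) {
      w <- as.numeric(table(factor(values, levels = u)) / length(values))
      return(list(single_mode = FALSE, means = u, sds = c(0, 0), weights = w,
                  boundary = mean(u)))
    }
    return(list(single_mode = TRUE, means = mean(values), sds = stats::sd(values),
                weights = 1, boundary = NA_real_))
  }
  if (fit$G == 1) {
    return(list(single_mode = TRUE, means = unname(fit$parameters$mean),
                sds = sqrt(unname(fit$parameters$variance$sigmasq)),
                weights = 1, boundary = NA_real_))
  }
  mu <- as.numeric(fit$parameters$mean)
  sd2 <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd2) == 1) sd2 <- rep(sd2, 2)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sd2 <- sd2[o]; w <- w[o]
  pooled <- sqrt(mean(sd2^2))
  if (abs(diff(mu)) < 0.1 * pooled) {
    return(list(single_mode = TRUE, means = mu, sds = sd2, weights = w,
                boundary = NA_real_))
  }
  grid <- seq(mu[1], mu[2], length.out = 513)
  dens <- w[1] * stats::dnorm(grid, mu[1], max(sd2[1], 1e-12)) +
    w[2] * stats::dnorm(grid, mu[2], max(sd2[2], 1e-12))
  at_min <- which(dens <= min(dens) * (1 + 1e-9) + 1e-300)
  boundary <- mean(grid[at_min])
  list(single_mode = FALSE, means = mu, sds = sd2, weights = w,
       boundary = boundary)
}

#' Nearest-neighbour gap statistic on sorted log calcium areas
#'
#' Sorts the values ascending and computes, for each point, the mean
#' absolute distance to its `k_neighbors` nearest neighbours (by value).
#' The gap index is the maximum of the distance series *between the
#' modes*: the search region lies strictly between the two outermost
#' modes of a kernel density estimate of the values, so that the inflated
#' neighbour distances in the distribution tails are never mistaken for a
#' gap. A unimodal sample therefore reports no gap. Significance is
#' assessed by a two-sample t-test of the center four points around the
#' gap against all remaining interior points, in both the equal-variance
#' and the Welch variant.
#'
#' @param log_areas numeric vector, `n > 2 * k_neighbors`
#' @param k_neighbors neighbourhood size (default 6)
#' @return list: `sorted` values, `distance` series (same order),
#'   `gap_index` (into the sorted series), `center_points` (indices of the
#'   center four), `p_equal_var`, `p_welch`, and `gap_value` (the sorted
#'   value at the gap)
#' @export
gap_statistic <- function(log_areas, k_neighbors = 6) {
  n <- length(log_areas)
  if (n <= 2 * k_neighbors) {
    stop(sprintf("gap_statistic: need more than %d values (got %d)",
                 2 * k_neighbors, n))
  }
  x <- sort(log_areas)
  d <- vapply(seq_len(n), function(i) {
    mean(sort(abs(x[-i] - x[i]))[seq_len(k_neighbors)])
  }, numeric(1))
  interior <- (k_neighbors + 1):(n - k_neighbors)
  # the gap is sought between the modes of the value distribution
  dens <- stats::density(x)
  peaks <- which(diff(sign(diff(dens$y))) < 0) + 1L
  peaks <- peaks[dens$y[peaks] >= 0.1 * max(dens$y)]
  if (length(peaks) < 2) {
    return(list(sorted = x, distance = d, gap_index = NA_integer_,
                center_points = integer(0), p_equal_var = NA_real_,
                p_welch = NA_real_, gap_value = NA_real_))
  }
  lo <- dens$x[min(peaks)]
  hi <- dens$x[max(peaks)]
  between <- intersect(interior, which(x > lo & x < hi))
  if (length(between) == 0) between <- interior
  gap <- between[which.max(d[between])]
  center <- intersect(seq(gap - 1L, gap + 2L), seq_len(n))
  baseline <- setdiff(interior, center)
  p_eq <- p_w <- NA_real_
  if (length(center) >= 2 && length(baseline) >= 2 &&
      (stats::sd(d[center]) > 0 || stats::sd(d[baseline]) > 0)) {
    p_eq <- stats::t.test(d[center], d[baseline], var.equal = TRUE)$p.value
    p_w <- stats::t.test(d[center], d[baseline], var.equal = FALSE)$p.value
  }
  list(sorted = x, distance = d, gap_index = gap, center_points = center,
       p_equal_var = p_eq, p_welch = p_w, gap_value = x[gap])
}

#' Two-step K-means classification of SPW-R events
#'
#' Step one separates doublets from singlets, preferring the detector's
#' complex kinds when available and falling back to a two-Gaussian split
#' of the duration histogram. Step two runs K = 2 K-means on the
#' standardized `(log Ca area, log peak-to-peak)` plane of the singlets;
#' the cluster with the larger mean log Ca area is the high-ripple group.
#'
#' @param features data.frame with `duration_ms`, `ca_area_dffs`,
#'   `peak_to_peak_uv` and optionally `kind`
#' @param seed seed for the K-means restarts
#' @return character vector of group labels (`"doublet"`,
#'   `"high_ripple"`, `"low_ripple"`, `"unassigned"`), one per row
#' @export
kmeans_two_step <- function(features, seed = 1L) {
  n <- nrow(features)
  labels <- rep("unassigned", n)
  is_doublet <- if ("kind" %in% names(features)) {
    features$kind == "doublet"
  } else {
    sp <- two_gaussian_split(features$duration_ms)
    if (!sp$single_mode) features$duration_ms > sp$boundary else rep(FALSE, n)
  }
  labels[is_doublet] <- "doublet"
  singlet <- which(!is_doublet & features$ca_area_dffs > 0 &
                     features$peak_to_peak_uv > 0)
  if (length(singlet) < 2) return(labels)
  xy <- cbind(log(features$ca_area_dffs[singlet]),
              log(features$peak_to_peak_uv[singlet]))
  sds <- apply(xy, 2, stats::sd)
  if (all(sds == 0)) {
    labels[singlet] <- "low_ripple"    # identical singlets: tie-break low
    return(labels)
  }
  xs <- sweep(sweep(xy, 2, colMeans(xy), "-"), 2, pmax(sds, 1e-12), "/")
  km <- with_seed(seed, stats::kmeans(xs, centers = 2, nstart = 25))
  mean_area <- tapply(xy[, 1], km$cluster, mean)
  high_cl <- as.integer(names(which.max(mean_area)))
  labels[singlet] <- ifelse(km$cluster == high_cl, "high_ripple", "low_ripple")
  labels
}

#' Product distance over six SPW-R parameters
#'
#' Each parameter (duration, peak-to-peak, area, power, frequency and
#' calcium area by default) is min-max normalised to `(eps, 1]` and the
#' per-event product is returned; the score is monotone increasing in
#' every parameter. The exact parameter set is configurable.
#'
#' @param features data.frame of event features
#' @param params column names entering the product
#' @param eps lower edge of the normalisation range
#' @return numeric score per event (`NA` where a parameter is missing)
#' @export
six_param_distance <- function(features,
                               params = c("duration_ms", "peak_to_peak_uv",
                                          "area_uvs", "power_uv2s",
                                          "frequency_hz", "ca_area_dffs"),
                               eps = 1e-3) {
  missing_cols <- setdiff(params, names(features))
  if (length(missing_cols) > 0) {
    stop(sprintf("six_param_distance: missing parameter column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  score <- rep(1, nrow(features))
  for (p in params) {
    x <- features[[p]]
    rng <- range(x, na.rm = TRUE)
    xn <- if (diff(rng) > 0) eps + (1 - eps) * (x - rng[1]) / diff(rng) else rep(1, length(x))
    score <- score * xn
  }
  score[!stats::complete.cases(features[, params])] <- NA_real_
  score
}

#' Consensus grouping across classification methods
#'
#' Detector complex kinds fix the doublets; singlets take the
#' spectral-histogram verdict (log Ca area against the two-Gaussian
#' boundary); K-means disagreements are flagged and an agreement rate over
#' the singlets is reported.
#'
#' @param features data.frame with `kind` and `ca_area_dffs`
#' @param split result of [two_gaussian_split()] on `log(ca_area_dffs)`
#' @param kmeans_labels labels from [kmeans_two_step()]
#' @return list with `group` (per event), `flagged` (logical), and
#'   `agreement` (fraction of singlets where the methods agree)
#' @export
consensus_groups <- function(features, split, kmeans_labels) {
  n <- nrow(features)
  group <- rep("unassigned", n)
  group[features$kind == "doublet"] <- "doublet"
  singlet <- which(features$kind != "doublet")
  hist_lab <- rep(NA_character_, n)
  if (!split$single_mode) {
    hist_lab[singlet] <- ifelse(log(features$ca_area_dffs[singlet]) > split$boundary,
                                "high_ripple", "low_ripple")
    group[singlet] <- hist_lab[singlet]
  } else if (length(singlet) > 0) {
    group[singlet] <- "low_ripple"
  }
  flagged <- rep(FALSE, n)
  agree <- NA_real_
  if (length(singlet) > 0) {
    cmp <- kmeans_labels[singlet] == group[singlet]
    flagged[singlet] <- !cmp
    agree <- mean(cmp)
  }
  list(group = group, flagged = flagged, agreement = agree)
}
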