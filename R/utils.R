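#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage draws from its own stream so that stages stay
#' independently reproducible under one master seed. The sub-seed is a
#' deterministic hash of the master seed and a stream label, kept below
#' 2^31 - 1.
#'
#' @param seed master integer seed
#' @param label character stream label (e.g. "lfp", "imaging")
#' @return an integer seed
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Evaluate an expression under a fixed RNG seed, restoring the RNG state
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Symmetric Gaussian kernel, truncated at `trunc` standard deviations and
# normalised to unit sum. `sigma` in samples.
gaussian_kernel <- function(sigma, trunc = 4) {
  if (sigma <= 0) stop("gaussian_kernel: sigma must be positive")
  half <- max(1L, ceiling(trunc * sigma))
  x <- seq(-half, half)
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# Zero-phase convolution with edge replication, same length as x.
convolve_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + length(x))])
}

# Trapezoidal integral of y sampled at uniform spacing dt.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}

# Running mean over a centered window of `width` samples (clipped at edges).
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2L
  i0 <- pmax(1L, seq_len(n) - half)
  i1 <- pmin(n, seq_len(n) + half)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
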