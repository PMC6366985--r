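#' First-order intensity statistics (14 descriptors)
#'
#' Summaries of the voxel intensity distribution: energy, entropy, kurtosis,
#' maximum, mean, mean absolute deviation, median, minimum, range, root mean
#' square, skewness, standard deviation, uniformity, variance. Entropy and
#' uniformity are computed on an equal-width histogram with \code{nbins}
#' bins over the observed range; entropy is in bits. Standard deviation and
#' variance use the sample (n - 1) convention; skewness and kurtosis use
#' central moment ratios (kurtosis is not excess-corrected). Degenerate
#' moments of constant data return 0 by convention.
#'
#' @param values numeric vector of (masked) intensities, or a
#'   \code{normalized_region}.
#' @param nbins histogram bin count for entropy/uniformity.
#' @return Named numeric vector of length 14; names carry the
#'   \code{firstorder_} prefix.
#' @export
first_order_features <- function(values, nbins = 32L) {
  if (is.list(values) && !is.null(values$values)) values <- values$values
  v <- as.numeric(values)
  if (length(v) < 1L) stop("empty region")
  n <- length(v)
  mu <- mean(v)
  cent <- v - mu
  m2 <- mean(cent^2)
  m3 <- mean(cent^3)
  m4 <- mean(cent^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  rng <- range(v)
  p <- intensity_histogram(v, nbins)
  p <- p[p > 0]
  out <- c(
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    kurtosis = kurt,
    maximum = rng[2],
    mean = mu,
    mean_absolute_deviation = mean(abs(cent)),
    median = stats::median(v),
    minimum = rng[1],
    range = rng[2] - rng[1],
    root_mean_square = sqrt(mean(v^2)),
    skewness = skew,
    standard_deviation = if (n > 1) stats::sd(v) else 0,
    uniformity = sum(p^2),
    variance = if (n > 1) stats::var(v) else 0
  )
  names(out) <- paste0("firstorder_", names(out))
  out
}

# Equal-width histogram probabilities over [min, max]; constant input
# collapses to a single full bin.
intensity_histogram <- function(v, nbins) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(1)
  idx <- pmin(nbins, floor((v - rng[1]) / (rng[2] - rng[1]) * nbins) + 1)
  tabulate(idx, nbins) / length(v)
}
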