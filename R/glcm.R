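#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized level pairs over the 13 unique 3D lattice
#' directions at the given voxel distance, restricted to voxel pairs that are
#' both inside the mask. Counts are accumulated into a single pooled matrix,
#' symmetrized (each ordered pair counted both ways) and normalized to sum 1.
#' Offsets act on the voxel lattice; no spacing correction is applied
#' (native-space analysis).
#'
#' @param q a \code{quantized_region} from \code{\link{quantize}}.
#' @param distance offset length in voxels (default 1).
#' @return An object of class \code{glc_matrix}: \code{P} (Ng x Ng symmetric,
#'   sums to 1), \code{Ng}, \code{distance}.
#' @export
compute_glcm <- function(q, distance = 1L) {
  Ng <- q$Ng
  arr <- q$array
  counts <- matrix(0, Ng, Ng)
  dirs <- lattice_directions_13() * as.integer(distance)
  for (r in seq_len(nrow(dirs))) {
    b <- shift_array(arr, dirs[r, 1], dirs[r, 2], dirs[r, 3], fill = NA)
    ok <- !is.na(arr) & !is.na(b)
    if (!any(ok)) next
    i <- arr[ok]; j <- b[ok]
    tab <- tabulate((i - 1L) * Ng + j, nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng, byrow = TRUE)
  }
  if (sum(counts) == 0) stop("no valid voxel pairs for GLCM")
  counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), Ng = Ng,
                 distance = as.integer(distance)),
            class = "glc_matrix")
}

#' GLCM texture descriptors (22 features)
#'
#' The standard 22-descriptor co-occurrence catalog. Entropies are in bits
#' with the convention 0 log 0 = 0. Degenerate statistics (correlation with
#' zero marginal variance, information measures with zero marginal entropy)
#' return 0.
#'
#' @param glcm a \code{glc_matrix} from \code{\link{compute_glcm}}.
#' @return Named numeric vector of 22 features with the \code{glcm_} prefix.
#' @export
glcm_features <- function(glcm) {
  P <- glcm$P
  Ng <- glcm$Ng
  if (abs(sum(P) - 1) > 1e-9) stop("GLCM must be normalized to sum 1")
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)                     # symmetric: px == py
  mu <- sum(seq_len(Ng) * px)
  sigma2 <- sum((seq_len(Ng) - mu)^2 * px)
  sigma <- sqrt(sigma2)

  # Diagonal and cross-diagonal distributions p_{x-y}, p_{x+y}
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))

  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  HXY <- -sum(xlog2(P))
  HX <- -sum(xlog2(px))
  pxpy <- outer(px, px)
  HXY1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log2(pxpy), 0))
  HXY2 <- -sum(xlog2(pxpy))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 0
  sa <- sum(k_sum * p_sum)
  off <- abs(i - j)

  out <- c(
    autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_entropy = -sum(xlog2(p_diff)),
    dissimilarity = sum(off * P),
    energy = sum(P^2),
    entropy = HXY,
    homogeneity_1 = sum(P / (1 + off)),
    homogeneity_2 = sum(P / (1 + off^2)),
    informational_measure_of_correlation_1 = imc1,
    informational_measure_of_correlation_2 = imc2,
    inverse_difference_moment_normalized = sum(P / (1 + (off / Ng)^2)),
    inverse_difference_normalized = sum(P / (1 + off / Ng)),
    inverse_variance = sum(P[off > 0] / off[off > 0]^2),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(xlog2(p_sum)),
    sum_variance = sum((k_sum - sa)^2 * p_sum),
    variance = sum((i - mu)^2 * P)
  )
  names(out) <- paste0("glcm_", names(out))
  out
}
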