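#' Z-score normalization inside the tumor mask
#'
#' Intensities of the masked voxels are transformed to
#' (v - mean) / sd with the sample standard deviation (n - 1 denominator),
#' per tumor, never across a cohort. Voxels outside the mask are discarded.
#'
#' @param volume an \code{\link{image_volume}}.
#' @param mask a congruent \code{\link{tumor_mask}}.
#' @return An object of class \code{normalized_region} with elements
#'   \code{values} (normalized masked intensities), \code{array} (3D array,
#'   NA outside the mask), \code{mask} (logical 3D array), \code{spacing}.
#' @export
znormalize <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask shapes differ")
  m <- mask$data != 0
  v <- volume$data[m]
  if (length(v) < 2L) stop("need at least 2 masked voxels")
  s <- stats::sd(v)
  if (s == 0) stop("zero variance: constant region cannot be z-scored")
  z <- (v - mean(v)) / s
  arr <- array(NA_real_, dim = dim(volume$data))
  arr[m] <- z
  structure(list(values = z, array = arr, mask = m, spacing = volume$spacing),
            class = "normalized_region")
}

#' Equal-width gray-level quantization
#'
#' Bins span [min, max] of the region's values; the maximum maps to level
#' \code{Ng}. Quantization is monotone and invariant to positive affine
#' transforms of the intensities (bin edges track the observed range).
#' A constant region maps every voxel to level 1.
#'
#' @param region a \code{normalized_region} from \code{\link{znormalize}}, or
#'   any list with \code{values}, \code{array}, \code{mask} of that shape.
#' @param Ng number of gray levels (>= 2).
#' @return An object of class \code{quantized_region}: \code{levels}
#'   (integer per masked voxel in 1..Ng), \code{array} (3D integer array, NA
#'   outside mask), \code{mask}, \code{Ng}.
#' @export
quantize <- function(region, Ng = 32L) {
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("Ng must be >= 2")
  v <- region$values
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev <- rep.int(1L, length(v))
  } else {
    lev <- pmin(Ng, as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * Ng)) + 1L)
  }
  arr <- array(NA_integer_, dim = dim(region$array))
  arr[region$mask] <- lev
  structure(list(levels = lev, array = arr, mask = region$mask, Ng = Ng),
            class = "quantized_region")
}
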