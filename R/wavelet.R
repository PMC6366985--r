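#' Wavelet filter bank
#'
#' Orthonormal decomposition filter pairs available for the stationary 3D
#' transform. Coefficients are frozen in the package; each low-pass filter
#' sums to sqrt(2) and has unit l2 norm, and the high-pass filter is its
#' quadrature mirror.
#'
#' @return Named list of lists with elements \code{lo} and \code{hi}.
#' @export
wavelet_filters <- function() {
  haar_lo <- c(1, 1) / sqrt(2)
  db2_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  coif1_lo <- c(-0.015655728135791993, -0.07273261951252645,
                0.3848648468648578, 0.8525720202116004,
                0.3378976624574818, -0.07273261951252645)
  qmf <- function(lo) {
    n <- length(lo)
    rev(lo) * (-1)^(seq_len(n) - 1)
  }
  lapply(list(haar = haar_lo, db2 = db2_lo, coif1 = coif1_lo),
         function(lo) list(lo = lo, hi = qmf(lo)))
}

# Periodic (circular) correlation of a 3D array with a 1D filter along one
# axis: out[v] = sum_t h[t] * a[v + (t-1)*e_axis  (mod extent)].
filter_axis_periodic <- function(a, h, axis) {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, dim = d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (t in seq_along(h)) {
    sh <- idx
    sh[[axis]] <- ((idx[[axis]] + t - 2L) %% n) + 1L
    out <- out + h[t] * a[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
  }
  out
}

#' Single-level stationary 3D wavelet transform
#'
#' Undecimated (shift-invariant) separable decomposition with periodic
#' boundary handling, producing the 8 sub-bands LLL, LLH, LHL, LHH, HLL,
#' HLH, HHL, HHH. The letter order follows the (x, y, z) axis order: the
#' first letter is the filter applied along x, so HLL is high-pass along x
#' and low-pass along y and z. For an orthonormal family the sub-band
#' energies sum to 8 times the input energy (each undecimated stage doubles
#' energy).
#'
#' @param arr 3D numeric array (every axis at least as long as the filter).
#' @param family wavelet family name, see \code{\link{wavelet_filters}}.
#' @return Named list of 8 arrays, each the size of \code{arr}.
#' @export
swt3 <- function(arr, family = "coif1") {
  filt <- wavelet_filters()[[family]]
  if (is.null(filt)) stop("unknown wavelet family: ", family)
  if (any(dim(arr) < length(filt$lo)))
    stop("region too small for the '", family, "' filter (length ",
         length(filt$lo), ")")
  bands <- stats::setNames(list(arr), "")
  for (axis in 1:3) {
    nb <- list()
    for (k in seq_along(bands)) {
      nm <- names(bands)[k]
      nb[[paste0(nm, "L")]] <- filter_axis_periodic(bands[[k]], filt$lo, axis)
      nb[[paste0(nm, "H")]] <- filter_axis_periodic(bands[[k]], filt$hi, axis)
    }
    bands <- nb
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Wavelet-domain texture features (376 descriptors)
#'
#' The volume is z-scored with the masked-voxel mean and SD, cropped to the
#' mask bounding box, and decomposed with \code{\link{swt3}}. On each of the
#' 8 sub-bands the 14 first-order, 22 GLCM, and 11 GLRLM descriptors are
#' recomputed over the masked voxels after the usual equal-width
#' quantization, giving 8 x 47 = 376 features with sub-band suffixes
#' (e.g. \code{firstorder_median_HHL}).
#'
#' @param volume an \code{\link{image_volume}}.
#' @param mask a congruent \code{\link{tumor_mask}}.
#' @param family wavelet family.
#' @param Ng gray levels for sub-band quantization.
#' @return Named numeric vector of length 376.
#' @export
wavelet_features <- function(volume, mask, family = "coif1", Ng = 32L) {
  m <- mask$data != 0
  v <- volume$data[m]
  if (length(v) < 2L || stats::sd(v) == 0)
    stop("need a non-constant masked region for wavelet features")
  norm_vol <- (volume$data - mean(v)) / stats::sd(v)
  bb <- mask_bbox(m)
  sub <- crop_bbox(norm_vol, bb)
  msub <- crop_bbox(m, bb)
  flen <- length(wavelet_filters()[[family]]$lo)
  if (any(dim(sub) < flen))
    stop("mask bounding box ", paste(dim(sub), collapse = "x"),
         " smaller than the '", family, "' filter length ", flen)
  bands <- swt3(sub, family)
  out <- numeric(0)
  for (nm in names(bands)) {
    band <- bands[[nm]]
    vals <- band[msub]
    region <- list(values = vals,
                   array = {
                     a <- array(NA_real_, dim = dim(band)); a[msub] <- vals; a
                   },
                   mask = msub)
    fo <- first_order_features(vals, nbins = Ng)
    q <- quantize(region, Ng)
    gf <- glcm_features(compute_glcm(q))
    rf <- glrlm_features(compute_glrlm(q))
    blk <- c(fo, gf, rf)
    names(blk) <- paste0(names(blk), "_", nm)
    out <- c(out, blk)
  }
  out
}
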