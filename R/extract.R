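subband_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

first_order_names <- function() {
  paste0("firstorder_", c("energy", "entropy", "kurtosis", "maximum", "mean",
                          "mean_absolute_deviation", "median", "minimum",
                          "range", "root_mean_square", "skewness",
                          "standard_deviation", "uniformity", "variance"))
}

shape_names <- function() {
  paste0("shape_", c("volume", "surface_area", "surface_to_volume_ratio",
                     "sphericity", "compactness_1", "compactness_2",
                     "spherical_disproportion", "maximum_3d_diameter"))
}

glcm_names <- function() {
  paste0("glcm_", c("autocorrelation", "cluster_prominence", "cluster_shade",
                    "cluster_tendency", "contrast", "correlation",
                    "difference_entropy", "dissimilarity", "energy",
                    "entropy", "homogeneity_1", "homogeneity_2",
                    "informational_measure_of_correlation_1",
                    "informational_measure_of_correlation_2",
                    "inverse_difference_moment_normalized",
                    "inverse_difference_normalized", "inverse_variance",
                    "maximum_probability", "sum_average", "sum_entropy",
                    "sum_variance", "variance"))
}

glrlm_names <- function() {
  paste0("glrlm_", c("short_run_emphasis", "long_run_emphasis",
                     "gray_level_nonuniformity", "run_length_nonuniformity",
                     "run_percentage", "low_gray_level_run_emphasis",
                     "high_gray_level_run_emphasis",
                     "short_run_low_gray_level_emphasis",
                     "short_run_high_gray_level_emphasis",
                     "long_run_low_gray_level_emphasis",
                     "long_run_high_gray_level_emphasis"))
}

#' The fixed 431-descriptor feature catalog
#'
#' The extractor's output vocabulary, in extraction order: 14 first-order +
#' 8 shape + 22 GLCM + 11 GLRLM on the original image, then the same 47
#' intensity/texture descriptors on each of the 8 stationary-wavelet
#' sub-bands (suffixes LLL..HHH), 14 + 8 + 22 + 11 + 8 x 47 = 431 names.
#' The vocabulary is frozen: extraction order and names never change between
#' runs.
#'
#' @return Character vector of 431 feature names.
#' @export
feature_catalog <- function() {
  texture47 <- c(first_order_names(), glcm_names(), glrlm_names())
  c(first_order_names(), shape_names(), glcm_names(), glrlm_names(),
    unlist(lapply(subband_names, function(sb) paste0(texture47, "_", sb))))
}

#' Extract the complete 431-feature radiomic vector
#'
#' Pipeline per tumor: z-score the masked intensities (per tumor), compute
#' 14 first-order statistics and 8 shape descriptors; quantize to Ng equal
#' width gray levels and compute 22 GLCM and 11 GLRLM descriptors; then
#' decompose the z-scored bounding box with a single-level stationary 3D
#' wavelet transform and recompute the 47 intensity/texture descriptors on
#' each of the 8 sub-bands. The result is deterministic and invariant to
#' positive affine rescaling of the raw intensities (guaranteed by the
#' z-scoring and min/max quantization).
#'
#' @param volume an \code{\link{image_volume}}.
#' @param mask a congruent \code{\link{tumor_mask}}.
#' @param config an \code{\link{analysis_config}} (quantization levels and
#'   wavelet family are taken from it).
#' @return Named numeric vector of exactly 431 finite values, ordered as
#'   \code{\link{feature_catalog}}.
#' @export
extract_all <- function(volume, mask, config = analysis_config()) {
  Ng <- config$quantization_levels
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("feature group '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  region <- step("normalization", znormalize(volume, mask))
  fo <- step("first-order", first_order_features(region, nbins = Ng))
  sh <- step("shape", shape_features(mask))
  q <- step("quantization", quantize(region, Ng))
  gf <- step("glcm", glcm_features(compute_glcm(q)))
  rf <- step("glrlm", glrlm_features(compute_glrlm(q)))
  wf <- step("wavelet", wavelet_features(volume, mask,
                                         family = config$wavelet_family,
                                         Ng = Ng))
  out <- c(fo, sh, gf, rf, wf)
  stopifnot(identical(names(out), feature_catalog()))
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite features produced: ", paste(bad, collapse = ", "))
  }
  out
}

#' Extract features for a list of volume/mask pairs
#'
#' @param volumes list of \code{\link{image_volume}} objects.
#' @param masks list of congruent \code{\link{tumor_mask}} objects.
#' @param sample_ids identifiers; default names of \code{volumes}.
#' @param config an \code{\link{analysis_config}}.
#' @return A \code{\link{feature_table}} (samples x 431).
#' @export
extract_cohort <- function(volumes, masks, sample_ids = names(volumes),
                           config = analysis_config()) {
  if (length(volumes) != length(masks)) stop("volumes/masks length mismatch")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_along(volumes))
  vals <- t(vapply(seq_along(volumes), function(k)
    extract_all(volumes[[k]], masks[[k]], config),
    numeric(length(feature_catalog()))))
  feature_table(vals, sample_ids = sample_ids,
                feature_names = feature_catalog())
}
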