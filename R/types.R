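#' Construct an image volume
#'
#' A 3D scalar intensity grid together with its physical voxel spacing in mm.
#' Intensities are arbitrary units (T2-weighted MRI in the intended
#' application); no rescaling is applied at construction.
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing numeric length-3 vector of positive voxel edge lengths in mm,
#'   in (x, y, z) axis order.
#' @return An object of class \code{image_volume} with elements \code{data}
#'   and \code{spacing}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image volume must be a 3D array")
  if (any(dim(data) < 1L)) stop("image volume must have >= 1 voxel per axis")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("image volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths in mm")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Construct a tumor mask
#'
#' A binary foreground grid congruent with an \code{\link{image_volume}}.
#' Any nonzero voxel is treated as foreground.
#'
#' @param data 3D array; coerced to 0/1 (nonzero -> 1).
#' @param spacing voxel spacing in mm, as for \code{\link{image_volume}}.
#' @return An object of class \code{tumor_mask}.
#' @export
tumor_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("tumor mask must be a 3D array")
  m <- array(as.numeric(data != 0), dim = dim(data))
  if (sum(m) < 1) stop("empty mask: no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths in mm")
  structure(list(data = m, spacing = spacing), class = "tumor_mask")
}

#' Construct a feature table
#'
#' Samples-by-features matrix of named radiomic descriptors. The full
#' extractor produces exactly 431 columns (see \code{\link{feature_catalog}}).
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids character vector of unique row identifiers.
#' @param feature_names character vector of unique column names.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    stop("sample ids must be present and unique")
  if (is.null(feature_names) || anyDuplicated(feature_names))
    stop("feature names must be present and unique")
  if (length(sample_ids) != nrow(values) || length(feature_names) != ncol(values))
    stop("dimension mismatch between values and names")
  if (!all(is.finite(values))) stop("feature values must be finite")
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_names))
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 feature_names = as.character(feature_names)),
            class = "feature_table")
}

#' Construct a clinical cohort table
#'
#' Per-sample phenotype label (IDH status, \code{"MUT"} or \code{"WT"}),
#' right-censored overall survival, and optional covariates.
#'
#' @param sample_ids unique sample identifiers.
#' @param label factor or character in \{WT, MUT\}; may be NA-free or absent.
#' @param os_days nonnegative overall survival time in days (optional).
#' @param event 0 = censored, 1 = death (optional, required with os_days).
#' @param age,sex,grade optional covariates.
#' @return An object of class \code{clinical_cohort} (a data.frame).
#' @export
clinical_cohort <- function(sample_ids, label = NULL, os_days = NULL,
                            event = NULL, age = NULL, sex = NULL, grade = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  n <- length(sample_ids)
  df <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(label)) {
    label <- as.character(label)
    if (!all(label %in% c("WT", "MUT"))) stop("label must be 'WT' or 'MUT'")
    df$label <- label
  }
  if (!is.null(os_days)) {
    if (is.null(event)) stop("event flag required with os_days")
    os_days <- as.numeric(os_days)
    event <- as.numeric(event)
    if (any(os_days < 0, na.rm = TRUE)) stop("os_days must be >= 0")
    if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
    df$os_days <- os_days
    df$event <- event
  }
  if (!is.null(age)) df$age <- as.numeric(age)
  if (!is.null(sex)) df$sex <- as.character(sex)
  if (!is.null(grade)) df$grade <- as.character(grade)
  if (nrow(df) != n) stop("covariate length mismatch")
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' Construct an expression matrix
#'
#' Genes-by-samples matrix of (assumed log-scale) expression values.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids unique identifiers.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (is.null(sample_ids) || anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (!all(is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. All
#' randomness downstream is driven by \code{seed}.
#'
#' @param seed integer RNG seed owned by the run.
#' @param fdr_threshold BH false-discovery-rate cutoff for SAM selection.
#' @param fold_change_threshold linear-scale fold-change cutoff applied to
#'   gene (not radiomic-feature) selection; 1.20 means a >20\% change.
#' @param correlation_threshold absolute Pearson r cutoff for the
#'   radiogenomic screen.
#' @param min_survival_days patients surviving fewer days are excluded from
#'   prognostic signature construction.
#' @param n_permutations label permutations for the SAM null.
#' @param quantization_levels gray levels Ng for texture matrices.
#' @param wavelet_family one of \code{"coif1"}, \code{"db2"}, \code{"haar"}.
#' @param cox_pvalue_threshold univariate Cox Wald-p cutoff for the
#'   prognostic signature.
#' @param ridge ridge penalty for logistic fits.
#' @return An object of class \code{analysis_config} (a list).
#' @export
analysis_config <- function(seed = 1L,
                            fdr_threshold = 0.05,
                            fold_change_threshold = 1.20,
                            correlation_threshold = 0.4,
                            min_survival_days = 30,
                            n_permutations = 1000L,
                            quantization_levels = 32L,
                            wavelet_family = "coif1",
                            cox_pvalue_threshold = 0.05,
                            ridge = 1e-4) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            fold_change_threshold >= 1,
            correlation_threshold >= 0, correlation_threshold < 1,
            min_survival_days >= 0, n_permutations >= 1,
            quantization_levels >= 2,
            cox_pvalue_threshold > 0, cox_pvalue_threshold <= 1,
            ridge >= 0)
  if (!wavelet_family %in% names(wavelet_filters()))
    stop("unknown wavelet family: ", wavelet_family)
  structure(list(seed = as.integer(seed),
                 fdr_threshold = fdr_threshold,
                 fold_change_threshold = fold_change_threshold,
                 correlation_threshold = correlation_threshold,
                 min_survival_days = min_survival_days,
                 n_permutations = as.integer(n_permutations),
                 quantization_levels = as.integer(quantization_levels),
                 wavelet_family = wavelet_family,
                 cox_pvalue_threshold = cox_pvalue_threshold,
                 ridge = ridge),
            class = "analysis_config")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  invisible(x)
}
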