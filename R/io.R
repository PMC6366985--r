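#' Read a NIfTI-1 image volume
#'
#' Reads a 3D NIfTI-1 file and returns its intensity grid and voxel spacing.
#' Intensities are returned unchanged; no resampling or reorientation is
#' performed (the analysis runs in native image space).
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected a 3D image, got ",
                                   length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (!all(is.finite(arr))) stop("image contains non-finite voxels")
  image_volume(array(as.numeric(arr), dim = dim(arr)), spacing = sp)
}

#' Write an image volume or mask to NIfTI-1
#'
#' @param volume an \code{\link{image_volume}} or \code{\link{tumor_mask}}.
#' @param path destination \code{.nii} or \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tumor mask congruent with a volume
#'
#' Values are coerced to \{0, 1\}: any nonzero voxel is foreground. The mask
#' grid must match the volume's grid exactly; no resampling is performed.
#'
#' @param path path to the mask NIfTI file.
#' @param volume the \code{\link{image_volume}} the mask annotates.
#' @return A \code{\link{tumor_mask}} carrying the volume's spacing.
#' @export
read_mask <- function(path, volume) {
  m <- read_volume(path)
  if (!identical(dim(m$data), dim(volume$data)))
    stop("mask shape ", paste(dim(m$data), collapse = "x"),
         " does not match volume shape ", paste(dim(volume$data), collapse = "x"))
  if (all(m$data == 0)) stop("empty mask: no foreground voxels")
  tumor_mask(m$data, spacing = volume$spacing)
}

#' Read a clinical table (CSV)
#'
#' Expects a header row with at least \code{sample_id}; recognised optional
#' columns are \code{label} (IDH status, MUT/WT), \code{os_days},
#' \code{event}, \code{age}, \code{sex}, \code{grade}.
#'
#' @param path CSV path.
#' @param require_survival error if os_days/event are absent.
#' @param require_label error if the label column is absent.
#' @return A \code{\link{clinical_cohort}}.
#' @export
read_clinical_table <- function(path, require_survival = FALSE,
                                require_label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing required column 'sample_id'")
  if (require_survival && !all(c("os_days", "event") %in% names(df)))
    stop("survival analysis requested but 'os_days'/'event' columns are missing")
  if (require_label && !"label" %in% names(df))
    stop("phenotype labels requested but 'label' column is missing")
  clinical_cohort(sample_ids = df$sample_id,
                  label = df[["label"]],
                  os_days = df[["os_days"]],
                  event = df[["event"]],
                  age = df[["age"]],
                  sex = df[["sex"]],
                  grade = df[["grade"]])
}

#' Write a clinical cohort to CSV
#' @param cohort a \code{\link{clinical_cohort}}.
#' @param path destination path.
#' @export
write_clinical_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a gene-expression matrix (TSV, genes x samples)
#'
#' First column holds gene ids; remaining columns are samples.
#'
#' @param path TSV path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene id column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  vals <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(vals, gene_ids = genes, sample_ids = colnames(df)[-1])
}

#' Write an expression matrix to TSV
#' @param expr an \code{\link{expression_matrix}}.
#' @param path destination path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature table (CSV)
#'
#' Values survive a write/read round trip to at least 12 significant digits.
#'
#' @param table a \code{\link{feature_table}}.
#' @param path CSV path; first column \code{sample_id}.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids,
                   format(table$values, digits = 15, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$feature_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing required column 'sample_id'")
  ids <- as.character(df$sample_id)
  vals <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  feature_table(vals, sample_ids = ids,
                feature_names = setdiff(names(df), "sample_id"))
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file whose keys match \code{\link{analysis_config}}
#'   arguments.
#' @return An \code{\link{analysis_config}}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Read a GMT gene-set annotation file
#'
#' One term per line: term id, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors (term -> gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate term ids in GMT")
  sets
}
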