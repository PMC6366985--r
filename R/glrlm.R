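#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal quantized gray level along each of the 13
#' unique 3D lattice directions, aggregated into one matrix R[level, length].
#' A run is a maximal set of consecutive in-mask voxels with identical level
#' along a direction. Every masked voxel belongs to exactly one run per
#' direction, so \eqn{\sum_{i,j} j R(i,j) = n_{voxels} \times 13}.
#'
#' @param q a \code{quantized_region} from \code{\link{quantize}}.
#' @return An object of class \code{glrl_matrix}: \code{R} (Ng x Lmax run
#'   counts), \code{Ng}, \code{n_voxels}, \code{n_directions}.
#' @export
compute_glrlm <- function(q) {
  arr <- q$array
  Ng <- q$Ng
  n_vox <- sum(!is.na(arr))
  if (n_vox < 1L) stop("empty region")
  dirs <- lattice_directions_13()
  lmax <- max(dim(arr))
  counts <- matrix(0, Ng, lmax)
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    nxt <- shift_array(arr, o[1], o[2], o[3], fill = NA)
    prv <- shift_array(arr, -o[1], -o[2], -o[3], fill = NA)
    same_next <- !is.na(arr) & !is.na(nxt) & arr == nxt
    is_start <- !is.na(arr) & (is.na(prv) | prv != arr)
    # run length via repeated propagation: f(v) = 1 + f(v + o) while the
    # level chain continues; converges once the longest run is covered
    f <- array(1L, dim = dim(arr))
    repeat {
      fn <- shift_array(f, o[1], o[2], o[3], fill = 0L)
      fnew <- ifelse(same_next, 1L + fn, 1L)
      if (identical(fnew, f)) break
      f <- fnew
    }
    lev <- arr[is_start]
    len <- f[is_start]
    tab <- tabulate((lev - 1L) * lmax + len, nbins = Ng * lmax)
    counts <- counts + matrix(tab, Ng, lmax, byrow = TRUE)
  }
  structure(list(R = counts, Ng = Ng, n_voxels = n_vox,
                 n_directions = nrow(dirs)),
            class = "glrl_matrix")
}

#' GLRLM texture descriptors (11 features)
#'
#' Short/long run emphasis, gray-level and run-length nonuniformity, run
#' percentage, and the low/high gray-level variants. Run percentage is
#' defined as n_runs / (n_voxels x n_directions).
#'
#' @param glrlm a \code{glrl_matrix} from \code{\link{compute_glrlm}}.
#' @return Named numeric vector of 11 features with the \code{glrlm_} prefix.
#' @export
glrlm_features <- function(glrlm) {
  R <- glrlm$R
  nr <- sum(R)
  if (nr == 0) stop("empty run-length matrix")
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  out <- c(
    short_run_emphasis = sum(R / j^2) / nr,
    long_run_emphasis = sum(R * j^2) / nr,
    gray_level_nonuniformity = sum(rowSums(R)^2) / nr,
    run_length_nonuniformity = sum(colSums(R)^2) / nr,
    run_percentage = nr / (glrlm$n_voxels * glrlm$n_directions),
    low_gray_level_run_emphasis = sum(R / i^2) / nr,
    high_gray_level_run_emphasis = sum(R * i^2) / nr,
    short_run_low_gray_level_emphasis = sum(R / (i^2 * j^2)) / nr,
    short_run_high_gray_level_emphasis = sum(R * i^2 / j^2) / nr,
    long_run_low_gray_level_emphasis = sum(R * j^2 / i^2) / nr,
    long_run_high_gray_level_emphasis = sum(R * i^2 * j^2) / nr
  )
  names(out) <- paste0("glrlm_", names(out))
  out
}
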