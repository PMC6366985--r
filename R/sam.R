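#' SAM moderated difference statistic
#'
#' d = (mean2 - mean1) / (s + s0) where s is the pooled two-sample standard
#' error and s0 a small positive fudge factor stabilizing items with tiny
#' variance.
#'
#' @param x1,x2 numeric vectors for the two groups (each >= 2 values).
#' @param s0 fudge factor added to the standard error.
#' @return The d statistic (scalar).
#' @export
sam_statistic <- function(x1, x2, s0 = 0) {
  if (length(x1) < 2L || length(x2) < 2L) stop("each group needs >= 2 samples")
  d_stat_matrix(rbind(c(x1, x2)),
                c(rep(1L, length(x1)), rep(2L, length(x2))), s0)[1L]
}

# Vectorized d statistics for items x samples matrix; g in {1, 2}.
d_stat_matrix <- function(X, g, s0) {
  i1 <- which(g == 1L); i2 <- which(g == 2L)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  ss1 <- rowSums((X[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  (m2 - m1) / (s + s0)
}

#' SAM differential selection between two phenotype groups
#'
#' Computes the moderated d statistic per item (feature or gene), builds a
#' pooled permutation null by recomputing d under B seeded label
#' permutations, converts to two-sided permutation p-values, adjusts with
#' Benjamini-Hochberg, and flags items passing the FDR threshold (and, when
#' active, the linear-scale fold-change criterion). The fudge factor s0
#' defaults to the median of the per-item standard errors.
#'
#' @param values numeric matrix, items x samples, or a
#'   \code{\link{feature_table}} (transposed internally) or
#'   \code{\link{expression_matrix}}.
#' @param labels two-class factor/character per sample (e.g. WT/MUT).
#' @param fdr_threshold BH q-value cutoff (default 0.05).
#' @param n_permutations number of label permutations B (warns below 100).
#' @param fold_change linear-scale fold-change cutoff, e.g. 1.20 for the
#'   20\% criterion applied to gene selection; \code{NULL} disables it
#'   (the default for radiomic features).
#' @param log_base when values are on a log scale, the base used to convert
#'   group mean differences to linear fold changes; \code{NULL} (default)
#'   treats values as linear and uses the mean ratio.
#' @param s0 fudge factor; \code{NULL} (default) uses the median per-item
#'   standard error.
#' @param seed integer seed for the permutation null.
#' @return A data.frame of class \code{sam_result}: item, d, s, p, q,
#'   fold_change (NA when inactive), selected.
#' @export
sam_select <- function(values, labels, fdr_threshold = 0.05,
                       n_permutations = 1000L, fold_change = NULL,
                       log_base = NULL, s0 = NULL, seed = 1L) {
  X <- as_item_matrix(values)
  labels <- as.character(labels)
  if (ncol(X) != length(labels)) stop("labels length does not match samples")
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("exactly two label classes required")
  g <- ifelse(labels == lv[1], 1L, 2L)
  if (sum(g == 1L) < 2L || sum(g == 2L) < 2L)
    stop("each class needs >= 2 samples")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations gives coarse p-values")

  i1 <- which(g == 1L); i2 <- which(g == 2L)
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  ss1 <- rowSums((X[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / length(i1) + 1 / length(i2)) *
              (ss1 + ss2) / (length(i1) + length(i2) - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  d <- (m2 - m1) / (s + s0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_abs <- matrix(0, nrow(X), n_permutations)
  for (b in seq_len(n_permutations)) {
    gp <- sample(g)
    null_abs[, b] <- abs(d_stat_matrix(X, gp, s0))
  }
  # pooled null across items and permutations; +1 correction keeps p > 0
  null_sorted <- sort(null_abs)
  exceed <- length(null_sorted) - findInterval(abs(d) - 1e-12, null_sorted)
  p <- (exceed + 1) / (length(null_sorted) + 1)
  q <- stats::p.adjust(p, method = "BH")

  fc <- rep(NA_real_, nrow(X))
  sel <- q < fdr_threshold
  if (!is.null(fold_change)) {
    fc <- if (is.null(log_base)) m2 / m1 else log_base^(m2 - m1)
    sel <- sel & is.finite(fc) &
      (fc > fold_change | fc < 1 / fold_change)
  }
  res <- data.frame(item = rownames(X), d = d, s = s, s0 = s0, p = p, q = q,
                    fold_change = fc, selected = sel,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("sam_result", "data.frame")
  res
}

as_item_matrix <- function(values) {
  if (inherits(values, "feature_table")) {
    X <- t(values$values)
  } else if (inherits(values, "expression_matrix")) {
    X <- values$values
  } else {
    X <- as.matrix(values)
  }
  if (is.null(rownames(X))) rownames(X) <- sprintf("item_%d", seq_len(nrow(X)))
  X
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
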