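#' Unsupervised hierarchical clustering of radiomic profiles
#'
#' Features are z-scored per column, samples are compared with Euclidean
#' distance, and an agglomerative average-linkage tree is cut into k
#' clusters. Constant columns are dropped before scaling. Cluster labels are
#' deterministic given the sample order.
#'
#' @param features a \code{\link{feature_table}} or numeric matrix
#'   (samples x features).
#' @param k number of clusters (>= 2).
#' @return An object of class \code{cluster_assignment}: \code{cluster}
#'   (named integer vector in 1..k), \code{tree} (the hclust object),
#'   \code{linkage}, \code{metric}.
#' @export
hierarchical_cluster <- function(features, k = 2L) {
  X <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  if (k < 2L) stop("k must be >= 2")
  if (nrow(X) < k) stop("k exceeds the number of samples")
  keep <- apply(X, 2L, stats::sd) > 0
  Z <- scale(X[, keep, drop = FALSE])
  tree <- stats::hclust(stats::dist(Z, method = "euclidean"),
                        method = "average")
  cl <- stats::cutree(tree, k = k)
  structure(list(cluster = cl, tree = tree, linkage = "average",
                 metric = "euclidean"),
            class = "cluster_assignment")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the probabilities of all
#' hypergeometric outcomes (with the observed margins) no more likely than
#' the observed table.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  # tolerance guards against ties broken by floating error
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
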