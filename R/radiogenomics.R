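#' Pearson correlation screen between radiomic features and genes
#'
#' For every (feature, gene) pair sharing at least 3 samples, computes the
#' Pearson r and a two-sided p-value from the t distribution with n - 2
#' degrees of freedom. A pair is flagged significant when |r| exceeds the
#' threshold AND p < 0.05. Zero-variance genes or features are excluded
#' (not assigned r = 0) and reported in the \code{excluded} attribute.
#'
#' @param features \code{\link{feature_table}} (samples x features) or
#'   matrix with sample rownames; may also be a named per-sample vector
#'   (e.g. the risk score).
#' @param expression \code{\link{expression_matrix}} (genes x samples).
#' @param r_threshold absolute correlation cutoff (default 0.4).
#' @param p_threshold significance cutoff (default 0.05).
#' @return A data.frame of class \code{correlation_table}: feature, gene,
#'   r, p, significant; attribute \code{excluded} lists dropped items.
#' @export
pearson_feature_gene <- function(features, expression, r_threshold = 0.4,
                                 p_threshold = 0.05) {
  if (is.numeric(features) && is.null(dim(features))) {
    features <- matrix(features, ncol = 1,
                       dimnames = list(names(features), "risk_score"))
  }
  Xf <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  E <- expression$values
  shared <- intersect(rownames(Xf), colnames(E))
  n <- length(shared)
  if (n < 3L) stop("need >= 3 shared samples, got ", n)
  Xf <- Xf[shared, , drop = FALSE]
  E <- E[, shared, drop = FALSE]

  sd_f <- apply(Xf, 2L, stats::sd)
  sd_g <- apply(E, 1L, stats::sd)
  excluded <- c(
    if (any(sd_f == 0)) paste0("feature:", colnames(Xf)[sd_f == 0]),
    if (any(sd_g == 0)) paste0("gene:", rownames(E)[sd_g == 0]))
  Xf <- Xf[, sd_f > 0, drop = FALSE]
  E <- E[sd_g > 0, , drop = FALSE]
  if (!ncol(Xf) || !nrow(E)) stop("no variable features/genes left")

  r <- stats::cor(Xf, t(E))                 # features x genes
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  res <- data.frame(feature = rep(rownames(r), times = ncol(r)),
                    gene = rep(colnames(r), each = nrow(r)),
                    r = as.vector(r), p = as.vector(p),
                    stringsAsFactors = FALSE)
  res$significant <- abs(res$r) > r_threshold & res$p < p_threshold
  attr(res, "excluded") <- excluded
  attr(res, "n_samples") <- n
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Top-k genes associated with a feature
#'
#' Significant pairs are filtered first, then ranked by signed r: descending
#' for the positive list, ascending for the negative list, truncated to k.
#' Fewer than k genes are returned when fewer qualify.
#'
#' @param table a \code{correlation_table}.
#' @param feature feature name to rank genes for.
#' @param k list length cap (default 200).
#' @param direction \code{"positive"} or \code{"negative"}.
#' @return Data.frame of gene, r, p ordered by association strength.
#' @export
top_k_genes <- function(table, feature, k = 200L,
                        direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sub <- table[table$feature == feature & table$significant, , drop = FALSE]
  sub <- if (direction == "positive") {
    sub <- sub[sub$r > 0, , drop = FALSE]
    sub[order(-sub$r), , drop = FALSE]
  } else {
    sub <- sub[sub$r < 0, , drop = FALSE]
    sub[order(sub$r), , drop = FALSE]
  }
  utils::head(sub[, c("gene", "r", "p")], k)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of over-representation of a gene list
#' in each annotation term, with BH adjustment across terms. A local
#' replacement for web-based GO enrichment: the annotation is user-supplied
#' (e.g. from \code{\link{read_gmt}}).
#'
#' @param gene_list character vector of selected genes.
#' @param annotation named list of term -> gene id vectors.
#' @param universe character vector of all assayed genes.
#' @return Data.frame: term, n_term, n_overlap, p, q, ordered by p.
#' @export
hypergeometric_enrichment <- function(gene_list, annotation, universe) {
  gene_list <- unique(as.character(gene_list))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  gene_list <- intersect(gene_list, universe)
  N <- length(universe)
  k <- length(gene_list)
  rows <- lapply(names(annotation), function(term) {
    term_genes <- intersect(annotation[[term]], universe)
    m <- length(term_genes)
    x <- length(intersect(gene_list, term_genes))
    # P(X >= x) for X ~ Hypergeom(N, m, k)
    p <- if (m == 0) 1 else
      stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, n_term = m, n_overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
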