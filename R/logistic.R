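#' Ridge-penalized logistic regression via IRLS
#'
#' Maximum penalized likelihood fit of P(y = 1 | x) = 1 / (1 + exp(-(a +
#' x'b))) by iteratively reweighted least squares. A small ridge penalty
#' (lambda/2)||b||^2 on the slopes (never the intercept) keeps the fit
#' identifiable under the quasi-separation that strong radiomic signatures
#' produce. Wald z statistics and p-values come from the inverse penalized
#' observed information.
#'
#' @param X numeric matrix (samples x features); columns are standardized
#'   internally unless \code{standardize = FALSE}.
#' @param y 0/1 response (or two-level factor; second level = 1).
#' @param lambda ridge penalty (default 1e-4).
#' @param standardize center/scale columns before fitting (coefficients are
#'   reported on the standardized scale together with the scaling used).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An object of class \code{logistic_model}: \code{coefficients}
#'   (named, excluding intercept), \code{intercept}, \code{p_values},
#'   \code{se}, \code{converged}, \code{iterations}, \code{lambda},
#'   \code{center}, \code{scale}, \code{feature_names}.
#' @export
fit_logistic <- function(X, y, lambda = 1e-4, standardize = TRUE,
                         max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    f <- as.factor(y)
    if (nlevels(f) != 2L) stop("y must have exactly two classes")
    y <- as.numeric(f == levels(f)[2])
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2L) stop("single-class response")
  if (!all(is.finite(X))) stop("non-finite predictor values")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(Xd %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xd, Xd * w) + pen
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))

  structure(list(coefficients = stats::setNames(beta[-1], colnames(X)),
                 intercept = unname(beta[1]),
                 se = stats::setNames(se[-1], colnames(X)),
                 p_values = stats::setNames(pv[-1], colnames(X)),
                 converged = converged, iterations = iter,
                 lambda = lambda, center = ctr, scale = scl,
                 feature_names = colnames(X)),
            class = "logistic_model")
}

#' Predict class-1 probabilities from a fitted logistic model
#'
#' Applies the training standardization (frozen center/scale) to new data
#' before the linear predictor; validation cohorts are never re-standardized
#' with their own statistics.
#'
#' @param model a \code{logistic_model}.
#' @param X numeric matrix with the model's feature columns.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names))
      stop("unnamed matrix with wrong column count")
    colnames(X) <- model$feature_names
  }
  X <- X[, model$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  eta <- model$intercept + drop(Xs %*% model$coefficients)
  1 / (1 + exp(-eta))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Rank-based AUC: the probability that a random positive scores higher than
#' a random negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or two-level) true classes; both must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- as.factor(labels)
    if (nlevels(f) != 2L) stop("labels must have exactly two classes")
    labels <- as.numeric(f == levels(f)[2])
  }
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Backward elimination of logistic-model features
#'
#' Starting from the (SAM-selected) feature set, the model is refit
#' repeatedly and the feature with the largest Wald p-value is dropped each
#' round, down to a single feature. Training AUC is recorded at every model
#' size; the chosen model is the smallest one attaining the maximum recorded
#' AUC (ties resolved toward fewer features). The full trace is returned so
#' other stopping rules can be replayed.
#'
#' @param X numeric matrix (samples x features) or
#'   \code{\link{feature_table}}.
#' @param y 0/1 response or two-level labels.
#' @param lambda ridge penalty passed to \code{\link{fit_logistic}}.
#' @return An object of class \code{elimination_trace}: \code{trace}
#'   (data.frame with model_size, removed_feature, train_auc),
#'   \code{models} is not kept except the final refit \code{model},
#'   \code{selected_features}, \code{selected_size}.
#' @export
backward_eliminate <- function(X, y, lambda = 1e-4) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("empty starting feature set")
  current <- colnames(X)
  if (is.null(current)) {
    colnames(X) <- current <- sprintf("x%d", seq_len(ncol(X)))
  }
  sizes <- integer(0); removed <- character(0); aucs <- numeric(0)
  feature_sets <- list()
  while (length(current) >= 1L) {
    fit <- fit_logistic(X[, current, drop = FALSE], y, lambda = lambda)
    auc <- roc_auc(predict_proba(fit, X[, current, drop = FALSE]), y)
    sizes <- c(sizes, length(current))
    aucs <- c(aucs, auc)
    feature_sets[[length(sizes)]] <- current
    if (length(current) == 1L) {
      removed <- c(removed, NA_character_)
      break
    }
    worst <- names(which.max(fit$p_values))
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
  }
  best <- which(aucs == max(aucs))
  pick <- best[which.min(sizes[best])]
  sel <- feature_sets[[pick]]
  final <- fit_logistic(X[, sel, drop = FALSE], y, lambda = lambda)
  structure(list(trace = data.frame(model_size = sizes,
                                    removed_feature = removed,
                                    train_auc = aucs,
                                    stringsAsFactors = FALSE),
                 selected_features = sel,
                 selected_size = length(sel),
                 model = final),
            class = "elimination_trace")
}
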