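#' Cox proportional-hazards fit (univariate or multivariate)
#'
#' Wraps a partial-likelihood Newton-Raphson fit with Efron tie handling
#' (day-resolution survival produces heavy ties) and returns, per
#' coefficient, the log hazard ratio beta, HR = exp(beta), the symmetric
#' Wald 95\% CI exp(beta +/- 1.96 se), and the Wald p-value. Patients with
#' survival below \code{min_days} are removed before fitting (signature
#' construction rule); set \code{min_days = 0} to keep everyone.
#'
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param os_days,event survival time (days) and 0/1 event flag.
#' @param min_days exclusion threshold in days (default 0).
#' @param ties tie-handling method, default \code{"efron"}.
#' @return An object of class \code{cox_fit}: data.frame \code{summary}
#'   (term, beta, hr, ci_lower, ci_upper, se, p), plus \code{n},
#'   \code{n_events}, \code{converged}, \code{ties}.
#' @export
cox_fit <- function(covariates, os_days, event, min_days = 0,
                    ties = "efron") {
  X <- if (is.data.frame(covariates)) covariates else
    as.data.frame(as.matrix(covariates))
  if (is.null(colnames(X)) || any(colnames(X) == ""))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  os_days <- as.numeric(os_days); event <- as.numeric(event)
  keep <- os_days >= min_days
  X <- X[keep, , drop = FALSE]
  os_days <- os_days[keep]; event <- event[keep]
  if (sum(event) == 0) stop("no events in the (filtered) data")
  if (sum(event) < 10) warning("fewer than 10 events: unstable fit")
  dat <- cbind(data.frame(.time = os_days, .event = event), X)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(X)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  summ <- data.frame(term = names(beta),
                     beta = as.numeric(beta),
                     hr = exp(as.numeric(beta)),
                     ci_lower = exp(as.numeric(beta) - 1.96 * se),
                     ci_upper = exp(as.numeric(beta) + 1.96 * se),
                     se = as.numeric(se),
                     p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summ, n = fit$n, n_events = fit$nevent,
                 converged = is.null(fit$info) || fit$iter < 100,
                 ties = ties, fit = fit),
            class = "cox_fit")
}

#' Univariate Cox screen for prognostic features
#'
#' Fits one Cox model per feature (after removing short-survival patients)
#' and retains features with Wald p < alpha; the retained betas become the
#' risk-score weights.
#'
#' @param features \code{\link{feature_table}} or numeric matrix (samples x
#'   features), typically restricted to the IDH-specific (SAM-selected) set.
#' @param os_days,event survival data aligned with the feature rows.
#' @param alpha Wald p cutoff (default 0.05).
#' @param min_days survival exclusion threshold in days (default 30).
#' @return An object of class \code{risk_model}: \code{feature_names},
#'   \code{weights} (Cox betas), \code{univariate} (full per-feature
#'   data.frame), \code{alpha}, \code{min_days}; \code{cutoff} is NA until
#'   \code{\link{optimal_cutoff}} is applied.
#' @export
select_prognostic_features <- function(features, os_days, event,
                                       alpha = 0.05, min_days = 30) {
  X <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  if (length(os_days) != nrow(X)) stop("survival length mismatch")
  if (sum(as.numeric(event)) == 0) stop("no events in survival data")
  rows <- lapply(colnames(X), function(f) {
    fit <- tryCatch(
      suppressWarnings(cox_fit(stats::setNames(data.frame(X[, f]), f),
                               os_days, event, min_days = min_days)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    fit$summary
  })
  uni <- do.call(rbind, rows)
  if (is.null(uni)) stop("no feature could be fit")
  uni <- uni[is.finite(uni$beta) & is.finite(uni$p), , drop = FALSE]
  keep <- uni$p < alpha
  structure(list(feature_names = uni$term[keep],
                 weights = stats::setNames(uni$beta[keep], uni$term[keep]),
                 univariate = uni, alpha = alpha, min_days = min_days,
                 cutoff = NA_real_),
            class = "risk_model")
}

#' Cox-weighted prognostic risk score
#'
#' Risk score = sum over retained features of (feature value x Cox beta),
#' an exact linear combination with no further normalization.
#'
#' @param features feature values: \code{\link{feature_table}}, matrix or
#'   data.frame containing every model feature.
#' @param model a \code{risk_model} from
#'   \code{\link{select_prognostic_features}}.
#' @return Named numeric vector of per-sample scores.
#' @export
risk_score <- function(features, model) {
  X <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) stop("missing model features: ",
                            paste(missing, collapse = ", "))
  drop(X[, model$feature_names, drop = FALSE] %*% model$weights)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function.
#'
#' @param os_days,event survival time and 0/1 event flag.
#' @return An object of class \code{km_curve}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}.
#' @export
km_estimate <- function(os_days, event) {
  fit <- survival::survfit(survival::Surv(as.numeric(os_days),
                                          as.numeric(event)) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event),
            class = "km_curve")
}

#' Log-rank test between two survival groups
#'
#' @param time_a,event_a survival data of group A.
#' @param time_b,event_b survival data of group B.
#' @return List with \code{statistic} (1-df chi-square) and \code{p}.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("empty group")
  time <- c(as.numeric(time_a), as.numeric(time_b))
  event <- c(as.numeric(event_a), as.numeric(event_b))
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  if (sum(event) == 0) stop("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = as.numeric(sd$chisq),
       p = stats::pchisq(as.numeric(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Log-rank-optimal risk-score cutoff
#'
#' Exhaustive scan over midpoints of adjacent sorted unique scores; the
#' cutoff minimizing the two-group log-rank p-value is returned (ties break
#' toward the lower cutoff). Candidates leaving fewer than
#' \code{min_group_frac} of the samples on either side are infeasible. The
#' cutoff chosen on a training cohort is frozen and applied unchanged to
#' other cohorts.
#'
#' @param scores per-sample risk scores.
#' @param os_days,event survival data.
#' @param min_group_frac minimum fraction of samples per side (default 0.1).
#' @return List of class \code{cutoff_scan}: \code{cutoff}, \code{p},
#'   \code{candidates} (data.frame cutoff/p).
#' @export
optimal_cutoff <- function(scores, os_days, event, min_group_frac = 0.1) {
  scores <- as.numeric(scores)
  n <- length(scores)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("no feasible cutoff: all scores equal")
  cand <- (u[-1] + u[-length(u)]) / 2
  min_n <- max(1L, ceiling(min_group_frac * n))
  feasible <- vapply(cand, function(cut)
    sum(scores > cut) >= min_n && sum(scores <= cut) >= min_n, logical(1))
  cand <- cand[feasible]
  if (!length(cand)) stop("no feasible cutoff under the group-size constraint")
  pvals <- vapply(cand, function(cut) {
    hi <- scores > cut
    logrank_test(os_days[hi], event[hi], os_days[!hi], event[!hi])$p
  }, numeric(1))
  best <- which(pvals == min(pvals))[1]  # ties -> lower cutoff (cand sorted)
  list(cutoff = cand[best], p = pvals[best],
       candidates = data.frame(cutoff = cand, p = pvals))
}
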