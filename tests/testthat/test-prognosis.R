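sim_ph <- function(n, beta, censor = 0.2, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  surv <- generate_survival(beta * z, lambda0 = 1 / 1000,
                            censor_rate = censor, seed = seed + 1)
  list(z = z, os = surv$os_days, ev = surv$event)
}

test_that("cox_fit output is internally consistent (HR, CI identities)", {
  d <- sim_ph(300, 0.6, seed = 41)
  fit <- cox_fit(data.frame(z = d$z), d$os, d$ev)
  s <- fit$summary
  expect_equal(s$hr, exp(s$beta), tolerance = 1e-12)
  expect_equal(s$hr, sqrt(s$ci_lower * s$ci_upper), tolerance = 1e-9)
  expect_true(s$ci_lower <= s$hr && s$hr <= s$ci_upper)
  expect_equal(fit$ties, "efron")
})

test_that("null covariates give small coefficients", {
  d <- sim_ph(500, 0, seed = 42)
  fit <- cox_fit(data.frame(z = d$z), d$os, d$ev)
  expect_lt(abs(fit$summary$beta), 0.15)
})

test_that("planted log-hazard is recovered at n = 1000", {
  d <- sim_ph(1000, 0.7, censor = 0.2, seed = 43)
  fit <- cox_fit(data.frame(z = d$z), d$os, d$ev)
  expect_lt(abs(fit$summary$beta - 0.7), 0.1)
})

test_that("short-survival exclusion applies before fitting", {
  d <- sim_ph(200, 0.5, seed = 44)
  d$os[1:20] <- 5
  fit <- cox_fit(data.frame(z = d$z), d$os, d$ev, min_days = 30)
  expect_equal(fit$n, sum(d$os >= 30))
})

test_that("prognostic screen keeps planted features, bounds false hits", {
  set.seed(45)
  n <- 300
  X <- matrix(rnorm(n * 23), n, 23,
              dimnames = list(NULL, c(paste0("true", 1:3),
                                      paste0("null", 1:20))))
  risk <- 0.8 * X[, 1] + 0.8 * X[, 2] + 0.8 * X[, 3]
  surv <- generate_survival(risk, censor_rate = 0.2, seed = 45)
  mod <- select_prognostic_features(X, surv$os_days, surv$event,
                                    alpha = 0.05, min_days = 0)
  expect_true(all(paste0("true", 1:3) %in% mod$feature_names))
  false_hits <- sum(grepl("^null", mod$feature_names))
  expect_lte(false_hits, 4)
  # retained set invariant to feature ordering
  perm <- sample(23)
  mod2 <- select_prognostic_features(X[, perm], surv$os_days, surv$event,
                                     alpha = 0.05, min_days = 0)
  expect_setequal(mod$feature_names, mod2$feature_names)
  # alpha = 0 boundary: empty set
  mod0 <- select_prognostic_features(X, surv$os_days, surv$event,
                                     alpha = 1e-300, min_days = 0)
  expect_length(mod0$feature_names, 0)
})

test_that("risk score is the exact linear combination", {
  mod <- structure(list(feature_names = "f", weights = c(f = 2),
                        cutoff = NA_real_), class = "risk_model")
  X <- matrix(1.5, 1, 1, dimnames = list("s1", "f"))
  expect_equal(unname(risk_score(X, mod)), 3.0)
  mod$weights <- c(f = 0)
  expect_equal(unname(risk_score(X, mod)), 0)
  # linearity in each feature
  mod2 <- structure(list(feature_names = c("a", "b"),
                         weights = c(a = 0.5, b = -2),
                         cutoff = NA_real_), class = "risk_model")
  X2 <- cbind(a = c(1, 2), b = c(3, 3))
  expect_equal(diff(risk_score(X2, mod2)), 0.5 * 1)
  expect_error(risk_score(X, mod2), "missing model features")
})

test_that("KM with no censoring equals the empirical survivor function", {
  os <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- km_estimate(os, rep(1, 8))
  ecdf_surv <- vapply(km$time, function(t) mean(os > t), numeric(1))
  expect_equal(km$surv, ecdf_surv)
  expect_true(all(diff(km$surv) <= 0) && all(km$surv >= 0 & km$surv <= 1))
})

test_that("log-rank statistic matches the hand-computed O-E example", {
  # two groups of 5, all events
  ta <- c(1, 3, 5, 7, 9); tb <- c(2, 4, 6, 8, 10)
  res <- logrank_test(ta, rep(1, 5), tb, rep(1, 5))
  # hand O-E accumulation over the 10 distinct event times
  time <- c(ta, tb); ev <- rep(1, 10); grp <- rep(0:1, each = 5)
  o_minus_e <- 0; var_sum <- 0
  for (t in sort(time)) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t)
    o <- sum(time == t & grp == 1)
    e <- d * n1 / n
    o_minus_e <- o_minus_e + (o - e)
    if (n > 1) var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$statistic, o_minus_e^2 / var_sum, tolerance = 1e-10)
  # identical groups: statistic 0, p 1
  res0 <- logrank_test(ta, rep(1, 5), ta, rep(1, 5))
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-10)
})

test_that("log-rank p is consistent with a permutation reference", {
  set.seed(46)
  d <- sim_ph(60, 1.0, censor = 0.2, seed = 46)
  hi <- d$z > 0
  obs <- logrank_test(d$os[hi], d$ev[hi], d$os[!hi], d$ev[!hi])
  perm_stats <- replicate(400, {
    g <- sample(hi)
    logrank_test(d$os[g], d$ev[g], d$os[!g], d$ev[!g])$statistic
  })
  p_perm <- mean(perm_stats >= obs$statistic)
  expect_lt(abs(p_perm - obs$p), 0.05 + 3 * sqrt(obs$p * (1 - obs$p) / 400))
})

test_that("optimal cutoff minimizes the scanned log-rank p exhaustively", {
  set.seed(47)
  n <- 80
  grp <- rep(0:1, each = n / 2)
  scores <- grp * 2 + rnorm(n, 0, 0.3)        # two well-separated score groups
  surv <- generate_survival(1.2 * grp, censor_rate = 0.15, seed = 47)
  res <- optimal_cutoff(scores, surv$os_days, surv$event)
  # falls between the two planted groups
  expect_gt(res$cutoff, max(scores[grp == 0]) - 0.5)
  expect_lt(res$cutoff, min(scores[grp == 1]) + 0.5)
  # exhaustive check: no candidate beats the returned one
  expect_true(all(res$candidates$p >= res$p - 1e-12))
  hi <- scores > res$cutoff
  expect_equal(logrank_test(surv$os_days[hi], surv$event[hi],
                            surv$os_days[!hi], surv$event[!hi])$p, res$p)
})

test_that("degenerate cutoff inputs error out", {
  expect_error(optimal_cutoff(rep(1, 20), 1:20, rep(1, 20)), "all scores equal")
})

test_that("high-risk group is stochastically dominated on synthetic cohorts", {
  set.seed(48)
  n <- 500
  z <- rnorm(n)
  surv <- generate_survival(1.0 * z, censor_rate = 0.2, seed = 48)
  hi <- z > median(z)
  km_hi <- km_estimate(surv$os_days[hi], surv$event[hi])
  km_lo <- km_estimate(surv$os_days[!hi], surv$event[!hi])
  # compare at common grid
  grid <- quantile(surv$os_days, c(0.2, 0.4, 0.6, 0.8))
  sv <- function(km, t) {
    i <- findInterval(t, km$time)
    if (i == 0) 1 else km$surv[i]
  }
  for (t in grid)
    expect_lt(sv(km_hi, t), sv(km_lo, t))
})
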