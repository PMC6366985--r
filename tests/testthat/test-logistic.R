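test_that("separated 1D data gives monotone probabilities", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(x, y, lambda = 1e-4)
  p <- predict_proba(fit, x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p[y == 1] > 0.5) && all(p[y == 0] < 0.5))
})

test_that("null Wald p-values are approximately uniform", {
  set.seed(31)
  pv <- replicate(30, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- rbinom(200, 1, 0.5)
    fit_logistic(X, y, lambda = 1e-4)$p_values
  })
  pv <- as.vector(pv)
  expect_gt(ks.test(pv, "punif")$p.value, 1e-3)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("coefficients are consistent for planted effects", {
  set.seed(32)
  n <- 2000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- 2 * X[, 1]          # true beta = (2, 0), no intercept
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_logistic(X, y, lambda = 1e-6, standardize = FALSE)
  expect_lt(abs(fit$coefficients[["a"]] - 2), 0.2)
  expect_lt(abs(fit$coefficients[["b"]]), 0.2)
  expect_true(fit$converged)
})

test_that("ridge logistic agrees with glm at negligible penalty", {
  set.seed(33)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- rbinom(120, 1, plogis(0.5 * X[, 1] - 0.7 * X[, 3]))
  ours <- fit_logistic(X, y, lambda = 1e-10, standardize = FALSE)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-4)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("AUC equals exhaustive pair counting, with tie handling", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  set.seed(34)
  for (rep in 1:15) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)     # induces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                 info = paste("rep", rep))
  }
})

test_that("label flip maps AUC to its complement", {
  set.seed(35)
  s <- runif(30); l <- rbinom(30, 1, 0.4)
  if (length(unique(l)) == 2)
    expect_equal(roc_auc(s, l), 1 - roc_auc(s, 1 - l))
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("backward elimination keeps the informative feature", {
  set.seed(36)
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(n, 1, plogis(2 * X[, 1]))
    elim <- backward_eliminate(X, y, lambda = 1e-4)
    "f1" %in% elim$selected_features
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the elimination trace is strictly nested and reproducible", {
  set.seed(37)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(60, 1, plogis(X[, 2]))
  e1 <- backward_eliminate(X, y)
  e2 <- backward_eliminate(X, y)
  expect_identical(e1$trace, e2$trace)
  expect_equal(e1$trace$model_size, 6:1)
  # removed features never reappear
  expect_equal(anyDuplicated(na.omit(e1$trace$removed_feature)), 0)
  # chosen model attains the max AUC with the fewest features
  best <- max(e1$trace$train_auc)
  expect_equal(e1$selected_size,
               min(e1$trace$model_size[e1$trace$train_auc == best]))
})

test_that("validation scoring reuses frozen training standardization", {
  set.seed(38)
  X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(100, 1, plogis(1.5 * X[, 1]))
  fit <- fit_logistic(X, y)
  Xval <- matrix(rnorm(40 * 2, mean = 5), 40, 2,
                 dimnames = list(NULL, c("u", "v")))
  p <- predict_proba(fit, Xval)
  # shifted validation data must be standardized with training parameters,
  # hence probabilities saturate toward the positive class side
  expect_true(all(p >= 0 & p <= 1))
  manual <- plogis(fit$intercept +
                     drop(sweep(sweep(Xval, 2, fit$center), 2, fit$scale,
                                `/`) %*% fit$coefficients))
  expect_equal(p, manual, tolerance = 1e-12)
})
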