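test_that("sphere phantom voxel count matches the closed form", {
  ph <- generate_phantom(phantom_spec("sphere", size = 10,
                                      intensity = list(model = "constant"),
                                      seed = 1))
  count <- sum(ph$mask$data)
  expect_lt(abs(count - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("constant-intensity phantoms are constant on the foreground", {
  ph <- generate_phantom(phantom_spec("cube", size = 6,
                                      intensity = list(model = "constant",
                                                       value = 3),
                                      seed = 2))
  fg <- ph$volume$data[ph$mask$data == 1]
  expect_true(all(fg == 3))
  expect_true(all(ph$volume$data[ph$mask$data == 0] == 0))
})

test_that("phantom generation is deterministic given (spec, seed)", {
  spec <- phantom_spec("perturbed_sphere", size = 7,
                       intensity = list(model = "gaussian", mean = 1, sd = 2),
                       perturbation_amplitude = 0.2, smoothness = 1, seed = 9)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$data, p2$mask$data)
})

test_that("degenerate phantom sizes are rejected", {
  expect_error(phantom_spec("sphere", size = 1), "3 voxels")
  expect_error(phantom_spec("sphere", size = -2), "degenerate")
})

test_that("survival generator hits the target event fraction", {
  set.seed(61)
  risk <- rnorm(800, 0, 0.8)
  surv <- generate_survival(risk, lambda0 = 1 / 500, censor_rate = 0.3,
                            seed = 61)
  expect_lt(abs(mean(surv$event) - 0.7), 0.05)
  surv0 <- generate_survival(risk, censor_rate = 0, seed = 61)
  expect_true(all(surv0$event == 1))
  expect_error(generate_survival(risk, lambda0 = -1), "lambda0")
})

test_that("doubling exp(risk) halves median survival (exponential PH)", {
  n <- 40000
  s1 <- generate_survival(rep(0, n), lambda0 = 1 / 1000, censor_rate = 0,
                          seed = 62)
  s2 <- generate_survival(rep(log(2), n), lambda0 = 1 / 1000, censor_rate = 0,
                          seed = 63)
  expect_equal(median(s1$os_days) / median(s2$os_days), 2, tolerance = 0.06)
})

test_that("equal risks give uniform log-rank p over random halves", {
  set.seed(64)
  pvals <- vapply(1:15, function(s) {
    surv <- generate_survival(rep(0, 60), censor_rate = 0.2, seed = s)
    g <- sample(rep(c(TRUE, FALSE), 30))
    logrank_test(surv$os_days[g], surv$event[g],
                 surv$os_days[!g], surv$event[!g])$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("expression planting achieves the requested correlation", {
  set.seed(65)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(sprintf("s%03d", 1:n),
                                                  c("fa", "fb")))
  expr <- generate_expression(X, n_genes = 50,
                              planted = list(
                                gA = list(feature = "fa", rho = 0.6),
                                gB = list(feature = "fb", rho = -0.5)),
                              seed = 65)
  expect_equal(cor(expr$values["gA", ], X[, "fa"]), 0.6, tolerance = 0.15)
  expect_equal(cor(expr$values["gB", ], X[, "fb"]), -0.5, tolerance = 0.15)
  # unplanted genes are null
  expect_lt(abs(cor(expr$values["gene_0050", ], X[, "fa"])), 0.25)
  expect_error(generate_expression(X, planted = list(
    g = list(feature = "missing", rho = 0.5))), "absent")
})

test_that("cohort generator is reproducible and carries planted truth", {
  spec <- cohort_spec(n_per_class = c(3, 3), delta = 1.5, radius = 6,
                      seed = 66)
  c1 <- generate_cohort(spec, extract = FALSE)
  c2 <- generate_cohort(spec, extract = FALSE)
  expect_identical(c1$volumes[[1]]$data, c2$volumes[[1]]$data)
  expect_identical(c1$clinical$os_days, c2$clinical$os_days)
  expect_equal(c1$clinical$label, rep(c("WT", "MUT"), each = 3))
  expect_length(c1$truth$risk, 6)
  # class-2 mean intensity carries the planted shift
  mu <- vapply(seq_along(c1$volumes), function(i)
    mean(c1$volumes[[i]]$data[c1$masks[[i]]$data == 1]), numeric(1))
  # smoothed noise leaves a per-sample mean jitter of ~0.13, so compare
  # at 3 standard errors of the 3-vs-3 class means
  expect_equal(mean(mu[4:6]) - mean(mu[1:3]),
               1.5 + mean(c1$truth$z2[4:6]) - mean(c1$truth$z2[1:3]),
               tolerance = 0.45)
})

test_that("null cohorts produce no differential features", {
  spec <- cohort_spec(n_per_class = c(6, 6), delta = 0,
                      smoothness = c(1, 1), irregularity = c(0.08, 0.08),
                      radius = 6, seed = 67)
  coh <- generate_cohort(spec, extract = TRUE)
  counts <- vapply(1:3, function(s) {
    res <- sam_select(coh$features, coh$clinical$label,
                      n_permutations = 150, seed = s)
    sum(res$selected)
  }, numeric(1))
  expect_lt(mean(counts), 3)
})
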