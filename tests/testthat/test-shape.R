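test_that("discretized sphere matches analytic surface and volume", {
  r <- 10
  msk <- make_sphere_mask(r = r)
  sh <- shape_features(msk)
  v_analytic <- 4 / 3 * pi * r^3
  expect_lt(abs(sh[["shape_volume"]] - v_analytic) / v_analytic, 0.02)
  expect_lt(abs(sh[["shape_surface_to_volume_ratio"]] - 3 / r) / (3 / r), 0.05)
  expect_lt(abs(sh[["shape_sphericity"]] - 1), 0.05)
  expect_lt(abs(sh[["shape_spherical_disproportion"]] - 1), 0.05)
  # diameter of a radius-10 sphere of voxel centers
  expect_lt(abs(sh[["shape_maximum_3d_diameter"]] - 2 * r) / (2 * r), 0.07)
})

test_that("axis-aligned cube has SVR near 6/a and exact voxel volume", {
  a <- 10
  d <- c(16, 16, 16)
  m <- array(0, dim = d); m[4:13, 4:13, 4:13] <- 1
  sh <- shape_features(tumor_mask(m))
  expect_equal(sh[["shape_volume"]], a^3)
  # mesh rounds corners slightly; face-counted SVR is 6/a
  expect_lt(abs(sh[["shape_surface_to_volume_ratio"]] - 6 / a) / (6 / a), 0.15)
})

test_that("single voxel mask yields voxel volume and zero diameter", {
  m <- array(0, dim = c(5, 5, 5)); m[3, 3, 3] <- 1
  sh <- shape_features(tumor_mask(m, spacing = c(1, 1, 1)))
  expect_equal(sh[["shape_volume"]], 1)
  expect_equal(sh[["shape_maximum_3d_diameter"]], 0)
  expect_true(all(is.finite(sh)))
})

test_that("shape features respect physical spacing", {
  m <- array(0, dim = c(8, 8, 8)); m[3:6, 3:6, 3:6] <- 1
  iso <- shape_features(tumor_mask(m, spacing = c(1, 1, 1)))
  big <- shape_features(tumor_mask(m, spacing = c(2, 2, 2)))
  expect_equal(big[["shape_volume"]], 8 * iso[["shape_volume"]])
  expect_equal(big[["shape_surface_area"]], 4 * iso[["shape_surface_area"]],
               tolerance = 1e-8)
  expect_equal(big[["shape_maximum_3d_diameter"]],
               2 * iso[["shape_maximum_3d_diameter"]])
})

test_that("shape features are invariant to axis permutation with spacing", {
  set.seed(5)
  m <- array(0, dim = c(9, 11, 7))
  m[3:7, 4:9, 2:6] <- (array(runif(5 * 6 * 5), dim = c(5, 6, 5)) > 0.3) * 1
  if (sum(m) == 0) m[5, 5, 4] <- 1
  sp <- c(0.6, 0.8, 2.0)
  a <- shape_features(tumor_mask(m, spacing = sp))
  b <- shape_features(tumor_mask(aperm(m, c(3, 1, 2)),
                                 spacing = sp[c(3, 1, 2)]))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("sphere minimizes SVR among equal-volume phantoms", {
  sph <- generate_phantom(phantom_spec("sphere", size = 8,
                                       intensity = list(model = "constant"),
                                       seed = 1))
  per <- generate_phantom(phantom_spec("perturbed_sphere", size = 8,
                                       intensity = list(model = "constant"),
                                       perturbation_amplitude = 0.25,
                                       seed = 1))
  s1 <- shape_features(sph$mask)
  s2 <- shape_features(per$mask)
  svr_eq <- function(sh) 3 / ((3 * sh[["shape_volume"]] / (4 * pi))^(1 / 3))
  # compare SVR after normalizing to each phantom's own volume scale
  expect_gt(s2[["shape_surface_to_volume_ratio"]] / svr_eq(s2),
            s1[["shape_surface_to_volume_ratio"]] / svr_eq(s1))
})

test_that("surface irregularity amplitude maps monotonically to SVR", {
  amps <- c(0, 0.1, 0.2, 0.3)
  ratios <- vapply(amps, function(a) {
    ph <- generate_phantom(phantom_spec("perturbed_sphere", size = 8,
                                        intensity = list(model = "constant"),
                                        perturbation_amplitude = a, seed = 3))
    sh <- shape_features(ph$mask)
    svr_eq <- 3 / ((3 * sh[["shape_volume"]] / (4 * pi))^(1 / 3))
    sh[["shape_surface_to_volume_ratio"]] / svr_eq
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
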