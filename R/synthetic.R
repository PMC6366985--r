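#' Phantom specification
#'
#' Describes a single synthetic tumor phantom: an analytic base shape
#' (sphere, cube, ellipsoid, or radially perturbed sphere), an intensity
#' model for the foreground, and the voxel spacing. Sizes are in voxels.
#'
#' @param shape_kind one of \code{"sphere"}, \code{"cube"},
#'   \code{"ellipsoid"}, \code{"perturbed_sphere"}.
#' @param size numeric: radius for spheres, edge for cubes, three semi-axes
#'   for ellipsoids (voxels, >= 3 effective extent).
#' @param intensity list: \code{model} in \code{"constant"},
#'   \code{"gaussian"}, \code{"checker"}; \code{mean}/\code{sd} for
#'   gaussian, \code{value} for constant, \code{low}/\code{high}/
#'   \code{period} for the two-level checker.
#' @param spacing voxel spacing in mm.
#' @param perturbation_amplitude relative radial perturbation amplitude for
#'   \code{perturbed_sphere} (0 = exact sphere).
#' @param smoothness Gaussian blur sd (voxels) applied to gaussian-noise
#'   intensities; 0 disables.
#' @param margin background voxels added around the shape.
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape_kind = "sphere", size = 10,
                         intensity = list(model = "gaussian", mean = 0, sd = 1),
                         spacing = c(1, 1, 1),
                         perturbation_amplitude = 0,
                         smoothness = 0,
                         margin = 4L, seed = 1L) {
  shape_kind <- match.arg(shape_kind,
                          c("sphere", "cube", "ellipsoid", "perturbed_sphere"))
  size <- as.numeric(size)
  if (shape_kind == "ellipsoid" && length(size) != 3L)
    stop("ellipsoid needs three semi-axes")
  if (any(size <= 0)) stop("degenerate size")
  extent <- if (shape_kind == "cube") size[1] else 2 * max(size)
  if (extent < 3) stop("shape must span at least 3 voxels")
  if (!is.null(intensity$sd) && intensity$sd < 0) stop("sd must be >= 0")
  if (perturbation_amplitude < 0) stop("amplitude must be >= 0")
  structure(list(shape_kind = shape_kind, size = size, intensity = intensity,
                 spacing = as.numeric(spacing),
                 perturbation_amplitude = perturbation_amplitude,
                 smoothness = smoothness, margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic tumor phantom
#'
#' Discretizes the spec's analytic shape on a voxel grid (a voxel is
#' foreground when its center satisfies the shape inequality) and fills the
#' foreground with the requested intensity model. Perturbed spheres modulate
#' the radius with a smoothed random field on the direction sphere, so the
#' perturbation amplitude monotonically increases surface irregularity.
#' Deterministic given (spec, seed).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{volume} (\code{\link{image_volume}}) and
#'   \code{mask} (\code{\link{tumor_mask}}).
#' @export
generate_phantom <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  half <- if (spec$shape_kind == "cube") spec$size[1] / 2 else
    max(spec$size) * (1 + spec$perturbation_amplitude * 2.5)
  n <- ceiling(2 * half) + 2L * spec$margin
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  dx <- array(ax, dim = c(n, n, n))
  dy <- aperm(dx, c(2, 1, 3))
  dz <- aperm(dx, c(3, 2, 1))

  m <- switch(spec$shape_kind,
    sphere = dx^2 + dy^2 + dz^2 <= spec$size[1]^2,
    cube = abs(dx) <= spec$size[1] / 2 & abs(dy) <= spec$size[1] / 2 &
      abs(dz) <= spec$size[1] / 2,
    ellipsoid = (dx / spec$size[1])^2 + (dy / spec$size[2])^2 +
      (dz / spec$size[3])^2 <= 1,
    perturbed_sphere = {
      rr <- sqrt(dx^2 + dy^2 + dz^2)
      field <- unit_sphere_noise_field(dx, dy, dz, rr)
      rr <= spec$size[1] * (1 + spec$perturbation_amplitude * field)
    })
  if (!any(m)) stop("degenerate spec: empty mask")

  vol <- array(0, dim = c(n, n, n))
  im <- spec$intensity
  model <- if (is.null(im$model)) "gaussian" else im$model
  if (model == "constant") {
    vol[m] <- if (is.null(im$value)) 1 else im$value
  } else if (model == "gaussian") {
    noise <- array(stats::rnorm(n^3, 0, 1), dim = c(n, n, n))
    if (spec$smoothness > 0) noise <- gaussian_blur3(noise, spec$smoothness)
    # blur shrinks the pointwise sd; rescale so the foreground sd stays im$sd
    noise <- noise / stats::sd(noise[m])
    vol[m] <- (if (is.null(im$mean)) 0 else im$mean) +
      (if (is.null(im$sd)) 1 else im$sd) * noise[m]
  } else if (model == "checker") {
    per <- if (is.null(im$period)) 2L else as.integer(im$period)
    phase <- (floor(dx / per) + floor(dy / per) + floor(dz / per)) %% 2
    vol[m] <- ifelse(phase[m] == 0,
                     if (is.null(im$low)) 0 else im$low,
                     if (is.null(im$high)) 1 else im$high)
  } else stop("unknown intensity model: ", model)

  list(volume = image_volume(vol, spacing = spec$spacing),
       mask = tumor_mask(m * 1, spacing = spec$spacing))
}

# Smooth zero-mean, unit-sd random field over directions, evaluated at every
# voxel's direction: low-order random spherical harmonics give a band-limited
# perturbation whose amplitude maps monotonically to surface irregularity.
unit_sphere_noise_field <- function(dx, dy, dz, rr) {
  r1 <- pmax(rr, 1e-9)
  ux <- dx / r1; uy <- dy / r1; uz <- dz / r1
  basis <- list(ux, uy, uz,
                ux * uy, uy * uz, ux * uz,
                ux^2 - uy^2, 3 * uz^2 - 1,
                ux * (ux^2 - 3 * uy^2), uz * (5 * uz^2 - 3))
  w <- stats::rnorm(length(basis))
  f <- 0
  for (k in seq_along(basis)) f <- f + w[k] * basis[[k]]
  f / sqrt(sum(w^2) + 1e-12)   # bounded, roughly unit scale
}

# Separable Gaussian blur with reflecting boundary (sigma in voxels).
gaussian_blur3 <- function(a, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    out <- array(0, dim = dim(a))
    d <- dim(a)[axis]
    for (t in seq_along(k)) {
      off <- (-rad:rad)[t]
      idx <- seq_len(d) + off
      idx[idx < 1L] <- 1L - (idx[idx < 1L] - 1L)   # reflect
      idx[idx > d] <- 2L * d - idx[idx > d] + 1L
      sl <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
      sl[[axis]] <- idx
      out <- out + k[t] * a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    }
    a <- out
  }
  a
}

#' Cohort specification for synthetic studies
#'
#' Defines a two-class phantom cohort with planted effects: an intensity
#' shift between classes (in units of the within-class sd of the per-sample
#' mean intensity), per-class texture smoothness and surface irregularity,
#' a proportional-hazards survival model on latent per-sample variables,
#' and gene expression with planted feature correlations.
#'
#' @param n_per_class integer vector of two class sizes (>= 2 each).
#' @param delta intensity shift between classes (class 2 minus class 1).
#' @param smoothness per-class Gaussian blur sd in voxels (length 2).
#' @param irregularity per-class radial perturbation amplitude (length 2).
#' @param radius base sphere radius in voxels.
#' @param survival list: \code{lambda0} baseline exponential rate per day,
#'   \code{beta} named coefficients on latent variables (subset of
#'   \code{"z1"}, \code{"z2"}), \code{censor_rate} in [0, 1).
#' @param expression list or NULL: \code{n_genes}, \code{planted} named list
#'   gene -> list(feature, rho), \code{noise_sd}.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_class = c(20L, 20L), delta = 0,
                        smoothness = c(1, 1), irregularity = c(0.05, 0.05),
                        radius = 8,
                        survival = list(lambda0 = 1 / 1000,
                                        beta = c(z1 = 0.7),
                                        censor_rate = 0.2),
                        expression = NULL,
                        spacing = c(1, 1, 1), seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 2L || any(n_per_class < 2L))
    stop("n_per_class must be two integers >= 2")
  if (!is.null(survival)) {
    if (survival$lambda0 <= 0) stop("lambda0 must be > 0")
    if (survival$censor_rate < 0 || survival$censor_rate >= 1)
      stop("censoring fraction must be in [0, 1)")
  }
  if (!is.null(expression) && !is.null(expression$planted)) {
    rhos <- vapply(expression$planted, function(p) p$rho, numeric(1))
    if (any(abs(rhos) >= 1)) stop("|rho| must be < 1")
  }
  structure(list(n_per_class = n_per_class, delta = delta,
                 smoothness = smoothness, irregularity = irregularity,
                 radius = radius, survival = survival,
                 expression = expression, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate survival times from a proportional-hazards model
#'
#' Event times are exponential with hazard lambda0 * exp(risk); censoring is
#' independent uniform on [0, H] with the horizon H solved numerically so
#' the expected censored fraction matches \code{censor_rate}. With
#' \code{censor_rate = 0} every observation is an event.
#'
#' @param risk per-sample linear predictor (finite reals).
#' @param lambda0 baseline hazard per day (> 0).
#' @param censor_rate target fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return Data.frame with \code{os_days} and \code{event}.
#' @export
generate_survival <- function(risk, lambda0 = 1 / 1000, censor_rate = 0.2,
                              seed = 1L) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (!all(is.finite(risk))) stop("risk must be finite")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rate <- lambda0 * exp(risk)
  tt <- stats::rexp(length(risk), rate = rate)
  if (censor_rate == 0)
    return(data.frame(os_days = tt, event = rep(1, length(tt))))
  # P(event | rate r, horizon H) = 1 - (1 - exp(-rH)) / (rH)
  event_frac <- function(H) mean(1 - (1 - exp(-rate * H)) / (rate * H))
  target <- 1 - censor_rate
  lo <- 1e-6 / lambda0; hi <- 1e6 / lambda0
  H <- stats::uniroot(function(h) event_frac(h) - target, c(lo, hi),
                      tol = 1e-10)$root
  cens <- stats::runif(length(risk), 0, H)
  data.frame(os_days = pmin(tt, cens), event = as.numeric(tt <= cens))
}

#' Generate gene expression with planted feature correlations
#'
#' Each planted gene is regressed on the z-scored extracted feature value:
#' gene = rho * z(feature) + sqrt(1 - rho^2) * noise, so the Pearson
#' correlation between gene and feature equals rho in expectation. All
#' remaining genes are independent noise.
#'
#' @param features \code{\link{feature_table}} or numeric matrix (samples x
#'   features) whose columns the planting refers to.
#' @param n_genes total gene count.
#' @param planted named list gene id -> list(feature, rho).
#' @param noise_sd sd of the independent noise component.
#' @param seed integer seed.
#' @return An \code{\link{expression_matrix}} (genes x samples).
#' @export
generate_expression <- function(features, n_genes = 500L, planted = list(),
                                noise_sd = 1, seed = 1L) {
  X <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  n <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (length(planted)) {
    miss <- setdiff(vapply(planted, `[[`, character(1), "feature"),
                    colnames(X))
    if (length(miss)) stop("planted features absent: ",
                           paste(miss, collapse = ", "))
    ids[seq_along(planted)] <- names(planted)
  }
  E <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)
  for (k in seq_along(planted)) {
    pl <- planted[[k]]
    z <- as.numeric(scale(X[, pl$feature]))
    E[k, ] <- pl$rho * z + sqrt(1 - pl$rho^2) * stats::rnorm(n, 0, 1)
  }
  expression_matrix(E, gene_ids = ids,
                    sample_ids = rownames(X) %||% sprintf("S%03d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Draws per-sample latent variables z1 (modulates surface irregularity) and
#' z2 (modulates mean intensity, carrying the class shift delta), renders
#' one perturbed-sphere phantom per sample, assigns WT/MUT class labels,
#' simulates proportional-hazards survival on the latents, and (optionally,
#' after feature extraction) plants gene-feature correlations in an
#' expression matrix.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param extract compute the 431-feature table (required for expression
#'   planting); default TRUE.
#' @param config \code{\link{analysis_config}} used for extraction.
#' @return List: \code{volumes}, \code{masks}, \code{clinical}
#'   (\code{\link{clinical_cohort}}), \code{features}
#'   (\code{\link{feature_table}} or NULL), \code{expression}
#'   (\code{\link{expression_matrix}} or NULL), \code{truth} (planted
#'   parameters and latent variables).
#' @export
generate_cohort <- function(spec, extract = TRUE,
                            config = analysis_config(seed = spec$seed)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- sum(spec$n_per_class)
  cls <- rep(1:2, spec$n_per_class)
  ids <- sprintf("S%03d", seq_len(n))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  # latent-to-phantom mapping: z1 widens/narrows the perturbation amplitude,
  # z2 shifts the mean intensity; the class adds delta on the z2 axis.
  amp <- pmax(0, spec$irregularity[cls] * exp(0.3 * z1))
  mu <- z2 + spec$delta * (cls == 2L)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)

  volumes <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(
      shape_kind = "perturbed_sphere", size = spec$radius,
      intensity = list(model = "gaussian", mean = mu[i], sd = 1),
      spacing = spec$spacing, perturbation_amplitude = amp[i],
      smoothness = spec$smoothness[cls[i]], seed = seeds[i]))
    volumes[[i]] <- ph$volume
    masks[[i]] <- ph$mask
  }
  names(volumes) <- names(masks) <- ids

  surv <- NULL
  risk <- rep(0, n)
  if (!is.null(spec$survival)) {
    b <- spec$survival$beta
    lat <- cbind(z1 = z1, z2 = z2)
    risk <- drop(lat[, names(b), drop = FALSE] %*% b)
    surv <- generate_survival(risk, lambda0 = spec$survival$lambda0,
                              censor_rate = spec$survival$censor_rate,
                              seed = seeds[1] + 1L)
  }
  clinical <- clinical_cohort(
    sample_ids = ids,
    label = ifelse(cls == 2L, "MUT", "WT"),
    os_days = surv$os_days, event = surv$event,
    age = round(stats::runif(n, 25, 70)),
    sex = sample(c("Male", "Female"), n, replace = TRUE),
    grade = sample(c("II", "III"), n, replace = TRUE))

  features <- NULL
  expr <- NULL
  if (extract) {
    features <- extract_cohort(volumes, masks, sample_ids = ids,
                               config = config)
    if (!is.null(spec$expression)) {
      ex <- spec$expression
      expr <- generate_expression(features,
                                  n_genes = ex$n_genes %||% 500L,
                                  planted = ex$planted %||% list(),
                                  noise_sd = ex$noise_sd %||% 1,
                                  seed = seeds[1] + 2L)
    }
  }
  list(volumes = volumes, masks = masks, clinical = clinical,
       features = features, expression = expr,
       truth = list(class = cls, z1 = z1, z2 = z2, risk = risk,
                    amplitude = amp, mean_intensity = mu,
                    survival = spec$survival, expression = spec$expression))
}
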