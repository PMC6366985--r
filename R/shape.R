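#' 3D shape descriptors of a tumor mask (8 features)
#'
#' Geometry is measured in physical units using the voxel spacing: volume is
#' voxel count times voxel volume; surface area comes from a triangulated
#' isosurface of the (lightly smoothed) binary mask built by marching
#' tetrahedra at iso-level 0.5; the maximum 3D diameter is the largest
#' pairwise Euclidean distance between surface voxel centers in mm.
#' Derived quantities: surface-to-volume ratio A/V, sphericity
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}, compactness 1 \eqn{V / (\sqrt{\pi}
#' A^{3/2})}, compactness 2 \eqn{36 \pi V^2 / A^3}, spherical disproportion
#' \eqn{A / (4 \pi R^2)} with \eqn{R = (3V / 4\pi)^{1/3}}.
#'
#' @param mask a \code{\link{tumor_mask}}.
#' @return Named numeric vector of 8 features with the \code{shape_} prefix.
#' @export
shape_features <- function(mask) {
  m <- mask$data != 0
  if (!any(m)) stop("empty mask")
  sp <- mask$spacing
  vol <- sum(m) * prod(sp)
  area <- mesh_surface_area(m, sp)
  diam <- max_pairwise_diameter(surface_voxel_coords(m, sp))
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  out <- c(
    volume = vol,
    surface_area = area,
    surface_to_volume_ratio = area / vol,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    compactness_1 = vol / (sqrt(pi) * area^(3 / 2)),
    compactness_2 = 36 * pi * vol^2 / area^3,
    spherical_disproportion = area / (4 * pi * r_eq^2),
    maximum_3d_diameter = diam
  )
  names(out) <- paste0("shape_", names(out))
  out
}

# Triangulated isosurface area by marching tetrahedra.
#
# The binary mask is zero-padded, smoothed with a separable [1,2,1]/4 kernel
# so isosurface vertices interpolate between voxel centers, and each grid
# cell is split into six tetrahedra sharing the main diagonal. Linear
# interpolation to iso-level 0.5 along tetrahedron edges yields one or two
# triangles per crossing tetrahedron; triangle areas are summed in mm^2.
mesh_surface_area <- function(m, spacing) {
  raw <- pad_zero(array(as.numeric(m), dim = dim(m)))
  f <- smooth_121(raw)
  a <- mesh_area_from_field(f, spacing)
  if (a == 0) a <- mesh_area_from_field(raw, spacing)  # 1-voxel-thin masks
  a
}

mesh_area_from_field <- function(f, spacing) {
  d <- dim(f)
  nc <- d - 1L
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  corner_vals <- lapply(1:8, function(ci) {
    o <- corner_off[ci, ]
    as.vector(f[(1:nc[1]) + o[1], (1:nc[2]) + o[2], (1:nc[3]) + o[3]])
  })
  inside <- lapply(corner_vals, function(v) v >= 0.5)
  n_in <- Reduce(`+`, inside)
  mixed <- which(n_in > 0 & n_in < 8)
  if (!length(mixed)) return(0)
  cv <- lapply(corner_vals, function(v) v[mixed])
  cell_idx <- arrayInd(mixed, nc)
  base <- sweep(cell_idx - 1L, 2L, spacing, `*`)
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  cases <- tetrahedron_cases()
  total <- 0
  for (t in seq_len(nrow(tets))) {
    ids <- tets[t, ]
    fv <- cbind(cv[[ids[1]]], cv[[ids[2]]], cv[[ids[3]]], cv[[ids[4]]])
    pos <- lapply(1:4, function(k)
      base + matrix(corner_off[ids[k], ] * spacing, nrow(base), 3, byrow = TRUE))
    patt <- (fv[, 1] >= 0.5) + 2L * (fv[, 2] >= 0.5) +
      4L * (fv[, 3] >= 0.5) + 8L * (fv[, 4] >= 0.5)
    for (pc in 1:14) {
      rows <- which(patt == pc)
      if (!length(rows)) next
      for (tri in cases[[pc]]) {
        pts <- lapply(tri, function(edge) {
          u <- edge[1]; w <- edge[2]
          fu <- fv[rows, u]; fw <- fv[rows, w]
          tt <- (0.5 - fu) / (fw - fu)
          pos[[u]][rows, , drop = FALSE] +
            tt * (pos[[w]][rows, , drop = FALSE] - pos[[u]][rows, , drop = FALSE])
        })
        e1 <- pts[[2]] - pts[[1]]
        e2 <- pts[[3]] - pts[[1]]
        cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        total <- total + 0.5 * sum(sqrt(rowSums(cr^2)))
      }
    }
  }
  total
}

pad_zero <- function(a) {
  d <- dim(a)
  out <- array(0, dim = d + 2L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  out
}

# Triangle list for each of the 14 crossing sign patterns of a tetrahedron.
# Each triangle is three edges, each edge an (inside, outside) vertex pair.
tetrahedron_cases <- function() {
  lapply(1:14, function(pc) {
    inside <- which(bitwAnd(pc, c(1L, 2L, 4L, 8L)) != 0L)
    outside <- setdiff(1:4, inside)
    if (length(inside) == 1L) {
      a <- inside
      list(list(c(a, outside[1]), c(a, outside[2]), c(a, outside[3])))
    } else if (length(inside) == 3L) {
      d <- outside
      list(list(c(inside[1], d), c(inside[2], d), c(inside[3], d)))
    } else {
      a <- inside[1]; b <- inside[2]; cc <- outside[1]; dd <- outside[2]
      e1 <- c(a, cc); e2 <- c(a, dd); e3 <- c(b, dd); e4 <- c(b, cc)
      list(list(e1, e2, e3), list(e1, e3, e4))
    }
  })
}

# Physical coordinates (mm) of mask voxels having at least one 6-neighbor
# outside the mask (or lying on the array border).
surface_voxel_coords <- function(m, spacing) {
  interior <- array(TRUE, dim = dim(m))
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    interior <- interior &
      shift_array(m, off[1], off[2], off[3], fill = FALSE) &
      shift_array(m, -off[1], -off[2], -off[3], fill = FALSE)
  }
  idx <- which(m & !interior, arr.ind = TRUE)
  sweep(idx - 1L, 2L, spacing, `*`)
}

# Exact maximum pairwise distance, chunked to bound memory.
max_pairwise_diameter <- function(pts, chunk = 2000L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  sq <- rowSums(pts^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[s:e], rep(1, n)) + outer(rep(1, e - s + 1L), sq) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
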