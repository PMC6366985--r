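# Internal array helpers shared by the texture and shape modules.

# Shift a 3D array by (dx, dy, dz): out[i,j,k] = a[i+dx, j+dy, k+dz],
# filling positions that fall outside with `fill`.
shift_array <- function(a, dx, dy, dz, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  ix <- sx + dx; iy <- sy + dy; iz <- sz + dz
  okx <- ix >= 1L & ix <= d[1]; oky <- iy >= 1L & iy <= d[2]
  okz <- iz >= 1L & iz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[ix[okx], iy[oky], iz[okz]]
  out
}

# Separable [1,2,1]/4 smoothing along each axis with zero boundary;
# used to place isosurface vertices between voxel centers.
smooth_121 <- function(a) {
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L)
    off[ax] <- 1L
    a <- 0.5 * a +
      0.25 * shift_array(a, off[1], off[2], off[3], fill = 0) +
      0.25 * shift_array(a, -off[1], -off[2], -off[3], fill = 0)
  }
  a
}

# The 13 unique 3D lattice directions (one of each +/- pair).
lattice_directions_13 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- dirs$dz > 0 | (dirs$dz == 0 & dirs$dy > 0) |
    (dirs$dz == 0 & dirs$dy == 0 & dirs$dx > 0)
  as.matrix(dirs[keep, , drop = FALSE])
}

# Bounding box (index ranges) of a logical/0-1 3D array.
mask_bbox <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  list(x = range(idx[, 1]), y = range(idx[, 2]), z = range(idx[, 3]))
}

crop_bbox <- function(a, bb, margin = 0L) {
  d <- dim(a)
  a[max(1L, bb$x[1] - margin):min(d[1], bb$x[2] + margin),
    max(1L, bb$y[1] - margin):min(d[2], bb$y[2] + margin),
    max(1L, bb$z[1] - margin):min(d[3], bb$z[2] + margin), drop = FALSE]
}
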