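# Independent brute-force oracles used to validate the vectorized
# implementations on small inputs.

# All 26 lattice offsets (both signs of each of the 13 directions).
all_offsets_26 <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
}

# GLCM by exhaustive ordered-pair enumeration: for every masked voxel and
# every one of the 26 offsets, count the (level, neighbor level) pair.
# Equivalent to symmetric accumulation over 13 directions.
brute_glcm <- function(levels_arr, Ng, distance = 1L) {
  d <- dim(levels_arr)
  offs <- all_offsets_26() * distance
  P <- matrix(0, Ng, Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- levels_arr[x, y, z]
    if (is.na(i)) next
    for (r in seq_len(nrow(offs))) {
      xx <- x + offs[r, 1]; yy <- y + offs[r, 2]; zz <- z + offs[r, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
        next
      j <- levels_arr[xx, yy, zz]
      if (is.na(j)) next
      P[i, j] <- P[i, j] + 1
    }
  }
  P / sum(P)
}

# GLRLM by explicit run walking along each of the 13 directions.
brute_glrlm <- function(levels_arr, Ng) {
  d <- dim(levels_arr)
  dirs <- lggradiomics_dirs13()
  lmax <- max(d)
  R <- matrix(0, Ng, lmax)
  inb <- function(x, y, z) x >= 1 && y >= 1 && z >= 1 &&
    x <= d[1] && y <= d[2] && z <= d[3]
  val <- function(x, y, z) if (inb(x, y, z)) levels_arr[x, y, z] else NA
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      v <- val(x, y, z)
      if (is.na(v)) next
      prev <- val(x - o[1], y - o[2], z - o[3])
      if (!is.na(prev) && prev == v) next   # not a run start
      len <- 1L
      while (TRUE) {
        nxt <- val(x + len * o[1], y + len * o[2], z + len * o[3])
        if (is.na(nxt) || nxt != v) break
        len <- len + 1L
      }
      R[v, len] <- R[v, len] + 1
    }
  }
  R
}

# Mirror of the package's 13-direction set (kept here independently so the
# oracle does not borrow internals).
lggradiomics_dirs13 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- dirs$dz > 0 | (dirs$dz == 0 & dirs$dy > 0) |
    (dirs$dz == 0 & dirs$dy == 0 & dirs$dx > 0)
  as.matrix(dirs[keep, , drop = FALSE])
}

# AUC by exhaustive concordant-pair counting, ties counted one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p by enumeration of the full hypergeometric support.
brute_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- n - a - b - cc
    exp(lchoose(c1, a) + lchoose(n - c1, b) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic quantized test region: random levels on a blobby mask.
random_quantized_region <- function(dim3 = c(7, 7, 7), Ng = 4L, seed = 1L,
                                    p_mask = 0.7) {
  set.seed(seed)
  m <- array(runif(prod(dim3)) < p_mask, dim = dim3)
  if (!any(m)) m[1, 1, 1] <- TRUE
  lev <- array(NA_integer_, dim = dim3)
  lev[m] <- sample.int(Ng, sum(m), replace = TRUE)
  structure(list(levels = lev[m], array = lev, mask = m, Ng = Ng),
            class = "quantized_region")
}

# Sphere phantom helpers shared across test files.
make_sphere_mask <- function(r = 10, spacing = c(1, 1, 1), margin = 3L) {
  n <- ceiling(2 * r) + 2L * margin
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  dx <- array(ax, dim = c(n, n, n))
  dy <- aperm(dx, c(2, 1, 3))
  dz <- aperm(dx, c(3, 2, 1))
  tumor_mask((dx^2 + dy^2 + dz^2 <= r^2) * 1, spacing = spacing)
}

make_noise_volume <- function(mask, mean = 0, sd = 1, seed = 1L) {
  set.seed(seed)
  d <- dim(mask$data)
  image_volume(array(rnorm(prod(d), mean, sd), dim = d),
               spacing = mask$spacing)
}
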