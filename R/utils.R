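# Internal array helpers shared across modules.

# Shift a 3-D array by one voxel along an axis, replicating the border.
shift3d <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  idx[[axis]] <- src
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Separable Gaussian smoothing of a 3-D array; sigma in voxels per axis.
# Border rows are renormalized (replicate-style), so constants are preserved
# exactly and interior-supported mass is conserved.
gaussSmooth3d <- function(a, sigmaVox) {
  sigmaVox <- rep(sigmaVox, length.out = 3)
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3.5 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- k[keep]
    }
    K <- K / rowSums(K)
    a <- applyAlongAxis(a, axis, K)
  }
  a
}

# Multiply each axis-`axis` fibre of `a` by matrix K (n x n).
applyAlongAxis <- function(a, axis, K) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# Gaussian smoothing of a field given sigma in mm and spacing in mm.
gaussSmoothMm <- function(a, sigmaMm, spacing) {
  gaussSmooth3d(a, sigmaMm / spacing)
}

# World-coordinate arrays (mm) for a grid; origin at the first voxel.
coordArrays <- function(dims, spacing) {
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]
  list(x = array(rep(cx, times = dims[2] * dims[3]), dims),
       y = array(rep(rep(cy, each = dims[1]), times = dims[3]), dims),
       z = array(rep(cz, each = dims[1] * dims[2]), dims))
}

# Stable 32-bit integer stream seed derived from a master seed and a string
# (subject id), so per-subject draws are reproducible under any ordering.
deriveSeed <- function(masterSeed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(masterSeed) * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` with a local RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trilinear sampling of a 3-D array at x + disp (disp in mm, 4-D array).
sampleWarped <- function(a, dispMm, spacing, clampEdge = FALSE, outside = 0) {
  d <- dim(a)
  out <- warp_trilinear_cpp(as.double(a), as.integer(d),
                            as.double(dispMm[, , , 1] / spacing[1]),
                            as.double(dispMm[, , , 2] / spacing[2]),
                            as.double(dispMm[, , , 3] / spacing[3]),
                            clampEdge, outside)
  array(out, d)
}

# Compose displacement fields: (u2 after u1)(x) = u2(x + u1(x)) + u1(x).
composeDisp <- function(u2, u1, spacing) {
  d <- dim(u1)
  out <- array(0, d)
  for (c in 1:3)
    out[, , , c] <- sampleWarped(u2[, , , c], u1, spacing, clampEdge = TRUE) +
      u1[, , , c]
  out
}

# Central-difference gradient of a 3-D array (one-sided at the faces),
# in units of value per mm.
gradient3d <- function(a, spacing) {
  d <- dim(a)
  g <- vector("list", 3)
  for (axis in 1:3) {
    fwd <- shift3d(a, axis, -1L)
    bwd <- shift3d(a, axis, 1L)
    den <- array(2 * spacing[axis], d)
    # one-sided at faces: shift3d replicates, so the difference spans 1 voxel
    idx <- lapply(d, seq_len)
    idx[[axis]] <- c(1L, d[axis])
    ones <- idx
    den[ones[[1]], ones[[2]], ones[[3]]] <- spacing[axis]
    g[[axis]] <- (fwd - bwd) / den
  }
  g
}

# Block-average downsampling by 2 along every axis (pads by replication if odd).
downsample2 <- function(a) {
  d <- dim(a)
  dp <- d + d %% 2
  if (any(dp != d)) {
    b <- array(0, dp)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    if (dp[1] > d[1]) b[dp[1], , ] <- b[d[1], , ]
    if (dp[2] > d[2]) b[, dp[2], ] <- b[, d[2], ]
    if (dp[3] > d[3]) b[, , dp[3]] <- b[, , d[3]]
    a <- b
    d <- dp
  }
  h <- d %/% 2
  dim(a) <- c(2, h[1], 2, h[2], 2, h[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}

# Trilinear upsampling of a 3-D array to target dims.
upsampleTo <- function(a, dims) {
  d <- dim(a)
  sc <- (d - 1) / pmax(dims - 1, 1)
  co <- coordArrays(dims, c(1, 1, 1))
  out <- resample_trilinear_cpp(as.double(a), as.integer(d),
                                as.double(co$x * sc[1]),
                                as.double(co$y * sc[2]),
                                as.double(co$z * sc[3]),
                                TRUE, 0)
  array(out, dims)
}
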