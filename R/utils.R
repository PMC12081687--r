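# internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing of a 3D array, sigma in voxels
gauss_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(m, n) {
    # banded convolution matrix with renormalized truncated edges
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K %*% m
  }
  x <- matrix(arr, d[1], d[2] * d[3])
  x <- smooth_axis(x, d[1])
  arr <- array(x, d)
  arr <- aperm(arr, c(2, 1, 3))
  x <- matrix(arr, d[2], d[1] * d[3])
  x <- smooth_axis(x, d[2])
  arr <- aperm(array(x, c(d[2], d[1], d[3])), c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))
  x <- matrix(arr, d[3], d[2] * d[1])
  x <- smooth_axis(x, d[3])
  aperm(array(x, c(d[3], d[2], d[1])), c(3, 2, 1))
}

# axis-aligned ellipsoid mask over the full grid (voxel-center inclusion)
ellipsoid_mask <- function(dim, spacing, center_mm, semi_mm) {
  cx <- (seq_len(dim[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dim[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dim[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / semi_mm[3])^2
  xy <- outer(dx2, dy2, "+")
  arr <- array(0, dim)
  for (kk in seq_len(dim[3])) arr[, , kk] <- xy + dz2[kk]
  arr <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
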