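# Independent brute-force oracles, deliberately naive implementations that
# share no code path with the package internals.

# exhaustive nearest-feature Euclidean distance (mm between voxel centers)
oracle_edt <- function(mask, spacing) {
  spacing <- rep_len(spacing, 3L)
  ft <- which(mask, arr.ind = TRUE)
  if (nrow(ft) == 0) stop("no features")
  ftp <- sweep(ft - 0.5, 2, spacing, "*")
  d <- dim(mask)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  allp <- sweep(all_idx - 0.5, 2, spacing, "*")
  out <- numeric(nrow(allp))
  for (i in seq_len(nrow(allp))) {
    dx <- sweep(ftp, 2, allp[i, ])
    out[i] <- sqrt(min(rowSums(dx^2)))
  }
  array(out, d)
}

# flood-fill 26-connected labeling with an explicit queue
oracle_label_bfs <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    queue <- list(arrayInd(s, d)[1, ])
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (mask[qi] && lab[qi] == 0) {
          lab[qi] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# optimal transport between two histograms on a common support, as an
# explicit linear program over the full coupling matrix
oracle_wasserstein_lp <- function(h1, h2, bin_width) {
  n <- length(h1)
  h1 <- h1 / sum(h1)
  h2 <- h2 / sum(h2)
  cost <- as.vector(outer(seq_len(n), seq_len(n),
    function(i, j) abs(i - j) * bin_width))
  Aeq <- matrix(0, 2 * n, n * n)
  for (i in seq_len(n)) Aeq[i, ((i - 1) * n + 1):(i * n)] <- 1 # row sums
  for (j in seq_len(n)) Aeq[n + j, seq(j, n * n, by = n)] <- 1 # col sums
  # drop one redundant constraint so the LP is non-degenerate
  sol <- pracma::linprog(cost,
    Aeq = Aeq[-(2 * n), ], beq = c(h1, h2)[-(2 * n)],
    maxiter = 5000, maximize = FALSE
  )
  stopifnot(sol$errno == 1)
  sum(cost * sol$x)
}

# two-sided exact signed-rank p by full enumeration of sign assignments
oracle_wilcoxon_enum <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  p_le <- mean(W <= w + 1e-12)
  p_ge <- mean(W >= w - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# type-7 percentile computed from an explicit full sort
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# minimal cohort tibble (centroid-level) for targeted scenarios
make_cohort <- function(centroids_mm, dim, spacing_mm, site = "site1",
                        primary = "all", voxels = NULL) {
  n <- nrow(centroids_mm)
  if (is.null(voxels)) {
    idx <- mm_to_voxel_pub(centroids_mm, spacing_mm, dim)
    voxels <- lapply(seq_len(n), function(i) idx[i, , drop = FALSE])
  }
  co <- tibble::tibble(
    patient_id = seq_len(n), site = rep_len(site, n),
    primary = rep_len(primary, n), lesion_id = 1L,
    volume_cc_drawn = NA_real_,
    n_voxels = vapply(voxels, nrow, integer(1)),
    volume_cc = vapply(voxels, nrow, integer(1)) * spacing_mm^3 / 1000,
    centroid_x_mm = centroids_mm[, 1], centroid_y_mm = centroids_mm[, 2],
    centroid_z_mm = centroids_mm[, 3], voxels = voxels,
    overlap_forced = FALSE
  )
  attr(co, "grid_dim") <- as.integer(dim)
  attr(co, "spacing_mm") <- spacing_mm
  class(co) <- c("bm_cohort", class(co))
  co
}

mm_to_voxel_pub <- function(xyz, spacing_mm, dim) {
  idx <- floor(xyz / spacing_mm) + 1L
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1L), dim[a])
  storage.mode(idx) <- "integer"
  idx
}

# digitized ellipsoid voxel set for sphericity fixtures
ellipsoid_fixture <- function(semi, spacing) {
  n <- ceiling(2 * max(semi) / spacing) + 6
  cen <- rep(n / 2 * spacing, 3)
  grid <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  ctr <- (grid - 0.5) * spacing
  keep <- ((ctr[, 1] - cen[1]) / semi[1])^2 +
    ((ctr[, 2] - cen[2]) / semi[2])^2 +
    ((ctr[, 3] - cen[3]) / semi[3])^2 <= 1
  out <- grid[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
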