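test_that("connected-component extraction counts and measures lesions", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE
  m[8:10, 8:10, 8:10] <- TRUE
  les <- extract_lesions(volume3d(m, c(1, 1, 1)))
  expect_equal(nrow(les), 2)
  expect_equal(les$volume_cc, c(0.027, 0.027))

  # blocks touching only at a corner merge under 26-connectivity
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[5:7, 5:7, 5:7] <- TRUE
  les <- extract_lesions(volume3d(m, c(1, 1, 1)))
  expect_equal(nrow(les), 1)

  # empty mask
  les <- extract_lesions(volume3d(array(FALSE, c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(nrow(les), 0)
})

test_that("component labeling agrees with an independent BFS oracle", {
  set.seed(11)
  for (p in c(0.05, 0.2, 0.4)) {
    m <- array(runif(30^3) < p, c(30, 30, 30))
    lab <- label_components(volume3d(m, c(1, 1, 1)))
    ref <- oracle_label_bfs(m)
    expect_equal(max(lab), max(ref))
    # identical partitions: label images must match up to renaming
    expect_equal(length(unique(paste(lab[m], ref[m]))), max(ref))
  }
})

test_that("lesion volumes sum to the mask volume exactly", {
  set.seed(12)
  m <- array(runif(20^3) < 0.1, c(20, 20, 20))
  les <- extract_lesions(volume3d(m, c(2, 2, 2)))
  expect_equal(sum(les$volume_cc), sum(m) * 0.008)
  expect_equal(sum(les$n_voxels), sum(m))
})

test_that("sphericity closed forms hold", {
  one <- matrix(c(5L, 5L, 5L), ncol = 3)
  expect_equal(
    compute_sphericity(one, c(1, 1, 1), "voxel_faces"),
    (pi / 6)^(1 / 3),
    tolerance = 1e-12
  )

  # a digitized radius-10 sphere has near-unit mesh sphericity
  m <- ellipsoid_fixture(rep(10, 3), 1)
  psi <- compute_sphericity(m, c(1, 1, 1), "mesh")
  expect_gt(psi, 0.97)
  expect_lte(psi, 1)

  # elongation reduces voxel-face sphericity below the cube value
  rod <- cbind(3L, 3L, 3:22)
  expect_lt(
    compute_sphericity(rod, c(1, 1, 1), "voxel_faces"),
    (pi / 6)^(1 / 3)
  )
})

test_that("mesh sphericity is scale-invariant", {
  m <- ellipsoid_fixture(c(6, 4, 3), 1)
  a <- compute_sphericity(m, c(1, 1, 1), "mesh")
  b <- compute_sphericity(m, c(2.5, 2.5, 2.5), "mesh")
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("single-voxel lesions fall back from mesh with a warning", {
  one <- matrix(c(2L, 2L, 2L), ncol = 3)
  expect_warning(psi <- compute_sphericity(one, c(1, 1, 1), "mesh"),
    "voxel_faces")
  expect_equal(psi, (pi / 6)^(1 / 3), tolerance = 1e-12)
})

test_that("interface distance map is exact on a flat slab", {
  slab <- fix_slab(nz = 20, n = 8, spacing = 1, z_split = 10)
  dm <- interface_distance_map(slab$gray, slab$white)
  # interface voxels sit at z = 9 (white side) and z = 10 (gray side)
  expect_true(all(dm$distance[, , 9] == 0))
  expect_true(all(dm$distance[, , 10] == 0))
  for (k in 11:20) expect_true(all(dm$distance[, , k] == k - 10))
  for (k in 1:8) expect_true(all(dm$distance[, , k] == 9 - k))
  expect_true(all(dm$distance[dm$interface] == 0))
})

test_that("distance map equals the exhaustive oracle on random crops", {
  set.seed(21)
  for (i in 1:5) {
    d <- sample(8:20, 3, replace = TRUE)
    gray <- array(runif(prod(d)) < 0.2, d)
    white <- array(runif(prod(d)) < 0.2, d) & !gray
    sp <- sample(c(1, 2), 1)
    dm <- tryCatch(
      interface_distance_map(volume3d(gray, rep(sp, 3)),
        volume3d(white, rep(sp, 3))),
      error = function(e) NULL
    )
    if (is.null(dm)) next # no adjacency in this draw
    ref <- oracle_edt(as.array(dm$interface), rep(sp, 3))
    expect_equal(as.array(dm$distance), ref, tolerance = 1e-9)
  }
})

test_that("disjoint, non-adjacent tissues raise an interface error", {
  d <- c(8, 8, 8)
  gray <- array(FALSE, d)
  white <- array(FALSE, d)
  gray[, , 1] <- TRUE
  white[, , 5] <- TRUE
  expect_error(
    interface_distance_map(volume3d(gray, c(1, 1, 1)),
      volume3d(white, c(1, 1, 1))),
    "no interface"
  )
  gray2 <- gray
  gray2[, , 5] <- TRUE
  expect_error(
    interface_distance_map(volume3d(gray2, c(1, 1, 1)),
      volume3d(gray2, c(1, 1, 1))),
    "overlap"
  )
})

test_that("centroid interface distances use nearest-voxel sampling", {
  slab <- fix_slab(nz = 20, n = 8, spacing = 1, z_split = 10)
  dm <- interface_distance_map(slab$gray, slab$white)
  les <- tibble::tibble(
    centroid_x_mm = c(4, 4), centroid_y_mm = c(4, 4),
    centroid_z_mm = c(9.5, 14.5) # voxel centers z = 10 and z = 15
  )
  les <- lesion_interface_distance(les, dm)
  expect_equal(les$interface_distance_mm, c(0, 5))

  # random centroids match a direct indexing oracle
  set.seed(22)
  cen <- cbind(runif(100, 0.1, 7.9), runif(100, 0.1, 7.9),
    runif(100, 0.1, 19.9))
  got <- lesion_interface_distance(
    tibble::tibble(centroid_x_mm = cen[, 1], centroid_y_mm = cen[, 2],
      centroid_z_mm = cen[, 3]), dm)$interface_distance_mm
  ref <- vapply(seq_len(100), function(i) {
    idx <- pmin(pmax(floor(cen[i, ]) + 1, 1), dim(dm$distance))
    dm$distance[idx[1], idx[2], idx[3]]
  }, numeric(1))
  expect_equal(got, ref)
})

test_that("membership assignment applies the 5 mm background rescue", {
  atlas <- array(0L, c(20, 20, 20))
  atlas[2:6, 2:6, 2:6] <- 3L
  atlas[14:18, 14:18, 14:18] <- 7L
  av <- volume3d(atlas, c(1, 1, 1))
  les <- tibble::tibble(
    centroid_x_mm = c(3.5, 8.2, 10.5),
    centroid_y_mm = c(3.5, 15.1, 10.5),
    centroid_z_mm = c(3.5, 15.1, 10.5)
  )
  les <- assign_membership(les, av)
  expect_equal(les$region_label[1], 3L) # inside region 3
  expect_equal(les$region_label[2], 7L) # background, ~2.2 mm from region 7
  expect_true(is.na(les$region_label[3])) # > 5 mm from any label
})

test_that("lesion_metrics fills the full morphometric record", {
  ph <- fix_phantom()
  co <- fix_cohort()
  met <- suppressWarnings(lesion_metrics(co, ph, dmap = fix_dmap()))
  expect_true(all(c("sphericity", "interface_distance_mm", "coarse_label",
    "fine_label", "functional_label", "vascular_label") %in% names(met)))
  expect_true(all(met$sphericity > 0 & met$sphericity <= 1))
  expect_true(all(met$interface_distance_mm >= 0))
  expect_true(all(met$centroid_in_brain))
})

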