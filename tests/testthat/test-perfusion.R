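test_that("perfusion normalization maps the 99th percentile to 1", {
  d <- c(20, 20, 20)
  brain <- volume3d(array(TRUE, d), c(1, 1, 1))
  ramp <- volume3d(array(seq(0, 100, length.out = prod(d)), d), c(1, 1, 1))
  pn <- normalize_perfusion(ramp, brain)
  expect_equal(max(pn), 1)
  p99 <- quantile(as.vector(ramp), 0.99, names = FALSE)
  expect_equal(sum(pn == 1), sum(ramp >= p99))
  below <- ramp < p99
  expect_equal(as.vector(pn)[below], as.vector(ramp)[below] / p99,
    tolerance = 1e-12)

  # already-normalized map with its maximum at the 99th percentile
  v <- as.array(ramp) / p99
  v[v > 1] <- 1
  pn2 <- normalize_perfusion(volume3d(v, c(1, 1, 1)), brain)
  expect_equal(as.array(pn2), v, tolerance = 1e-4)

  expect_error(
    normalize_perfusion(volume3d(array(3, d), c(1, 1, 1)), brain),
    "constant"
  )
})

test_that("normalization percentile equals a full-sort oracle", {
  ph <- fix_phantom()
  pn <- normalize_perfusion(ph$perfusion, ph$brain_mask)
  p99 <- oracle_percentile(ph$perfusion[ph$brain_mask], 0.99)
  ref <- pmin(as.array(ph$perfusion) / p99, 1)
  ref[!ph$brain_mask] <- 0
  expect_equal(as.array(pn), ref, tolerance = 1e-12)
})

test_that("subspace fraction has its boundary values and matches a per-voxel scan", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  pn <- normalize_perfusion(ph$perfusion, ph$brain_mask)
  co <- fix_cohort()

  # the full space always contains everything
  expect_equal(
    subspace_fraction(co, pn, dm, p_range = c(0, 1), d_max_mm = Inf)$fraction,
    1
  )

  # exhaustive oracle over all lesion voxels
  sf <- subspace_fraction(co, pn, dm)
  hits <- 0
  tot <- 0
  for (v in co$voxels) {
    for (r in seq_len(nrow(v))) {
      p <- pn[v[r, 1], v[r, 2], v[r, 3]]
      dd <- dm$distance[v[r, 1], v[r, 2], v[r, 3]]
      hits <- hits + (p >= 0.6 && p <= 0.95 && dd <= 5)
      tot <- tot + 1
    }
  }
  expect_equal(sf$fraction, hits / tot)
  expect_equal(sf$n_units, tot)

  # a cohort constructed entirely inside the subspace scores 1
  ok <- which(pn >= 0.7 & pn <= 0.9 & dm$distance <= 3 & ph$brain_mask)
  idx <- arrayInd(ok[seq(1, length(ok), length.out = 10)], ph$shape)
  co1 <- make_cohort((idx - 0.5) * ph$spacing_mm, ph$shape, ph$spacing_mm)
  expect_equal(subspace_fraction(co1, pn, dm)$fraction, 1)
})

test_that("subspace fraction is monotone in its bounds", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  pn <- normalize_perfusion(ph$perfusion, ph$brain_mask)
  co <- fix_cohort()
  f1 <- subspace_fraction(co, pn, dm, d_max_mm = 2)$fraction
  f2 <- subspace_fraction(co, pn, dm, d_max_mm = 5)$fraction
  f3 <- subspace_fraction(co, pn, dm, d_max_mm = 10)$fraction
  expect_true(f1 <= f2 && f2 <= f3)
  g1 <- subspace_fraction(co, pn, dm, p_range = c(0.65, 0.9))$fraction
  g2 <- subspace_fraction(co, pn, dm, p_range = c(0.6, 0.95))$fraction
  g3 <- subspace_fraction(co, pn, dm, p_range = c(0.4, 1))$fraction
  expect_true(g1 <= g2 && g2 <= g3)
})

test_that("joint histograms conserve brain and lesion volume exactly", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  pn <- normalize_perfusion(ph$perfusion, ph$brain_mask)
  co <- fix_cohort()
  rmap <- accumulate(co)
  jh <- perfusion_joint_histograms(rmap, pn, dm, ph$brain_mask)
  expect_equal(sum(jh$count_hist$n_voxels), sum(ph$brain_mask))
  expect_equal(sum(jh$volume_hist$n_lesion_voxels),
    sum(as.vector(rmap$counts)[which(ph$brain_mask)]))
})

test_that("perfusion-seeded cohorts show a positive density-perfusion trend", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  co <- simulate_cohort(ph,
    sim_config(seed = 41, n_patients = 400, tau_mm = Inf, gamma = 2,
      render = "centroid"),
    dmap = dm)
  dv <- density_vs_perfusion_by_region(co, ph)
  expect_gt(attr(dv, "spearman_rho"), 0.3)
})

test_that("without perfusion seeding the trend vanishes on average", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  rhos <- vapply(1:15, function(r) {
    co <- simulate_cohort(ph,
      sim_config(seed = 600 + r, n_patients = 400, tau_mm = Inf, gamma = 0,
        render = "centroid"),
      dmap = dm)
    attr(density_vs_perfusion_by_region(co, ph), "spearman_rho")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
})

test_that("an enriched low-perfusion region stands out above the trend", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  co <- simulate_cohort(ph,
    sim_config(seed = 43, n_patients = 400, tau_mm = Inf, gamma = 1,
      multipliers = c(brainstem = 3), render = "centroid"),
    dmap = dm)
  dv <- density_vs_perfusion_by_region(co, ph)
  bs <- dv[dv$region == "brainstem", ]
  expect_gt(bs$density, 1.5) # enriched by construction
  expect_lt(bs$mean_perfusion, median(dv$mean_perfusion)) # despite low perfusion
})
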