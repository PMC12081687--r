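test_that("accumulation reproduces single- and repeated-lesion cases", {
  d <- c(20, 20, 20)
  vx <- as.matrix(expand.grid(5:7, 5:7, 5:7))
  storage.mode(vx) <- "integer"
  co1 <- make_cohort(matrix(c(11, 11, 11), 1), d, 2, voxels = list(vx))
  rm1 <- accumulate(co1)
  expect_equal(rm1$c_max, 1)
  expect_equal(sum(rm1$counts), nrow(vx))
  expect_true(all(rm1$counts[vx] == 1)) # counts equal the lesion mask

  # two patients with identical masks double the counts
  co2 <- make_cohort(matrix(c(11, 11, 11, 11, 11, 11), 2, byrow = TRUE),
    d, 2, voxels = list(vx, vx))
  rm2 <- accumulate(co2)
  expect_equal(rm2$c_max, 2)
  expect_true(all(rm2$counts[vx] == 2))
  expect_equal(sum(rm2$counts), 2 * nrow(vx))
})

test_that("accumulation conserves lesion voxels, additively and permutation-invariantly", {
  co <- fix_cohort()
  rmap <- accumulate(co)
  # independent tally straight off the lesion list
  expect_equal(rmap$total_lesion_voxels, sum(vapply(co$voxels, nrow,
    integer(1))))
  expect_equal(sum(rmap$counts), rmap$total_lesion_voxels)
  expect_equal(rmap$c_max, max(rmap$counts))
  expect_equal(rmap$n_lesions, nrow(co))

  # per-site maps sum to the total
  tot <- Reduce(`+`, lapply(rmap$per_site, as.array))
  expect_equal(tot, as.array(rmap$counts))

  # permutation invariance
  set.seed(5)
  perm <- co[sample(nrow(co)), ]
  expect_equal(as.array(accumulate(perm)$counts), as.array(rmap$counts))

  # additivity over disjoint patient sets
  a <- co[co$patient_id <= 30, ]
  b <- co[co$patient_id > 30, ]
  expect_equal(
    as.array(accumulate(a)$counts) + as.array(accumulate(b)$counts),
    as.array(rmap$counts)
  )
})

test_that("off-grid lesions are rejected with a named error", {
  d <- c(10, 10, 10)
  bad <- matrix(c(11L, 2L, 2L), 1)
  co <- make_cohort(matrix(c(5, 5, 5), 1), d, 2, voxels = list(bad))
  expect_error(accumulate(co), "patient 1, lesion 1")
})

test_that("regional contributions sum to 100 over assigned lesions", {
  ph <- fix_phantom()
  rc <- region_contribution(fix_cohort(), ph)
  expect_equal(sum(rc$percent), 100, tolerance = 1e-9)
  expect_true(all(rc$density >= 0))
  expect_true(all(rc$site_mean >= rc$ci_low | is.na(rc$ci_low)))
  expect_true(all(rc$site_mean <= rc$ci_high | is.na(rc$ci_high)))
  # ventricles carry no parenchyma and are excluded, not silently dropped
  expect_true(all(grepl("ventricle", attr(rc, "excluded_regions"))))
})

test_that("a single-region cohort contributes 100% to that region", {
  ph <- fix_phantom()
  # centroids all inside the left frontal lobe
  lab <- which(ph$atlas_coarse == 1L & phantom_parenchyma(ph))
  idx <- arrayInd(lab[seq(1, length(lab), length.out = 20)], ph$shape)
  cen <- (idx - 0.5) * ph$spacing_mm
  co <- make_cohort(cen, ph$shape, ph$spacing_mm,
    site = rep(paste0("site", 1:4), 5))
  rc <- region_contribution(co, ph)
  expect_equal(rc$percent[rc$label == 1], 100)
  expect_true(all(rc$percent[rc$label != 1] == 0))
})

test_that("margin-0 expansion reproduces the plain regional statistics", {
  ph <- fix_phantom()
  co <- fix_cohort()
  plain <- region_contribution(co, ph)
  exp0 <- expansion_sensitivity(co, ph, margins_mm = 0)
  expect_equal(exp0$percent, plain$percent)
  expect_equal(exp0$lesion_count, plain$lesion_count)
})

test_that("label expansion resolves overlaps to the nearest region", {
  atlas <- array(0L, c(24, 12, 12))
  atlas[4, 6, 6] <- 1L
  atlas[14, 6, 6] <- 2L
  av <- volume3d(atlas, c(1, 1, 1))
  ex <- expand_labels(av, 20)
  # midpoints resolve by proximity to the original seeds
  expect_equal(ex[8, 6, 6], 1L)
  expect_equal(ex[11, 6, 6], 2L)
  # beyond the margin nothing is labeled
  ex5 <- expand_labels(av, 5)
  expect_equal(ex5[24, 6, 6], 0L)
  # oracle: exhaustive nearest-seed assignment within the margin
  ref_d1 <- oracle_edt(atlas == 1L, c(1, 1, 1))
  ref_d2 <- oracle_edt(atlas == 2L, c(1, 1, 1))
  ref <- ifelse(pmin(ref_d1, ref_d2) > 5, 0L, ifelse(ref_d1 <= ref_d2, 1L, 2L))
  ties <- abs(ref_d1 - ref_d2) < 1e-9 & pmin(ref_d1, ref_d2) <= 5
  expect_equal(as.vector(ex5)[!ties], as.vector(ref)[!ties])
})

test_that("laterality comparison is null for mirrored cohorts and extreme for one-sided ones", {
  ph <- fix_phantom()
  lab <- which(ph$atlas_coarse == 1L & phantom_parenchyma(ph))
  idx <- arrayInd(lab[seq(1, length(lab), length.out = 16)], ph$shape)
  cen_l <- (idx - 0.5) * ph$spacing_mm
  cen_r <- cen_l
  cen_r[, 1] <- ph$shape[1] * ph$spacing_mm - cen_l[, 1] # mirror in x
  cen <- rbind(cen_l, cen_r)
  co <- make_cohort(cen, ph$shape, ph$spacing_mm,
    site = rep(paste0("site", 1:4), 8))
  lat <- laterality_compare(co, ph)
  fr <- lat[lat$pair == "frontal", ]
  expect_equal(fr$left_pct, fr$right_pct)
  expect_equal(fr$p_value, 1)

  # all-left cohort
  co_l <- make_cohort(cen_l, ph$shape, ph$spacing_mm,
    site = rep(paste0("site", 1:4), 4))
  lat_l <- laterality_compare(co_l, ph)
  fr_l <- lat_l[lat_l$pair == "frontal", ]
  expect_equal(fr_l$left_pct, 100)
  expect_equal(fr_l$right_pct, 0)
})

test_that("riskmap tidiers expose provenance", {
  rmap <- accumulate(fix_cohort())
  g <- generics::glance(rmap)
  expect_equal(g$n_lesions, nrow(fix_cohort()))
  td <- generics::tidy(rmap)
  expect_equal(sum(td$count), rmap$total_lesion_voxels)
  expect_true(all(td$count >= 1))
})
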