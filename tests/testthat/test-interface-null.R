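test_that("observed histogram bins centroid distances correctly", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  edges <- seq(0, 10, 0.5)

  # all centroids on the interface: all mass in the first bin
  iface <- which(dm$interface)
  idx <- arrayInd(iface[seq(1, length(iface), length.out = 12)], ph$shape)
  co <- make_cohort((idx - 0.5) * ph$spacing_mm, ph$shape, ph$spacing_mm)
  h <- observed_histogram(co, ph, dm, edges = edges)
  expect_equal(h$observed_fraction[1], 1)
  expect_equal(sum(h$observed_fraction), 1, tolerance = 1e-9)

  # hand-placed fractional distances (1.2 and 3.6 mm on a 0.6 mm grid)
  # land in their own bins with fraction 1/2 each
  slab <- fix_slab(nz = 24, n = 8, spacing = 0.6, z_split = 10)
  dms <- interface_distance_map(slab$gray, slab$white)
  fake_ph <- structure(list(
    gray_mask = slab$gray, white_mask = slab$white,
    spacing_mm = 0.6, shape = dim(slab$gray)
  ), class = "bm_phantom")
  co2 <- make_cohort(
    cbind(c(2, 2), c(2, 2), c(6.9, 9.3)), # voxel centers z = 12 and 16
    dim(slab$gray), 0.6
  )
  h2 <- observed_histogram(co2, fake_ph, dms, edges = seq(0, 8, 0.5))
  expect_equal(h2$observed_fraction[h2$bin_start == 1], 0.5) # 1.2 mm
  expect_equal(h2$observed_fraction[h2$bin_start == 3.5], 0.5) # 3.6 mm
  expect_equal(sum(h2$observed_fraction), 1)
})

test_that("observed histogram equals a direct tally oracle", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  co <- fix_cohort()
  edges <- interface_bins(ph, dm)
  h <- observed_histogram(co, ph, dm, edges = edges)
  d <- lesion_interface_distance(co, dm)$interface_distance_mm
  for (b in seq_len(nrow(h))) {
    lo <- h$bin_start[b]
    hi <- h$bin_end[b]
    n_ref <- if (b < nrow(h)) sum(d >= lo & d < hi) else sum(d >= lo)
    expect_equal(h$observed_fraction[b], n_ref / length(d))
  }
  expect_equal(sum(h$observed_count), length(d))
})

test_that("null histogram is the parenchymal volume distribution", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  edges <- interface_bins(ph, dm)
  h <- null_histogram(ph, dm, edges = edges)
  expect_equal(sum(h$null_fraction), 1, tolerance = 1e-9)
  # exhaustive recount oracle
  par <- which(phantom_parenchyma(ph))
  d <- as.vector(dm$distance)[par]
  for (b in c(1, 5, nrow(h))) {
    lo <- h$bin_start[b]
    hi <- h$bin_end[b]
    n_ref <- if (b < nrow(h)) sum(d >= lo & d < hi) else sum(d >= lo)
    expect_equal(h$null_fraction[b], n_ref / length(d))
  }

  # slab geometry: uniform null over the gray-side bins
  slab <- fix_slab(nz = 22, n = 10, spacing = 1, z_split = 11)
  fake_ph <- structure(list(
    gray_mask = slab$gray, white_mask = slab$white,
    spacing_mm = 1, shape = dim(slab$gray)
  ), class = "bm_phantom")
  dms <- interface_distance_map(slab$gray, slab$white)
  hn <- null_histogram(fake_ph, dms, edges = seq(0, 10, 1))
  # distances on the slab take each integer value on whole planes;
  # interior bins away from the two zero-planes hold equal volume
  mid <- hn$null_fraction[2:9]
  expect_true(max(mid) - min(mid) < 1e-12)
})

test_that("comparison read-outs have their closed-form values", {
  n <- 20
  tb <- function(f) tibble::tibble(
    bin_start = seq(0, by = 0.5, length.out = n),
    bin_end = seq(0.5, by = 0.5, length.out = n),
    null_fraction = f
  )
  f <- rep(1 / n, n)
  obs <- tb(f)
  names(obs)[3] <- "observed_fraction"
  obs$observed_count <- as.integer(f * 1000)
  cmp <- compare_to_null(obs, tb(f))
  expect_equal(cmp$wasserstein_mm, 0)
  expect_equal(cmp$over_representation_pct, 0)

  # point masses at 2 mm vs 5 mm: pure translation
  o2 <- tb(rep(0, n))
  names(o2)[3] <- "observed_fraction"
  o2$observed_fraction[o2$bin_start == 2] <- 1
  o2$observed_count <- as.integer(o2$observed_fraction * 50)
  n5 <- tb(rep(0, n))
  n5$null_fraction[n5$bin_start == 5] <- 1
  cmp2 <- compare_to_null(o2, n5)
  expect_equal(cmp2$wasserstein_mm, 3)
  expect_equal(cmp2$over_representation_pct, 100)

  # mismatched binnings are rejected
  bad <- tb(f)
  bad$bin_start <- bad$bin_start + 0.25
  expect_error(compare_to_null(obs, bad), "different binnings")
})

test_that("the lesion-paired Wilcoxon detects interface bias", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  edges <- interface_bins(ph, dm)
  nul <- null_histogram(ph, dm, edges = edges)
  co <- simulate_cohort(ph,
    sim_config(seed = 19, n_patients = 150, tau_mm = 3, gamma = 0,
      render = "centroid"),
    dmap = dm)
  obs <- observed_histogram(co, ph, dm, edges = edges)
  cmp <- compare_to_null(obs, nul)
  expect_lt(cmp$wilcoxon_p, 0.01)
  expect_gt(cmp$over_representation_pct, 10)
  expect_gt(cmp$wasserstein_mm, 1)
})

test_that("within-5mm concentration decreases with the decay length tau", {
  ph <- fix_phantom()
  dm <- fix_dmap()
  edges <- interface_bins(ph, dm)
  fr <- vapply(c(2, 6, 30), function(tau) {
    co <- simulate_cohort(ph,
      sim_config(seed = 23, n_patients = 250, tau_mm = tau, gamma = 0,
        render = "centroid"),
      dmap = dm)
    obs <- observed_histogram(co, ph, dm, edges = edges)
    compare_to_null(obs, null_histogram(ph, dm, edges = edges))$
      frac_within_landmark
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("degenerate comparisons warn and return NA p-values", {
  n <- 8
  obs <- tibble::tibble(
    bin_start = seq(0, by = 0.5, length.out = n),
    bin_end = seq(0.5, by = 0.5, length.out = n),
    observed_count = c(2L, 1L, rep(0L, n - 2)),
    observed_fraction = c(2, 1, rep(0, n - 2)) / 3
  )
  nul <- obs[, c("bin_start", "bin_end")]
  nul$null_fraction <- obs$observed_fraction
  expect_warning(cmp <- compare_to_null(obs, nul), "fewer than 6|zero")
  expect_true(is.na(cmp$wilcoxon_p))
  expect_equal(cmp$wasserstein_mm, 0)
})

test_that("empty cohorts are rejected", {
  ph <- fix_phantom()
  co <- fix_cohort()[0, ]
  expect_error(observed_histogram(co, ph, fix_dmap()), "empty cohort")
})
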