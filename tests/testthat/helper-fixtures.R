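# shared fixtures, built once per test run
.fix <- new.env()

fix_phantom <- function() {
  if (is.null(.fix$ph)) {
    .fix$ph <- build_phantom(spacing_mm = 2, shape = c(72, 72, 72), seed = 42)
  }
  .fix$ph
}

fix_dmap <- function() {
  if (is.null(.fix$dm)) {
    ph <- fix_phantom()
    .fix$dm <- interface_distance_map(ph$gray_mask, ph$white_mask)
  }
  .fix$dm
}

fix_cohort <- function() {
  if (is.null(.fix$co)) {
    .fix$co <- simulate_cohort(fix_phantom(),
      sim_config(seed = 7, n_patients = 60), dmap = fix_dmap())
  }
  .fix$co
}

# full-size phantom for the acceptance suite (default construction)
fix_phantom_full <- function() {
  if (is.null(.fix$phf)) .fix$phf <- build_phantom()
  .fix$phf
}

fix_dmap_full <- function() {
  if (is.null(.fix$dmf)) {
    ph <- fix_phantom_full()
    .fix$dmf <- interface_distance_map(ph$gray_mask, ph$white_mask)
  }
  .fix$dmf
}

# a small slab "phantom" (flat interface) for closed-form geometry checks
fix_slab <- function(nz = 20, n = 12, spacing = 1, z_split = 10) {
  d <- c(n, n, nz)
  gray <- array(FALSE, d)
  white <- array(FALSE, d)
  white[, , seq_len(z_split - 1)] <- TRUE
  gray[, , z_split:nz] <- TRUE
  list(
    gray = volume3d(gray, rep(spacing, 3)),
    white = volume3d(white, rep(spacing, 3))
  )
}
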