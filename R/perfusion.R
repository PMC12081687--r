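#' Normalize a perfusion map to \[0, 1\]
#'
#' Divides by the 99th percentile of in-brain values and clips to \[0, 1\];
#' percentile scaling is robust to the hot-spot outliers typical of
#' arterial-spin-labeling maps.
#'
#' @param raw Non-negative `volume3d`.
#' @param brain_mask Logical `volume3d` on the same grid.
#' @return A `volume3d` in \[0, 1\] (zero outside the brain).
#' @export
normalize_perfusion <- function(raw, brain_mask) {
  stopifnot_same_grid(raw, brain_mask)
  vals <- raw[brain_mask]
  if (any(vals < 0)) stop("perfusion map has negative values", call. = FALSE)
  if (diff(range(vals)) == 0) {
    stop("perfusion is constant within the brain; normalization undefined",
      call. = FALSE
    )
  }
  p99 <- quantile(vals, 0.99, names = FALSE)
  out <- pmin(pmax(as.array(raw) / p99, 0), 1)
  out[!brain_mask] <- 0
  volume3d(out, vox_spacing(raw), vox_origin(raw))
}

#' Lesion-volume fraction inside a perfusion-distance subspace
#'
#' Fraction of total lesion volume (voxel-weighted; or of lesions, by
#' centroid) whose normalized perfusion lies in `p_range` *and* whose
#' distance to the gray-white interface is at most `d_max_mm`. The
#' volume-weighted default matches claims about where metastasis *volume*
#' resides; the centroid variant is exposed for comparison.
#'
#' @param cohort A `bm_cohort`.
#' @param perfusion_norm Output of [normalize_perfusion()].
#' @param dmap A [interface_distance_map()].
#' @param p_range Closed perfusion interval.
#' @param d_max_mm Distance bound (mm); `Inf` disables it.
#' @param mode `"volume"` (per lesion voxel) or `"centroid"` (per lesion).
#' @return One-row tibble: `fraction`, `n_units` (voxels or lesions).
#' @export
subspace_fraction <- function(cohort, perfusion_norm, dmap,
                              p_range = c(0.6, 0.95), d_max_mm = 5,
                              mode = c("volume", "centroid")) {
  mode <- match.arg(mode)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  stopifnot_same_grid(perfusion_norm, dmap$distance)
  dims <- dim(perfusion_norm)
  if (mode == "volume") {
    lin <- unlist(lapply(cohort$voxels, voxel_linear, dim = dims))
  } else {
    cen <- as.matrix(cohort[, c("centroid_x_mm", "centroid_y_mm",
      "centroid_z_mm")])
    lin <- voxel_linear(mm_to_voxel(cen, vox_spacing(perfusion_norm), dims),
      dims)
  }
  p <- as.vector(perfusion_norm)[lin]
  d <- as.vector(dmap$distance)[lin]
  inside <- p >= p_range[1] & p <= p_range[2] & d <= d_max_mm
  tibble::tibble(fraction = mean(inside), n_units = length(lin))
}

#' Joint histograms of perfusion against lesion burden and distance
#'
#' Two 2-D histograms: brain-volume-weighted counts of (normalized
#' perfusion bin, lesions per voxel), and lesion-volume-weighted counts of
#' (normalized perfusion bin, interface distance bin). Both conserve their
#' totals exactly (brain voxel count, lesion voxel count).
#'
#' @param riskmap A `bm_riskmap`.
#' @param perfusion_norm,dmap As in [subspace_fraction()].
#' @param brain_mask Logical `volume3d`.
#' @param p_bins,d_bins Bin edges for perfusion and distance (mm).
#' @return List of two tibbles, `count_hist` (`perfusion_bin`,
#'   `lesion_count`, `brain_cc`) and `volume_hist` (`perfusion_bin`,
#'   `distance_bin`, `lesion_cc`).
#' @export
perfusion_joint_histograms <- function(riskmap, perfusion_norm, dmap,
                                       brain_mask,
                                       p_bins = seq(0, 1, 0.05),
                                       d_bins = NULL) {
  stopifnot_same_grid(perfusion_norm, riskmap$counts)
  vv <- voxel_volume_cc(perfusion_norm)
  inb <- which(brain_mask)
  p <- as.vector(perfusion_norm)[inb]
  cnt <- as.vector(riskmap$counts)[inb]
  pb <- pmax(pmin(findInterval(p, p_bins, rightmost.closed = TRUE),
    length(p_bins) - 1), 1)
  count_hist <- dplyr::count(
    tibble::tibble(
      perfusion_bin = p_bins[pb], lesion_count = cnt
    ),
    .data$perfusion_bin, .data$lesion_count, name = "n_voxels"
  )
  count_hist$brain_cc <- count_hist$n_voxels * vv

  d <- as.vector(dmap$distance)[inb]
  d_bins <- d_bins %||% seq(0, ceiling(max(d[cnt > 0], 1)), by = 1)
  les <- cnt > 0
  db <- pmax(pmin(findInterval(d[les], d_bins, rightmost.closed = TRUE),
    length(d_bins) - 1), 1)
  volume_hist <- dplyr::count(
    tibble::tibble(
      perfusion_bin = p_bins[pb[les]], distance_bin = d_bins[db],
      w = cnt[les]
    ),
    .data$perfusion_bin, .data$distance_bin,
    wt = .data$w, name = "n_lesion_voxels"
  )
  volume_hist$lesion_cc <- volume_hist$n_lesion_voxels * vv
  list(count_hist = count_hist, volume_hist = volume_hist)
}

#' Regional density against mean regional perfusion
#'
#' Per region: the parenchyma-volume-weighted mean normalized perfusion and
#' the density enrichment ratio from [region_contribution()], with the
#' Spearman rank correlation across regions attached as attribute
#' `spearman_rho` (and returned by `glance` on the result via the
#' attribute).
#'
#' @param cohort,phantom,atlas As in [region_contribution()].
#' @return Tibble `region`, `label`, `mean_perfusion`, `density`,
#'   `percent`; attribute `spearman_rho`.
#' @export
density_vs_perfusion_by_region <- function(cohort, phantom,
                                           atlas = "coarse") {
  rc <- region_contribution(cohort, phantom, atlas)
  pn <- normalize_perfusion(phantom$perfusion, phantom$brain_mask)
  av <- as.vector(phantom[[paste0("atlas_", atlas)]])
  par <- which(phantom_parenchyma(phantom))
  labs <- av[par]
  pvals <- as.vector(pn)[par]
  mp <- vapply(rc$label, function(lb) mean(pvals[labs == lb]), numeric(1))
  out <- tibble::tibble(
    region = rc$region, label = rc$label, mean_perfusion = mp,
    density = rc$density, percent = rc$percent
  )
  attr(out, "spearman_rho") <-
    cor(out$mean_perfusion, out$density, method = "spearman")
  out
}
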