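#' Accumulate a cohort into a voxelwise risk map
#'
#' The risk map is the cumulative lesion count per voxel over all patients
#' and lesions: `C(x) = sum_i sum_l [x in lesion_il]`, on the common atlas
#' grid (patient-to-atlas transforms are applied upstream; lesions here are
#' already in atlas space). Per-site maps are kept alongside and sum
#' voxelwise to the total.
#'
#' @param cohort A `bm_cohort` (or any lesion tibble with `voxels`, `site`,
#'   `patient_id` and grid attributes).
#' @return A `bm_riskmap`: list with `counts` (integer `volume3d`),
#'   `n_patients`, `n_lesions`, `c_max`, `total_lesion_voxels` and
#'   `per_site` (named list of integer `volume3d`).
#' @export
accumulate <- function(cohort) {
  g <- cohort_grid(cohort)
  if (is.null(g$dim)) stop("cohort carries no grid attributes", call. = FALSE)
  nvox <- prod(g$dim)
  for (j in seq_len(nrow(cohort))) {
    v <- cohort$voxels[[j]]
    if (any(v < 1) || any(v > matrix(g$dim, nrow(v), 3, byrow = TRUE))) {
      stop("lesion off grid: patient ", cohort$patient_id[j], ", lesion ",
        cohort$lesion_id[j],
        call. = FALSE
      )
    }
  }
  site_of <- split(seq_len(nrow(cohort)), cohort$site)
  per_site <- lapply(site_of, function(rows) {
    lin <- unlist(lapply(cohort$voxels[rows], voxel_linear, dim = g$dim))
    array(tabulate(lin, nbins = nvox), g$dim)
  })
  total <- Reduce(`+`, per_site)
  structure(
    list(
      counts = volume3d(array(as.integer(total), g$dim), g$spacing),
      n_patients = length(unique(cohort$patient_id)),
      n_lesions = nrow(cohort),
      c_max = max(total),
      total_lesion_voxels = sum(total),
      per_site = lapply(per_site, function(a) {
        volume3d(array(as.integer(a), g$dim), g$spacing)
      })
    ),
    class = "bm_riskmap"
  )
}

#' @export
print.bm_riskmap <- function(x, ...) {
  cat(sprintf(
    "<bm_riskmap> N=%d patients, L=%d lesions, C_max=%d, %d lesion voxels, %d site map(s)\n",
    x$n_patients, x$n_lesions, x$c_max, x$total_lesion_voxels,
    length(x$per_site)
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.bm_riskmap <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients, n_lesions = x$n_lesions, c_max = x$c_max,
    total_lesion_voxels = x$total_lesion_voxels,
    n_sites = length(x$per_site)
  )
}

#' @exportS3Method generics::tidy
tidy.bm_riskmap <- function(x, ...) {
  idx <- which(x$counts > 0)
  co <- arrayInd(idx, dim(x$counts))
  tibble::tibble(
    i = co[, 1], j = co[, 2], k = co[, 3],
    count = as.integer(x$counts[idx])
  )
}

#' Regional contribution and density statistics
#'
#' Assigns every lesion to one region by centroid membership, then reports
#' per region: the lesion count, the percent contribution (percentages over
#' assigned lesions sum to 100), the density enrichment ratio (percent
#' contribution divided by the region's percent share of seedable
#' parenchymal volume; 1 under uniform seeding), the per-site mean and its
#' 95% t confidence interval over sites. Unassigned lesions are excluded
#' from the 100% denominator and reported via the `n_unassigned` attribute;
#' regions with zero parenchymal volume (the ventricles) are excluded and
#' listed in the `excluded_regions` attribute.
#'
#' @param cohort A `bm_cohort`.
#' @param phantom A `bm_phantom`.
#' @param atlas `"coarse"`, `"fine"`, `"functional"` or `"vascular"`.
#' @param atlas_vol,region_table Override the phantom atlas (e.g. an
#'   expanded one); both must be given together.
#' @return A `bm_region_stats` tibble: `atlas`, `label`, `region`,
#'   `lesion_count`, `percent`, `density`, `site_mean`, `ci_low`, `ci_high`.
#' @export
region_contribution <- function(cohort, phantom, atlas = "coarse",
                                atlas_vol = NULL, region_table = NULL) {
  atlas_vol <- atlas_vol %||% phantom[[paste0("atlas_", atlas)]]
  region_table <- region_table %||%
    phantom$region_table[phantom$region_table$atlas == atlas, ]
  lesions <- assign_membership(cohort, atlas_vol, column = ".region")
  keep_tb <- region_table[region_table$parenchyma_cc > 0, ]
  excluded <- region_table$name[region_table$parenchyma_cc == 0]
  assigned <- lesions[!is.na(lesions$.region) &
    lesions$.region %in% keep_tb$label, ]
  n_unassigned <- nrow(lesions) - nrow(assigned)
  total <- nrow(assigned)
  if (total == 0) stop("no lesions could be assigned to any region",
    call. = FALSE)
  vol_share <- keep_tb$parenchyma_cc / sum(keep_tb$parenchyma_cc)

  sites <- sort(unique(assigned$site))
  per_site_n <- table(factor(assigned$site, levels = sites))
  stats <- purrr::map_dfr(seq_len(nrow(keep_tb)), function(r) {
    lb <- keep_tb$label[r]
    in_r <- assigned$.region == lb
    cnt <- sum(in_r)
    site_pct <- vapply(sites, function(s) {
      100 * sum(in_r & assigned$site == s) / max(1, per_site_n[[s]])
    }, numeric(1))
    ci <- if (length(sites) >= 2) ci95_over_sites(site_pct) else
      tibble::tibble(mean = mean(site_pct), low = NA_real_, high = NA_real_)
    tibble::tibble(
      label = lb, region = keep_tb$name[r], lesion_count = cnt,
      percent = 100 * cnt / total,
      density = (cnt / total) / vol_share[r],
      site_mean = ci$mean, ci_low = ci$low, ci_high = ci$high
    )
  })
  stats <- tibble::add_column(stats, atlas = atlas, .before = 1)
  attr(stats, "n_unassigned") <- n_unassigned
  attr(stats, "excluded_regions") <- excluded
  attr(stats, "site_levels") <- sites
  class(stats) <- c("bm_region_stats", class(stats))
  stats
}

#' Margin-expansion sensitivity of regional statistics
#'
#' Re-runs [region_contribution()] after expanding every atlas label
#' isotropically by each margin (Euclidean, in mm; overlapping expansions
#' resolve to the nearest original region), to probe how sensitive the
#' regional ranking is to boundary placement and mapping error.
#'
#' @param cohort,phantom,atlas As in [region_contribution()].
#' @param margins_mm Expansion margins; 0 reproduces the unexpanded stats.
#' @return Row-bound `bm_region_stats` with a `margin_mm` column.
#' @export
expansion_sensitivity <- function(cohort, phantom, atlas = "coarse",
                                  margins_mm = c(5, 10)) {
  stopifnot(all(margins_mm >= 0))
  region_table <- phantom$region_table[phantom$region_table$atlas == atlas, ]
  purrr::map_dfr(margins_mm, function(m) {
    av <- expand_labels(phantom[[paste0("atlas_", atlas)]], m)
    st <- region_contribution(cohort, phantom, atlas,
      atlas_vol = av, region_table = region_table)
    tibble::add_column(st, margin_mm = m, .before = 1)
  })
}

#' Laterality comparison of mirrored region pairs
#'
#' For every left/right partner pair in the region table, compares the
#' per-site percent contributions of the two sides with a two-tailed Welch
#' t test across sites.
#'
#' @param cohort,phantom,atlas As in [region_contribution()].
#' @param adjust Apply Benjamini-Hochberg adjustment across pairs (off by
#'   default; raw p-values are reported either way).
#' @return Tibble with one row per pair: region base name, left/right
#'   percent, `statistic`, `p_value` (and `p_adjusted` if requested).
#' @export
laterality_compare <- function(cohort, phantom, atlas = "coarse",
                               adjust = FALSE) {
  region_table <- phantom$region_table[phantom$region_table$atlas == atlas, ]
  lesions <- assign_membership(cohort, phantom[[paste0("atlas_", atlas)]],
    column = ".region")
  assigned <- lesions[!is.na(lesions$.region), ]
  sites <- sort(unique(assigned$site))
  per_site_n <- table(factor(assigned$site, levels = sites))
  site_pct <- function(lb) {
    vapply(sites, function(s) {
      100 * sum(assigned$.region == lb & assigned$site == s) /
        max(1, per_site_n[[s]])
    }, numeric(1))
  }
  paired <- region_table[!is.na(region_table$partner) &
    region_table$label < region_table$partner, ]
  out <- purrr::map_dfr(seq_len(nrow(paired)), function(r) {
    l_lab <- paired$label[r]
    r_lab <- paired$partner[r]
    lp <- site_pct(l_lab)
    rp <- site_pct(r_lab)
    tt <- tryCatch(welch_t_test(lp, rp),
      error = function(e) tibble::tibble(estimate = 0, statistic = NA_real_,
        df = NA_real_, p_value = NA_real_))
    tibble::tibble(
      pair = sub("_(left|right)$", "", paired$name[r]),
      left_label = l_lab, right_label = r_lab,
      left_pct = mean(lp), right_pct = mean(rp),
      statistic = tt$statistic, p_value = tt$p_value
    )
  })
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out
}
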