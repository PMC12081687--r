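#' Build a function-sparing radiotherapy target volume
#'
#' Boolean target construction: the union of the spared region masks is
#' expanded by an isotropic Euclidean margin (exact distance-transform
#' dilation, spacing-independent) and subtracted from the whole brain.
#' An empty spared set reproduces whole-brain radiotherapy (target =
#' brain); a spared set covering the brain yields an empty, degenerate
#' target (flagged with a warning).
#'
#' @param phantom A `bm_phantom`.
#' @param spared_regions Character region names (laterality pairs may be
#'   named without suffix) or integer labels; empty for plain WBRT.
#' @param margin_mm Isotropic expansion margin (mm).
#' @param atlas Atlas holding the labels (default coarse).
#' @param name Plan name (defaults to something descriptive).
#' @return A `bm_plan`: list with `name`, `spared_labels`, `margin_mm`,
#'   `target` (logical `volume3d`), `spared_volume_fraction` (share of
#'   brain volume excluded) and `spared_parenchyma_fraction` (share of
#'   gray+white volume excluded).
#' @export
build_target <- function(phantom, spared_regions = character(0),
                         margin_mm = 3, atlas = "coarse", name = NULL) {
  stopifnot(margin_mm >= 0)
  brain <- phantom$brain_mask
  if (length(spared_regions) == 0) {
    spared <- volume3d(array(FALSE, phantom$shape), vox_spacing(brain))
    labels <- integer(0)
  } else {
    labels <- region_labels(phantom, spared_regions, atlas)
    av <- phantom[[paste0("atlas_", atlas)]]
    spared_core <- array(av %in% labels, phantom$shape)
    spared <- dilate_mask(volume3d(spared_core, vox_spacing(brain)),
      margin_mm)
  }
  target <- array(brain & !spared, phantom$shape)
  par <- phantom_parenchyma(phantom)
  plan <- structure(
    list(
      name = name %||% if (length(labels) == 0) "wbrt" else
        paste0("spared_", length(labels), "_regions_", margin_mm, "mm"),
      spared_labels = labels,
      margin_mm = margin_mm,
      atlas = atlas,
      target = volume3d(target, vox_spacing(brain)),
      spared_volume_fraction = sum(brain & spared) / sum(brain),
      spared_parenchyma_fraction = sum(par & spared) / sum(par)
    ),
    class = "bm_plan"
  )
  if (!any(target)) warning("degenerate plan: target volume is empty")
  plan
}

#' @export
print.bm_plan <- function(x, ...) {
  cat(sprintf(
    "<bm_plan> %s: %d spared label(s), margin %g mm, %.1f%% of brain spared\n",
    x$name, length(x$spared_labels), x$margin_mm,
    100 * x$spared_volume_fraction
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.bm_plan <- function(x, ...) {
  tibble::tibble(
    plan = x$name, n_spared_labels = length(x$spared_labels),
    margin_mm = x$margin_mm,
    spared_volume_fraction = x$spared_volume_fraction,
    spared_parenchyma_fraction = x$spared_parenchyma_fraction
  )
}

#' Preset sparing plans
#'
#' `plan_wbrt()` is conventional whole-brain radiotherapy (nothing spared).
#' `plan_wbrt_ha()` spares the hippocampi with a 5 mm margin
#' (hippocampal-avoidance WBRT). `plan_protect()` spares the 3 mm isotropic
#' expansion of the union of hippocampi, amygdala, thalamus, pallidus,
#' caudate, putamen, brainstem and ventricles — the deep-structure
#' function-sparing target; the plan target is the whole brain minus that
#' expanded union.
#'
#' @param phantom A `bm_phantom`.
#' @name sparing-presets
#' @export
plan_wbrt <- function(phantom) {
  build_target(phantom, character(0), margin_mm = 0, name = "wbrt")
}

#' @rdname sparing-presets
#' @export
plan_wbrt_ha <- function(phantom) {
  build_target(phantom, "hippocampus", margin_mm = 5, name = "wbrt_ha")
}

#' @rdname sparing-presets
#' @export
plan_protect <- function(phantom) {
  build_target(phantom,
    c("hippocampus", "amygdala", "thalamus", "pallidus", "caudate",
      "putamen", "brainstem", "ventricle"),
    margin_mm = 3, name = "wbrt_protect"
  )
}

#' Expected metastasis coverage of a plan
#'
#' Percentage of a cohort's lesions covered by the plan's target volume:
#' by centroid (default; a lesion counts as covered iff the voxel holding
#' its centroid is in the target) or by volume (share of total lesion
#' voxels inside the target). Reported overall and per primary histology.
#' A lesion whose centroid falls outside the grid counts as uncovered.
#'
#' @param cohort A `bm_cohort`.
#' @param plan A `bm_plan`.
#' @param mode `"centroid"` or `"volume"`.
#' @return Tibble with rows `primary = "all"` plus each histology present:
#'   `plan`, `mode`, `primary`, `n_lesions`, `coverage_pct`,
#'   `spared_volume_fraction`.
#' @export
expected_coverage <- function(cohort, plan, mode = c("centroid", "volume")) {
  mode <- match.arg(mode)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  target <- plan$target
  dims <- dim(target)
  if (mode == "centroid") {
    cen <- as.matrix(cohort[, c("centroid_x_mm", "centroid_y_mm",
      "centroid_z_mm")])
    lin <- voxel_linear(mm_to_voxel(cen, vox_spacing(target), dims), dims)
    covered <- as.vector(target)[lin]
    weight <- rep(1, nrow(cohort))
  } else {
    covered <- vapply(cohort$voxels, function(v) {
      sum(as.vector(target)[voxel_linear(v, dims)])
    }, numeric(1))
    weight <- cohort$n_voxels
  }
  plan_name <- plan$name
  spared_frac <- plan$spared_volume_fraction
  one <- function(rows, tag) {
    tibble::tibble(
      plan = plan_name, mode = mode, primary = tag,
      n_lesions = length(rows),
      coverage_pct = 100 * sum(covered[rows]) / sum(weight[rows]),
      spared_volume_fraction = spared_frac
    )
  }
  out <- one(seq_len(nrow(cohort)), "all")
  for (pr in unique(cohort$primary)) {
    if (!identical(pr, "all")) {
      out <- dplyr::bind_rows(out, one(which(cohort$primary == pr), pr))
    }
  }
  out
}

#' Coverage-sparing tradeoff across nested plans
#'
#' Evaluates [expected_coverage()] for a list of plans whose spared sets
#' should be nested; coverage is then monotone non-increasing as sparing
#' grows. Non-nested plans are still computed, with a warning, and
#' monotonicity is not asserted.
#'
#' @param cohort A `bm_cohort`.
#' @param plans List of `bm_plan`s, ordered from least to most spared.
#' @param mode Passed to [expected_coverage()].
#' @return Tibble `plan`, `spared_volume_fraction`,
#'   `spared_parenchyma_fraction`, `coverage_pct`.
#' @export
tradeoff_curve <- function(cohort, plans, mode = "centroid") {
  nested <- TRUE
  if (length(plans) > 1) {
    for (i in seq_len(length(plans) - 1)) {
      a <- !plans[[i]]$target # spared-or-outside set grows down the nesting
      b <- !plans[[i + 1]]$target
      if (any(a & !b)) {
        nested <- FALSE
        break
      }
    }
  }
  if (!nested) warning("plans are not nested; coverage need not be monotone")
  purrr::map_dfr(plans, function(p) {
    cov <- expected_coverage(cohort, p, mode)
    tibble::tibble(
      plan = p$name,
      spared_volume_fraction = p$spared_volume_fraction,
      spared_parenchyma_fraction = p$spared_parenchyma_fraction,
      coverage_pct = cov$coverage_pct[cov$primary == "all"]
    )
  })
}
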