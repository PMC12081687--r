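#' Euclidean distance transform of a binary mask
#'
#' Exact distance (mm, between voxel centers) from every voxel to the nearest
#' `TRUE` voxel of `mask`, by the separable lower-envelope algorithm. Also
#' returns, for every voxel, the linear index of that nearest feature voxel,
#' which powers nearest-label assignment and margin expansion.
#'
#' @param mask A logical `volume3d` with at least one `TRUE` voxel.
#' @return A list with `distance` (a `volume3d`, mm; `Inf` where no feature
#'   exists) and `feature` (integer `volume3d` of 1-based linear indices).
#' @export
distance_transform <- function(mask) {
  if (!any(mask)) stop("mask has no foreground voxels", call. = FALSE)
  res <- edt_cpp(as.logical(mask), dim(mask), vox_spacing(mask))
  list(
    distance = volume3d(array(res$distance, dim(mask)), vox_spacing(mask),
      vox_origin(mask)),
    feature = volume3d(array(res$feature, dim(mask)), vox_spacing(mask),
      vox_origin(mask))
  )
}

#' Dilate a mask by an isotropic physical margin
#'
#' Euclidean dilation: a voxel joins the dilated set iff its center lies
#' within `margin_mm` of some foreground voxel center. Thresholding the exact
#' distance transform keeps the operation spacing-independent (no structuring
#' element).
#'
#' @param mask Logical `volume3d`.
#' @param margin_mm Non-negative margin in mm.
#' @export
dilate_mask <- function(mask, margin_mm) {
  stopifnot(margin_mm >= 0)
  if (margin_mm == 0) return(mask)
  if (margin_mm > max(dim(mask) * vox_spacing(mask))) {
    stop("margin ", margin_mm, " mm exceeds the grid extent", call. = FALSE)
  }
  d <- distance_transform(mask)$distance
  volume3d(array(d <= margin_mm, dim(mask)), vox_spacing(mask),
    vox_origin(mask))
}

#' Expand atlas labels into unlabeled space
#'
#' Every background voxel within `margin_mm` of a labeled voxel receives the
#' label of its *nearest* labeled voxel, so overlapping expansions resolve by
#' proximity to the original regions.
#'
#' @param atlas Integer `volume3d`; 0 is background.
#' @param margin_mm Expansion margin in mm.
#' @export
expand_labels <- function(atlas, margin_mm) {
  stopifnot(margin_mm >= 0)
  if (margin_mm == 0) return(atlas)
  if (margin_mm > max(dim(atlas) * vox_spacing(atlas))) {
    stop("margin ", margin_mm, " mm exceeds the grid extent", call. = FALSE)
  }
  fg <- atlas > 0
  dt <- distance_transform(volume3d(fg, vox_spacing(atlas)))
  out <- array(0L, dim(atlas))
  take <- dt$distance <= margin_mm
  out[take] <- as.integer(atlas[as.vector(dt$feature)[take]])
  volume3d(out, vox_spacing(atlas), vox_origin(atlas))
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask Logical `volume3d` (or 3D array).
#' @return Integer `volume3d` of component labels (0 = background), numbered
#'   in first-voxel scan order.
#' @export
label_components <- function(mask) {
  lab <- label_components_cpp(as.logical(mask), dim(mask))
  sp <- if (inherits(mask, "volume3d")) vox_spacing(mask) else c(1, 1, 1)
  volume3d(array(lab, dim(mask)), sp, vox_origin(mask))
}
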