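#' Extract lesions as 26-connected components
#'
#' Splits a binary lesion mask into its 26-connected components, one lesion
#' per component.
#'
#' @param mask Logical `volume3d`.
#' @param spacing_mm Optional spacing override when `mask` is a bare array.
#' @return A tibble with one row per lesion: `lesion_id`, `n_voxels`,
#'   `volume_cc`, centroid coordinates (mm, unweighted mean of voxel
#'   centers) and a `voxels` list-column of n x 3 integer index matrices.
#'   An empty mask yields a zero-row tibble.
#' @export
extract_lesions <- function(mask, spacing_mm = NULL) {
  sp <- if (!is.null(spacing_mm)) rep_len(spacing_mm, 3L) else vox_spacing(mask)
  if (is.null(sp)) stop("spacing unknown; pass `spacing_mm`", call. = FALSE)
  lab <- label_components_cpp(as.logical(mask), dim(mask))
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(tibble::tibble(
      lesion_id = integer(), n_voxels = integer(), volume_cc = numeric(),
      centroid_x_mm = numeric(), centroid_y_mm = numeric(),
      centroid_z_mm = numeric(), voxels = list()
    ))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  coords <- arrayInd(idx, dim(mask))
  vv <- voxel_volume_cc(sp)
  split_rows <- split(seq_along(idx), comp)
  purrr::map_dfr(seq_len(n_comp), function(i) {
    vx <- coords[split_rows[[i]], , drop = FALSE]
    cen <- colMeans(voxels_to_mm(vx, sp))
    tibble::tibble(
      lesion_id = i, n_voxels = nrow(vx), volume_cc = nrow(vx) * vv,
      centroid_x_mm = cen[1], centroid_y_mm = cen[2], centroid_z_mm = cen[3],
      voxels = list(vx)
    )
  })
}

#' Wadell sphericity of a voxelized lesion
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A`, equal to 1 for a perfect sphere. The
#' volume `V` is the voxel count times the voxel volume; the surface area
#' `A` is estimated either from a triangulated isosurface (`"mesh"`, the
#' default: marching tetrahedra on a Gaussian-smoothed indicator field,
#' which tracks the continuum surface area) or by counting exposed voxel
#' faces (`"voxel_faces"`, exactly testable but biased high in area, hence
#' low in sphericity). A single-voxel lesion falls back from mesh to
#' voxel-face counting with a warning. Mesh values are clipped to 1 when
#' discretization pushes them slightly above.
#'
#' @param voxels n x 3 integer matrix of voxel indices (one connected
#'   lesion), or a one-row lesion tibble from [extract_lesions()].
#' @param spacing_mm Voxel spacing (mm).
#' @param method `"mesh"` or `"voxel_faces"`.
#' @param smooth_sigma_vox Gaussian sigma (voxels) for the mesh indicator;
#'   the default adapts to lesion size, `min(0.7, r_eq/6)` with `r_eq` the
#'   volume-equivalent radius in voxels, so large lesions get the full
#'   staircase-removing smoothing while small ones are not shrunk below
#'   their own curvature scale.
#' @return Sphericity in (0, 1].
#' @export
compute_sphericity <- function(voxels, spacing_mm,
                               method = c("mesh", "voxel_faces"),
                               smooth_sigma_vox = NULL) {
  method <- match.arg(method)
  if (is.data.frame(voxels)) voxels <- voxels$voxels[[1]]
  voxels <- matrix(as.integer(voxels), ncol = 3)
  sp <- rep_len(spacing_mm, 3L)
  n <- nrow(voxels)
  if (n == 0) stop("empty lesion", call. = FALSE)
  V <- n * prod(sp)
  if (method == "mesh" && n == 1) {
    warning("single-voxel lesion: falling back to voxel_faces surface area")
    method <- "voxel_faces"
  }
  if (is.null(smooth_sigma_vox)) {
    r_eq_vox <- (3 * n / (4 * pi))^(1 / 3)
    smooth_sigma_vox <- min(0.7, r_eq_vox / 6)
  }
  A <- switch(method,
    voxel_faces = voxel_face_area(voxels, sp),
    mesh = mesh_surface_area(voxels, sp, smooth_sigma_vox)
  )
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  if (method == "mesh") psi <- min(psi, 1)
  psi
}

# exposed-face count weighted by per-axis face areas
voxel_face_area <- function(voxels, sp) {
  lo <- apply(voxels, 2, min) - 1L
  d <- apply(voxels, 2, max) - lo + 1L
  arr <- array(FALSE, d + 2L)
  arr[cbind(voxels[, 1] - lo[1] + 1L, voxels[, 2] - lo[2] + 1L,
    voxels[, 3] - lo[3] + 1L)] <- TRUE
  face_areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1))
  total <- 0
  for (k in seq_len(6)) {
    sh <- shifts[k, ]
    nb <- shift_array(arr, sh)
    exposed <- arr & !nb
    total <- total + sum(exposed) * face_areas[(k + 1) %/% 2]
  }
  total
}

shift_array <- function(arr, sh) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src <- dst <- list()
  for (a in 1:3) {
    if (sh[a] >= 0) {
      src[[a]] <- seq_len(d[a] - sh[a])
      dst[[a]] <- src[[a]] + sh[a]
    } else {
      src[[a]] <- seq_len(d[a] + sh[a]) - sh[a]
      dst[[a]] <- seq_len(d[a] + sh[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

mesh_surface_area <- function(voxels, sp, sigma_vox = 0.7) {
  pad <- max(3L, ceiling(3 * sigma_vox) + 1L)
  lo <- apply(voxels, 2, min) - pad
  d <- apply(voxels, 2, max) - lo + pad
  arr <- array(0, d)
  arr[cbind(voxels[, 1] - lo[1], voxels[, 2] - lo[2], voxels[, 3] - lo[3])] <- 1
  sm <- gauss_smooth_3d(arr, sigma_vox)
  mesh_area_cpp(as.numeric(sm), dim(sm), sp, 0.5)
}

#' Distance map to the gray-white matter interface
#'
#' The interface is the voxel set where gray and white matter meet under
#' 6-adjacency: gray voxels with a white face-neighbor plus white voxels
#' with a gray face-neighbor. The returned map holds the exact Euclidean
#' distance (mm) from every voxel center to the nearest interface voxel
#' center; it is zero exactly on the interface and 1-Lipschitz in physical
#' coordinates.
#'
#' @param gray,white Disjoint nonempty logical `volume3d` masks on one grid.
#' @return A `bm_dmap`: list with `distance` (`volume3d`, mm) and
#'   `interface` (logical `volume3d`).
#' @export
interface_distance_map <- function(gray, white) {
  stopifnot_same_grid(gray, white)
  if (any(gray & white)) stop("gray and white masks overlap", call. = FALSE)
  if (!any(gray) || !any(white)) {
    stop("gray and white masks must both be nonempty", call. = FALSE)
  }
  iface <- (gray & face_neighbor_any(white)) |
    (white & face_neighbor_any(gray))
  if (!any(iface)) {
    stop("gray and white matter are nowhere adjacent: no interface exists",
      call. = FALSE
    )
  }
  dt <- distance_transform(volume3d(iface, vox_spacing(gray)))
  structure(
    list(
      distance = dt$distance,
      interface = volume3d(array(iface, dim(gray)), vox_spacing(gray))
    ),
    class = "bm_dmap"
  )
}

face_neighbor_any <- function(mask) {
  m <- as.array(mask)
  out <- array(FALSE, dim(m))
  for (sh in list(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )) {
    out <- out | shift_array(m, sh)
  }
  out
}

#' Centroid distance to the gray-white interface
#'
#' Samples the interface distance map at the voxel containing each lesion
#' centroid (nearest-voxel sampling, per the voxel-center convention).
#' Centroids outside the brain mask are flagged but still get a distance.
#'
#' @param lesions Lesion tibble with centroid columns (from
#'   [extract_lesions()] or a cohort).
#' @param dmap A `bm_dmap` from [interface_distance_map()].
#' @param brain_mask Optional logical `volume3d` used only for flagging.
#' @return The lesion tibble with `interface_distance_mm` (and
#'   `centroid_in_brain` when a brain mask is supplied) appended.
#' @export
lesion_interface_distance <- function(lesions, dmap, brain_mask = NULL) {
  dist <- dmap$distance
  cen <- as.matrix(lesions[, c("centroid_x_mm", "centroid_y_mm",
    "centroid_z_mm")])
  idx <- mm_to_voxel(cen, vox_spacing(dist), dim(dist))
  lin <- voxel_linear(idx, dim(dist))
  lesions$interface_distance_mm <- as.vector(dist)[lin]
  if (!is.null(brain_mask)) {
    inb <- as.vector(brain_mask)[lin]
    if (any(!inb)) {
      warning(sum(!inb), " lesion centroid(s) fall outside the brain mask")
    }
    lesions$centroid_in_brain <- inb
  }
  lesions
}

#' Assign atlas region membership by lesion centroid
#'
#' Each lesion belongs to the region whose label covers the voxel containing
#' its centroid. Centroids on background are rescued to the nearest labeled
#' voxel within `rescue_mm`; beyond that the lesion is `NA` ("unassigned").
#'
#' @param lesions Lesion tibble with centroid columns.
#' @param atlas Integer `volume3d` of region labels (0 = background).
#' @param rescue_mm Background rescue radius (mm).
#' @param column Name of the membership column to create.
#' @return The lesion tibble with the membership column appended (integer
#'   label, `NA` if unassigned).
#' @export
assign_membership <- function(lesions, atlas, rescue_mm = 5,
                              column = "region_label") {
  cen <- as.matrix(lesions[, c("centroid_x_mm", "centroid_y_mm",
    "centroid_z_mm")])
  idx <- mm_to_voxel(cen, vox_spacing(atlas), dim(atlas))
  lin <- voxel_linear(idx, dim(atlas))
  lab <- as.integer(as.vector(atlas)[lin])
  miss <- which(lab == 0L)
  if (length(miss)) {
    dt <- distance_transform(volume3d(atlas > 0, vox_spacing(atlas)))
    dvals <- as.vector(dt$distance)[lin[miss]]
    feats <- as.vector(dt$feature)[lin[miss]]
    ok <- dvals <= rescue_mm
    lab[miss[ok]] <- as.integer(as.vector(atlas)[feats[ok]])
    lab[miss[!ok]] <- NA_integer_
  }
  lab[lab == 0L] <- NA_integer_
  lesions[[column]] <- lab
  lesions
}

#' Full per-lesion morphometric table
#'
#' Convenience pipeline: sphericity, interface distance and membership in
#' every phantom atlas, appended to a cohort or lesion tibble. This is the
#' per-lesion record the tabular store persists.
#'
#' @param lesions A `bm_cohort` or lesion tibble with `voxels` and centroid
#'   columns.
#' @param phantom A `bm_phantom`.
#' @param sphericity_method Passed to [compute_sphericity()].
#' @param dmap Optional precomputed [interface_distance_map()].
#' @return Tibble with `sphericity`, `interface_distance_mm`,
#'   `coarse_label`, `fine_label`, `functional_label`, `vascular_label`
#'   appended.
#' @export
lesion_metrics <- function(lesions, phantom,
                           sphericity_method = "mesh", dmap = NULL) {
  sp <- rep(phantom$spacing_mm, 3)
  lesions$sphericity <- purrr::map_dbl(lesions$voxels, function(v) {
    if (nrow(v) == 1) {
      compute_sphericity(v, sp, method = "voxel_faces")
    } else {
      compute_sphericity(v, sp, method = sphericity_method)
    }
  })
  dmap <- dmap %||% interface_distance_map(phantom$gray_mask,
    phantom$white_mask)
  lesions <- lesion_interface_distance(lesions, dmap, phantom$brain_mask)
  for (at in c("coarse", "fine", "functional", "vascular")) {
    lesions <- assign_membership(lesions, phantom[[paste0("atlas_", at)]],
      column = paste0(at, "_label"))
  }
  lesions
}
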