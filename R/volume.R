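#' 3D volumes with physical spacing
#'
#' A `volume3d` is a plain 3D array carrying an isotropic-or-not voxel
#' spacing (mm) and a physical origin. It is the common substrate for brain
#' masks, label atlases, scalar maps and lesion masks. The coordinate
#' convention, used everywhere in the package, is voxel-center: the physical
#' position of voxel `(i, j, k)` (1-based) is
#' `origin + (i - 0.5, j - 0.5, k - 0.5) * spacing`.
#'
#' @param data A 3D array (numeric, integer or logical).
#' @param spacing_mm Voxel edge lengths in mm; a single number is recycled to
#'   all three axes.
#' @param origin_mm Physical coordinate of the corner of voxel (1,1,1);
#'   defaults to the zero vector.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("voxel spacing must be positive and finite", call. = FALSE)
  }
  structure(data,
    spacing = spacing_mm,
    origin = rep_len(as.numeric(origin_mm), 3L),
    class = c("volume3d", class(data))
  )
}

#' @export
as.array.volume3d <- function(x, ...) {
  array(as.vector(x), dim(x))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels, spacing %s mm, %s\n",
    d[1], d[2], d[3], paste(signif(vox_spacing(x), 4), collapse = " x "),
    typeof(x)
  ))
  invisible(x)
}

vox_spacing <- function(vol) attr(vol, "spacing")
vox_origin <- function(vol) {
  o <- attr(vol, "origin")
  if (is.null(o)) c(0, 0, 0) else o
}

#' Physical volume of one voxel in cc
#' @param vol A `volume3d` or a spacing vector.
#' @export
voxel_volume_cc <- function(vol) {
  sp <- if (inherits(vol, "volume3d")) vox_spacing(vol) else rep_len(vol, 3L)
  prod(sp) / 1000
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) && all(abs(vox_spacing(a) - vox_spacing(b)) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("volumes are not on the same grid (dim ",
      paste(dim(a), collapse = "x"), " / spacing ",
      paste(vox_spacing(a), collapse = "x"), " vs dim ",
      paste(dim(b), collapse = "x"), " / spacing ",
      paste(vox_spacing(b), collapse = "x"), ")",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# voxel index matrix (n x 3, 1-based) -> physical centers (n x 3, mm)
voxels_to_mm <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep((idx - 0.5) %*% diag(spacing), 2, origin, "+")
}

# physical point(s) -> index of the containing voxel, clamped to the grid
mm_to_voxel <- function(xyz, spacing, dim, origin = c(0, 0, 0)) {
  xyz <- matrix(xyz, ncol = 3)
  idx <- floor(sweep(xyz, 2, origin, "-") %*% diag(1 / spacing)) + 1L
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1L), dim[a])
  storage.mode(idx) <- "integer"
  idx
}

# linear (1-based) index from an n x 3 voxel index matrix
voxel_linear <- function(idx, dim) {
  idx[, 1] + as.numeric(dim[1]) * (idx[, 2] - 1) +
    as.numeric(dim[1]) * dim[2] * (idx[, 3] - 1)
}

#' Read a volume from a NIfTI file
#'
#' Integer-valued data round-trips bit-exactly. The session can demand an
#' isotropic grid, in which case anisotropic files are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param require_isotropic Reject files whose voxels are not cubes.
#' @param expect_spacing_mm If given, error when the file's spacing differs.
#' @return A `volume3d`.
#' @export
read_volume <- function(path, require_isotropic = FALSE,
                        expect_spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (require_isotropic && diff(range(sp)) > 1e-6) {
    stop("anisotropic spacing (", paste(signif(sp, 5), collapse = " x "),
      " mm) but an isotropic grid was required",
      call. = FALSE
    )
  }
  if (!is.null(expect_spacing_mm)) {
    want <- rep_len(expect_spacing_mm, 3L)
    if (any(abs(sp - want) > 1e-6)) {
      stop("file spacing ", paste(signif(sp, 5), collapse = "x"),
        " mm does not match the session grid ",
        paste(signif(want, 5), collapse = "x"), " mm",
        call. = FALSE
      )
    }
  }
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  volume3d(arr, sp)
}

#' Write a volume to a NIfTI file
#'
#' @param vol A `volume3d`. Logical and integer data are stored as int32,
#'   doubles as float64, so integer content is preserved exactly.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  dt <- if (is.double(vol)) "double" else "int32"
  arr <- array(if (is.logical(vol)) as.integer(vol) else as.vector(vol),
    dim = dim(vol)
  )
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vox_spacing(vol)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
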