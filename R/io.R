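#' Read a contour set from JSON
#'
#' The JSON contour format carries a grid spec and, per lesion, a list of
#' closed planar polygons tagged with their plane:
#' ```
#' {"grid": {"shape": [64,64,64], "spacing_mm": 2},
#'  "lesions": [{"lesion_id": 1,
#'               "polygons": [{"axis": "z", "coord_mm": 31,
#'                             "vertices_mm": [[x1,y1], [x2,y2], ...]}]}]}
#' ```
#' Polygons are closed vertex loops (the last vertex connects back to the
#' first) in physical mm, on axis-aligned planes.
#'
#' @param path JSON file path.
#' @return A `bm_contours` list: `grid` (shape, spacing_mm) and `lesions`.
#' @export
read_contours <- function(path) {
  cs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
    simplifyMatrix = FALSE)
  validate_contours(cs)
  structure(cs, class = "bm_contours")
}

validate_contours <- function(cs) {
  if (is.null(cs$grid$shape) || is.null(cs$grid$spacing_mm)) {
    stop("contour set lacks a grid spec", call. = FALSE)
  }
  for (les in cs$lesions) {
    for (pg in les$polygons) {
      if (!pg$axis %in% c("x", "y", "z")) {
        stop("polygon plane must be axis-aligned (axis 'x', 'y' or 'z')",
          call. = FALSE
        )
      }
      if (length(pg$vertices_mm) < 3) {
        stop("polygon needs at least 3 vertices", call. = FALSE)
      }
    }
  }
  invisible(cs)
}

#' Rasterize planar contours to a binary mask
#'
#' A voxel is included iff its center lies inside the polygon of its plane
#' (even-odd rule), the same center-inclusion convention the lesion
#' simulator uses, so rasterized and simulated inputs are interchangeable.
#' The polygon's plane coordinate must coincide with a voxel-center plane.
#'
#' @param contours A `bm_contours` (or a single lesion's polygon list with
#'   `grid` supplied).
#' @param lesion_id Rasterize only this lesion (default: union of all).
#' @return Logical `volume3d`.
#' @export
rasterize_contours <- function(contours, lesion_id = NULL) {
  validate_contours(contours)
  shape <- rep_len(as.integer(unlist(contours$grid$shape)), 3L)
  sp <- rep_len(as.numeric(unlist(contours$grid$spacing_mm)), 3L)
  mask <- array(FALSE, shape)
  lesions <- contours$lesions
  if (!is.null(lesion_id)) {
    lesions <- Filter(function(l) identical(l$lesion_id, lesion_id) ||
      isTRUE(l$lesion_id == lesion_id), lesions)
  }
  for (les in lesions) {
    for (pg in les$polygons) {
      ax <- match(pg$axis, c("x", "y", "z"))
      k_real <- pg$coord_mm / sp[ax] + 0.5
      k <- round(k_real)
      if (abs(k_real - k) > 1e-6) {
        stop("polygon plane at ", pg$coord_mm,
          " mm does not align with a voxel-center plane of the grid",
          call. = FALSE
        )
      }
      if (k < 1 || k > shape[ax]) {
        stop("polygon plane outside the grid", call. = FALSE)
      }
      verts <- do.call(rbind, lapply(pg$vertices_mm, as.numeric))
      inplane <- setdiff(1:3, ax)
      cu <- (seq_len(shape[inplane[1]]) - 0.5) * sp[inplane[1]]
      cv <- (seq_len(shape[inplane[2]]) - 0.5) * sp[inplane[2]]
      gr <- expand.grid(u = cu, v = cv)
      inside <- point_in_polygon(gr$u, gr$v, verts[, 1], verts[, 2])
      plane <- matrix(inside, length(cu), length(cv))
      idx <- which(plane, arr.ind = TRUE)
      if (nrow(idx)) {
        full <- matrix(0L, nrow(idx), 3)
        full[, inplane[1]] <- idx[, 1]
        full[, inplane[2]] <- idx[, 2]
        full[, ax] <- as.integer(k)
        mask[full] <- TRUE
      }
    }
  }
  volume3d(mask, sp)
}

# even-odd (ray crossing) point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Persist / load a cohort's tabular record
#'
#' A relational file store: `patients.csv` (patient_id, site, primary,
#' n_lesions), `lesions.csv` (one row per lesion with morphometrics and
#' atlas memberships) and `runs.csv` (run_id, config hash, seed,
#' timestamp). Re-writing with the same config hash replaces the matching
#' run row, so repeated runs are idempotent.
#'
#' @param store_dir Directory (created if needed).
#' @param lesions Per-lesion tibble (e.g. from [lesion_metrics()]); the
#'   `voxels` list-column is dropped for storage.
#' @param config The `bm_sim_config` (hashed for the runs table).
#' @return `cohort_store_write` returns the store dir invisibly;
#'   `cohort_store_read` returns a list of the three tibbles.
#' @export
cohort_store_write <- function(store_dir, lesions, config = NULL) {
  dir.create(store_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- lesions[, setdiff(names(lesions), "voxels")]
  patients <- dplyr::summarise(
    dplyr::group_by(flat, .data$patient_id, .data$site, .data$primary),
    n_lesions = dplyr::n(), .groups = "drop"
  )
  write.csv(flat, file.path(store_dir, "lesions.csv"), row.names = FALSE)
  write.csv(patients, file.path(store_dir, "patients.csv"),
    row.names = FALSE)
  hash <- config_hash(config)
  runs_path <- file.path(store_dir, "runs.csv")
  runs <- if (file.exists(runs_path)) {
    tibble::as_tibble(read.csv(runs_path, stringsAsFactors = FALSE))
  } else {
    tibble::tibble(run_id = integer(), config_hash = character(),
      seed = integer(), n_lesions = integer(), timestamp = character())
  }
  runs <- runs[runs$config_hash != hash, , drop = FALSE]
  runs <- dplyr::bind_rows(runs, tibble::tibble(
    run_id = if (nrow(runs)) max(runs$run_id) + 1L else 1L,
    config_hash = hash,
    seed = if (is.null(config)) NA_integer_ else config$seed,
    n_lesions = nrow(flat),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ))
  write.csv(runs, runs_path, row.names = FALSE)
  invisible(store_dir)
}

#' @rdname cohort_store_write
#' @export
cohort_store_read <- function(store_dir) {
  list(
    patients = tibble::as_tibble(read.csv(
      file.path(store_dir, "patients.csv"), stringsAsFactors = FALSE)),
    lesions = tibble::as_tibble(read.csv(
      file.path(store_dir, "lesions.csv"), stringsAsFactors = FALSE)),
    runs = tibble::as_tibble(read.csv(
      file.path(store_dir, "runs.csv"), stringsAsFactors = FALSE))
  )
}

config_hash <- function(config) {
  if (is.null(config)) return("none")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
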