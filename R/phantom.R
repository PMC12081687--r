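#' Build a synthetic brain phantom
#'
#' Constructs a self-consistent digital head model on an isotropic grid:
#' nested ellipsoidal cerebrum, cerebellum and brainstem; a cortical gray
#' shell over a white interior; paired deep gray nuclei (thalamus, caudate,
#' putamen, pallidus, hippocampus, amygdala) and lateral ventricles; a coarse
#' anatomical atlas (lobes split left/right plus the structures above), a
#' finer subdivision, a functional atlas and a vascular-territory atlas; and
#' a smooth perfusion field that is higher in gray than in white matter. It
#' stands in for a standard-space template plus its atlas overlays so the
#' whole analysis stack is testable without external data.
#'
#' All structure positions and sizes scale linearly with the grid extent, so
#' the same anatomy is produced at any resolution. Construction is
#' deterministic given `seed` (the only random element is the smooth
#' perfusion texture).
#'
#' @param spacing_mm Isotropic voxel edge length in mm (default 2, the
#'   working resolution of the analyses; 1 mm works but is slower).
#' @param shape Grid dimensions; minimum 32 voxels per axis.
#' @param seed Integer seed for the perfusion texture.
#' @param gray_thickness_mm Thickness of the cortical gray shell. The
#'   default (8 mm) is thicker than real cortex: with no folding, a thick
#'   shell is what keeps the gray share of parenchyma (~40%) and the
#'   tissue-to-interface distance distribution in a realistic range.
#' @param perfusion_smooth_mm Gaussian sigma (mm) of the masked smoothing
#'   applied to the perfusion field, emulating the partial-volume blurring
#'   of arterial-spin-labeling maps.
#' @return A `bm_phantom`: list with logical `brain_mask`, `gray_mask`,
#'   `white_mask`; integer `atlas_coarse`, `atlas_fine`, `atlas_functional`,
#'   `atlas_vascular`; numeric `perfusion`; `spacing_mm`; and `region_table`,
#'   a tibble with one row per (atlas, label): name, laterality `partner`
#'   label (NA if unpaired), total `volume_cc` and seedable `parenchyma_cc`
#'   (volume within gray + white).
#' @examples
#' ph <- build_phantom(spacing_mm = 3, shape = c(64, 64, 64), seed = 1)
#' ph$region_table[ph$region_table$atlas == "coarse", ]
#' @export
build_phantom <- function(spacing_mm = 2, shape = c(96, 96, 96), seed = 7,
                          gray_thickness_mm = 8, perfusion_smooth_mm = 6) {
  stopifnot(spacing_mm > 0)
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape < 32)) {
    stop("phantom grid must be at least 32 voxels per axis", call. = FALSE)
  }
  sp <- rep(spacing_mm, 3)
  ext <- shape * sp
  s <- ext / 192 # reference anatomy is laid out on a 192 mm cube

  ref <- function(center, semi) {
    ellipsoid_mask(shape, sp, center * s, semi * s)
  }

  cerebrum <- ref(c(96, 105, 111), c(61, 69, 54))
  cerebellum <- ref(c(96, 54, 73), c(38, 25, 21))
  brainstem <- ref(c(96, 88, 70), c(10, 10, 24))
  brain <- cerebrum | cerebellum | brainstem

  # paired structures: list(center_ref, semi_ref); x offset mirrored
  pairs <- list(
    ventricle = list(c(9, 107, 116), c(5, 22, 8)),
    thalamus = list(c(17, 98, 106), c(9, 11, 8)),
    caudate = list(c(18, 118, 116), c(5, 13, 5)),
    pallidus = list(c(21, 108, 100), c(4, 6, 4)),
    putamen = list(c(27, 108, 106), c(7, 11, 6)),
    hippocampus = list(c(25, 88, 92), c(6, 13, 5)),
    amygdala = list(c(24, 103, 90), c(5, 6, 5))
  )

  lab <- array(0L, shape)
  xs <- (seq_len(shape[1]) - 0.5) * sp[1]
  left <- array(rep(xs < ext[1] / 2, prod(shape[2:3])), shape)

  assign_lab <- function(mask, l) {
    take <- mask & brain & lab == 0
    lab[take] <<- l
  }
  # priority order: brainstem, cerebellum, then deep structures, then lobes
  assign_lab(brainstem, 11L)
  assign_lab(cerebellum & left, 9L)
  assign_lab(cerebellum, 10L)
  deep_base <- c(ventricle = 24L, thalamus = 12L, caudate = 14L,
    pallidus = 18L, putamen = 16L, hippocampus = 20L, amygdala = 22L)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    lft <- ref(c(96 - p[[1]][1], p[[1]][2], p[[1]][3]), p[[2]])
    rgt <- ref(c(96 + p[[1]][1], p[[1]][2], p[[1]][3]), p[[2]])
    assign_lab(lft & cerebrum, deep_base[[nm]])
    assign_lab(rgt & cerebrum, deep_base[[nm]] + 1L)
  }
  # lobes on normalized cerebrum coordinates
  ys <- (seq_len(shape[2]) - 0.5) * sp[2]
  zs <- (seq_len(shape[3]) - 0.5) * sp[3]
  yn <- (ys - 105 * s[2]) / (69 * s[2])
  zn <- (zs - 111 * s[3]) / (54 * s[3])
  Yn <- aperm(array(rep(yn, shape[1] * shape[3]),
    c(shape[2], shape[1], shape[3])), c(2, 1, 3))
  Zn <- aperm(array(rep(zn, shape[1] * shape[2]),
    c(shape[3], shape[1], shape[2])), c(2, 3, 1))
  lobe <- ifelse(Yn > 0.2, 1L,
    ifelse(Yn < -0.55, 7L, ifelse(Zn < -0.25, 5L, 3L)))
  rest <- cerebrum & lab == 0
  lab[rest] <- lobe[rest] + ifelse(left[rest], 0L, 1L)

  labels_present <- sort(unique(lab[lab > 0]))
  if (!all(1:25 %in% labels_present)) {
    stop("grid too small to host all mandatory phantom regions (missing ",
      paste(setdiff(1:25, labels_present), collapse = ", "), ")",
      call. = FALSE
    )
  }

  # tissue classes
  hull <- cerebrum | cerebellum
  d_in <- edt_cpp(!hull, shape, sp)$distance
  shell <- hull & array(d_in <= gray_thickness_mm + 1e-9, shape)
  cortical <- lab %in% c(1:10) # lobes + cerebellum
  nuclei <- lab %in% 12:23
  ventr <- lab %in% 24:25
  gray <- array((cortical & shell) | nuclei, shape)
  white <- array((cortical & !shell) | lab == 11L, shape)

  # fine atlas: lobes and cerebellum split superior/inferior
  fine <- lab * 10L
  zn_cb <- (73 - 111) / 54 # cerebellum mid-plane in cerebrum-normalized z
  split_z <- (lab %in% 1:8 & Zn >= 0) | (lab %in% 9:10 & Zn >= zn_cb)
  fine[lab %in% c(1:10)] <- fine[lab %in% c(1:10)] +
    ifelse(split_z[lab %in% c(1:10)], 1L, 2L)

  # functional atlas
  func <- array(0L, shape)
  func[gray | white] <- 5L
  func[cortical & shell & abs(Yn) <= 0.12 & Zn > 0.3] <- 1L
  func[cortical & shell & Yn < -0.12 & Yn >= -0.38 & Zn > 0.3] <- 2L
  func[lab %in% 7:8 & shell] <- 3L
  func[nuclei] <- 4L
  func[ventr] <- 0L

  # vascular territories
  xn <- (xs - 96 * s[1]) / (61 * s[1])
  Xn <- array(rep(xn, prod(shape[2:3])), shape)
  vasc <- array(0L, shape)
  in_cerebrum_lab <- lab %in% c(1:8, 12:23)
  vasc[in_cerebrum_lab] <- ifelse(left[in_cerebrum_lab], 3L, 4L) # MCA default
  aca <- in_cerebrum_lab & abs(Xn) <= 0.3 & Yn >= 0.1
  vasc[aca] <- ifelse(left[aca], 1L, 2L)
  pca <- in_cerebrum_lab & Yn < -0.45
  vasc[pca] <- ifelse(left[pca], 5L, 6L)
  cb_sup <- lab %in% 9:10 & Zn >= zn_cb
  cb_inf <- lab %in% 9:10 & !cb_sup
  vasc[cb_sup] <- ifelse(left[cb_sup], 7L, 8L)
  vasc[cb_inf] <- ifelse(left[cb_inf], 9L, 10L)
  vasc[lab == 11L] <- 11L
  vasc[ventr] <- 12L

  # perfusion: tissue-dependent base plus a smooth random texture, then
  # masked smoothing so the field blurs like a low-resolution ASL map
  # without bleeding the zero background into the cortex
  perf <- array(0, shape)
  perf[white] <- 30
  perf[cortical & shell] <- 65
  perf[nuclei] <- 55
  perf[lab == 11L] <- 35
  perf[ventr] <- 8
  noise <- with_preserved_seed(seed, {
    n <- array(rnorm(prod(shape)), shape)
    n <- gauss_smooth_3d(n, sigma_vox = max(2, 8 / spacing_mm))
    n / sd(n) * 6
  })
  perf <- pmax(perf + noise * (brain), 0)
  if (perfusion_smooth_mm > 0) {
    sig <- perfusion_smooth_mm / spacing_mm
    num <- gauss_smooth_3d(perf * brain, sig)
    den <- gauss_smooth_3d(array(as.numeric(brain), shape), sig)
    perf[brain] <- num[brain] / den[brain]
  }
  perf[!brain] <- 0

  vol <- function(a) volume3d(a, sp)
  ph <- structure(list(
    brain_mask = vol(array(as.logical(brain), shape)),
    gray_mask = vol(array(as.logical(gray), shape)),
    white_mask = vol(array(as.logical(white), shape)),
    atlas_coarse = vol(array(as.integer(lab), shape)),
    atlas_fine = vol(array(as.integer(fine), shape)),
    atlas_functional = vol(array(as.integer(func), shape)),
    atlas_vascular = vol(array(as.integer(vasc), shape)),
    perfusion = vol(array(as.numeric(perf), shape)),
    spacing_mm = spacing_mm,
    shape = shape,
    seed = seed
  ), class = "bm_phantom")
  ph$region_table <- phantom_region_table(ph)
  ph
}

coarse_region_names <- function() {
  base <- c("frontal", "parietal", "temporal", "occipital", "cerebellum")
  paired <- as.vector(t(outer(base, c("left", "right"), paste, sep = "_")))
  deep <- c("thalamus", "caudate", "putamen", "pallidus", "hippocampus",
    "amygdala", "ventricle")
  deep_paired <- as.vector(t(outer(deep, c("left", "right"), paste,
    sep = "_")))
  tibble::tibble(
    label = c(1:10, 11L, 12:25),
    name = c(paired, "brainstem", deep_paired),
    partner = c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L, NA,
      13L, 12L, 15L, 14L, 17L, 16L, 19L, 18L, 21L, 20L, 23L, 22L, 25L, 24L)
  )
}

atlas_region_names <- function(atlas) {
  co <- coarse_region_names()
  switch(atlas,
    coarse = co,
    fine = {
      split <- co$label <= 10
      up <- co[split, ]
      lo <- co[split, ]
      up$label <- up$label * 10L + 1L
      up$name <- paste0(up$name, "_superior")
      up$partner <- up$partner * 10L + 1L
      lo$label <- lo$label * 10L + 2L
      lo$name <- paste0(lo$name, "_inferior")
      lo$partner <- lo$partner * 10L + 2L
      rest <- co[!split, ]
      rest$label <- rest$label * 10L
      rest$partner <- rest$partner * 10L
      dplyr::arrange(dplyr::bind_rows(up, lo, rest), .data$label)
    },
    functional = tibble::tibble(
      label = 1:5,
      name = c("motor_cortex", "sensory_cortex", "visual_cortex",
        "subcortical_network", "association_cortex"),
      partner = NA_integer_
    ),
    vascular = tibble::tibble(
      label = 1:12,
      name = c("aca_left", "aca_right", "mca_left", "mca_right",
        "pca_left", "pca_right", "superior_cerebellar_left",
        "superior_cerebellar_right", "inferior_cerebellar_left",
        "inferior_cerebellar_right", "basilar", "ventricular"),
      partner = c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L, NA, NA)
    ),
    stop("unknown atlas '", atlas, "'", call. = FALSE)
  )
}

phantom_region_table <- function(ph) {
  vv <- voxel_volume_cc(ph$brain_mask)
  par <- ph$gray_mask | ph$white_mask
  purrr::map_dfr(
    c("coarse", "fine", "functional", "vascular"),
    function(at) {
      a <- ph[[paste0("atlas_", at)]]
      tb <- atlas_region_names(at)
      counts <- tabulate(a[a > 0], nbins = max(tb$label))
      pcounts <- tabulate(a[a > 0 & par], nbins = max(tb$label))
      tb$volume_cc <- counts[tb$label] * vv
      tb$parenchyma_cc <- pcounts[tb$label] * vv
      tb$atlas <- at
      tb[, c("atlas", "label", "name", "partner", "volume_cc",
        "parenchyma_cc")]
    }
  )
}

#' @export
print.bm_phantom <- function(x, ...) {
  cat(sprintf(
    "<bm_phantom> %s voxels @ %g mm | brain %.0f cc (gray %.0f, white %.0f) | seed %d\n",
    paste(x$shape, collapse = "x"), x$spacing_mm,
    sum(x$brain_mask) * voxel_volume_cc(x$brain_mask),
    sum(x$gray_mask) * voxel_volume_cc(x$brain_mask),
    sum(x$white_mask) * voxel_volume_cc(x$brain_mask), x$seed
  ))
  invisible(x)
}

#' Parenchyma mask of a phantom (gray + white matter)
#' @param phantom A `bm_phantom`.
#' @export
phantom_parenchyma <- function(phantom) {
  volume3d(
    array(phantom$gray_mask | phantom$white_mask, phantom$shape),
    rep(phantom$spacing_mm, 3)
  )
}

#' Look up atlas labels by region name
#' @param phantom A `bm_phantom`.
#' @param regions Character region names (or integer labels, passed through).
#' @param atlas Atlas name: "coarse", "fine", "functional" or "vascular".
#' @export
region_labels <- function(phantom, regions, atlas = "coarse") {
  tb <- phantom$region_table[phantom$region_table$atlas == atlas, ]
  if (is.numeric(regions)) {
    bad <- setdiff(regions, tb$label)
    if (length(bad)) {
      stop("unknown ", atlas, " labels: ", paste(bad, collapse = ", "),
        "; valid labels are ", paste(tb$label, collapse = ", "),
        call. = FALSE
      )
    }
    return(as.integer(regions))
  }
  # names may be given without laterality suffix -> both sides
  out <- integer(0)
  for (r in regions) {
    hit <- tb$label[tb$name == r]
    if (!length(hit)) hit <- tb$label[grepl(paste0("^", r, "_(left|right)$"), tb$name)]
    if (!length(hit)) {
      stop("unknown region '", r, "' in the ", atlas, " atlas; valid names: ",
        paste(tb$name, collapse = ", "),
        call. = FALSE
      )
    }
    out <- c(out, hit)
  }
  sort(unique(out))
}
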