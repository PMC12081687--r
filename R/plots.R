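#' Plot an axial slice of a risk map
#'
#' @param object A `bm_riskmap`.
#' @param slice Axial (third-axis) slice index; defaults to the slice
#'   holding the count maximum.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bm_riskmap <- function(object, slice = NULL, ...) {
  counts <- object$counts
  if (is.null(slice)) {
    slice <- arrayInd(which.max(counts), dim(counts))[3]
  }
  sl <- counts[, , slice]
  df <- tidyr::expand_grid(
    i = seq_len(nrow(sl)), j = seq_len(ncol(sl))
  )
  df$count <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Cumulative lesion count, axial slice %d", slice),
      subtitle = sprintf("N = %d patients, L = %d lesions, C_max = %d",
        object$n_patients, object$n_lesions, object$c_max),
      fill = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Plot regional contribution with cross-site confidence intervals
#'
#' @param object A `bm_region_stats` tibble.
#' @param what `"percent"` (site-mean percent contribution) or `"density"`
#'   (enrichment ratio).
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.bm_region_stats <- function(object, what = c("percent", "density"),
                                     ...) {
  what <- match.arg(what)
  df <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(
    .data[[if (what == "percent") "site_mean" else "density"]]))
  df$region <- factor(df$region, levels = rev(df$region))
  if (what == "percent") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$site_mean, .data$region)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
        height = 0.3
      ) +
      ggplot2::labs(x = "% of lesions (mean over sites, 95% CI)", y = NULL)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$density, .data$region)) +
      ggplot2::geom_col(fill = "darkorange") +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::labs(x = "density enrichment ratio (1 = uniform)", y = NULL)
  }
  p + ggplot2::theme_minimal()
}

#' Observed vs null interface-distance histograms
#'
#' @param observed Tibble from [observed_histogram()].
#' @param null Tibble from [null_histogram()].
#' @return A ggplot.
#' @export
plot_interface_histograms <- function(observed, null) {
  df <- dplyr::left_join(observed, null, by = c("bin_start", "bin_end"))
  df <- tidyr::pivot_longer(df,
    c("observed_fraction", "null_fraction"),
    names_to = "series", values_to = "fraction"
  )
  df$series <- ifelse(df$series == "observed_fraction",
    "lesion centroids", "tissue volume (null)")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_start, .data$fraction,
    color = .data$series)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(
      x = "distance to gray-white interface (mm)",
      y = "fraction per 0.5 mm bin", color = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Coverage vs spared-volume tradeoff plot
#'
#' @param tradeoff Tibble from [tradeoff_curve()].
#' @return A ggplot.
#' @export
plot_tradeoff <- function(tradeoff) {
  ggplot2::ggplot(tradeoff, ggplot2::aes(
    100 * .data$spared_volume_fraction, .data$coverage_pct,
    label = .data$plan
  )) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 3, color = "firebrick") +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(
      x = "% of brain volume spared",
      y = "expected lesion coverage (%)"
    ) +
    ggplot2::ylim(NA, 102) +
    ggplot2::theme_minimal()
}
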