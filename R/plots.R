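#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Polar composition plot of canonical-network overlap
#'
#' @param object An [overlap_profile()] tibble (class `fcnm_overlap`) or
#'   the long table from [profile_report()].
#' @param polar Draw on polar coordinates (default `TRUE`), the
#'   conventional display for network composition.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcnm_overlap
#' @export
autoplot.fcnm_overlap <- function(object, polar = TRUE, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$proportion, fill = .data$label
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~network) +
    ggplot2::labs(
      x = NULL, y = "proportion of network voxels",
      title = "Canonical-network composition"
    ) +
    ggplot2::theme_minimal()
  if (polar) p <- p + ggplot2::coord_polar()
  p
}

#' Lollipop plot of neurotransmitter associations
#'
#' Fisher-z Spearman correlation per receptor/transporter map, FDR-passing
#' associations highlighted.
#'
#' @param object An `fcnm_molecular` tibble from [molecular_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcnm_molecular
#' @export
autoplot.fcnm_molecular <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$map <- factor(df$map, levels = df$map[order(df$rho_z)])
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rho_z, y = .data$map, colour = .data$significant
  )) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rho_z, yend = .data$map)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#C0392B", `FALSE` = "grey55"),
      name = "FDR significant"
    ) +
    ggplot2::labs(
      x = "Fisher-z Spearman rho (gray-matter adjusted)", y = NULL,
      title = "Neurotransmitter association screen"
    ) +
    ggplot2::theme_minimal()
}

#' Axial montage of a probability or scalar map
#'
#' @param map An `fcnm_map`.
#' @param slices Axial (z) slice indices; default: four evenly spaced
#'   in-mask slices.
#' @return A ggplot of tiles, one facet per slice.
#' @export
plot_map_slices <- function(map, slices = NULL) {
  dims <- map$grid$dim
  if (is.null(slices)) {
    zs <- which(apply(map$grid$mask, 3, any))
    slices <- unique(round(stats::quantile(zs, c(0.2, 0.4, 0.6, 0.8))))
  }
  df <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(
      i = rep(seq_len(dims[1]), dims[2]),
      j = rep(seq_len(dims[2]), each = dims[1]),
      value = as.numeric(map$data[, , z]),
      slice = paste0("z = ", z)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = map$kind) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Dice comparison bar plot
#'
#' @param dice_table Tibble of Dice rows (e.g. from [radius_sensitivity()]).
#' @param benchmark Reference line (default 0.5, the meaningful-overlap
#'   convention).
#' @return A ggplot.
#' @export
plot_dice <- function(dice_table, benchmark = 0.5) {
  df <- tibble::as_tibble(dice_table)
  df$comparison <- paste(df$id_a, "vs", df$id_b)
  if ("radius_mm" %in% names(df)) {
    df$comparison <- paste0(df$comparison, " (", df$radius_mm, " mm)")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$dice)) +
    ggplot2::geom_col(fill = "#2C3E50") +
    ggplot2::geom_hline(yintercept = benchmark, linetype = "dashed", colour = "#C0392B") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Dice coefficient", title = "Spatial overlap") +
    ggplot2::theme_minimal()
}
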