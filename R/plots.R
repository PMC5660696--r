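#' Plot an ion-channel image
#'
#' Raster plot of one channel of the plane-accumulated stack, on a
#' square-root count scale (ion images are Poisson; the square root
#' stabilises the variance and keeps dim background visible).
#'
#' @param object An [ion_count_stack()].
#' @param channel One of [ion_channels]; default the CN- detection channel.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ion_count_stack <- function(object, channel = "12C14N", ...) {
  channel <- match.arg(channel, ion_channels)
  img <- accumulate_planes(object)[[channel]]
  df <- tidyr::expand_grid(
    row = seq_len(nrow(img)), col = seq_len(ncol(img))
  )
  df$counts <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = sqrt(.data$counts))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = expression(sqrt(counts))) +
    ggplot2::labs(
      x = "column (px)", y = "row (px)",
      title = paste0(channel, "- accumulated counts")
    )
}

#' Boxplot of per-cell values by treatment with significance letters
#'
#' Mirrors the standard presentation of single-cell SIP results: one box per
#' treatment with the compact-letter display of the pairwise Van der Waerden
#' tests above each box (treatments sharing a letter are not significantly
#' different).
#'
#' @param data Data frame of per-cell values.
#' @param value,treatment Column names (strings) of the response and the
#'   treatment label.
#' @param alpha,correction Passed to [pairwise_letters()].
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_treatment_boxes <- function(data, value, treatment = "treatment",
                                 alpha = 0.05, correction = "holm",
                                 ylab = value) {
  gs <- grouped_samples(data, value_col = value, group_col = treatment)
  ld <- pairwise_letters(gs, alpha = alpha, correction = correction)
  tops <- gs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(top = max(.data$value), n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(ld$letters, by = "group")
  pad <- 0.05 * diff(range(gs$value))
  ggplot2::ggplot(gs, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(
      data = tops,
      ggplot2::aes(.data$group, .data$top + pad, label = .data$letters),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "treatment", y = ylab)
}

#' Per-treatment C-N regression plot
#'
#' Scatter of nitrogen against carbon isotope signal per cell with one
#' least-squares line per treatment — the visual companion of
#' [ancova_slopes()].
#'
#' @param data Data frame of per-cell values.
#' @param x,y,treatment Column names (strings).
#' @return A ggplot.
#' @export
plot_cn_regression <- function(data, x = "delta_C", y = "delta_N",
                               treatment = "treatment") {
  df <- tibble::tibble(
    x = data[[x]], y = data[[y]], treatment = data[[treatment]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$treatment)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
      linewidth = 0.6
    ) +
    ggplot2::labs(x = x, y = y)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
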