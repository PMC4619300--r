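#' Plot a confocal frame
#'
#' Grayscale raster of the frame in physical coordinates, y increasing
#' downwards as in image convention.
#'
#' @param object A [confocal_frame()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confocal_frame <- function(object, ...) {
  s <- object$pixel_size_um
  df <- expand.grid(
    y = (seq_len(nrow(object$pixels)) - 1) * s,
    x = (seq_len(ncol(object$pixels)) - 1) * s
  )
  df$value <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = object$specimen_id)
}

#' Plot a Voronoi tessellation
#'
#' Clipped Voronoi cells over the nucleus centres; boundary (non-interior)
#' cells, which are excluded from ENC and 3NDND, are drawn hollow.
#'
#' @param object A [build_tessellation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tessellation <- function(object, ...) {
  polys <- purrr::imap_dfr(object$tiles, function(tp, i) {
    purrr::imap_dfr(tp, function(p, k) {
      tibble(x = p$x, y = p$y, cell = i, ring = paste(i, k),
             interior = object$interior[i])
    })
  })
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(.data$x, .data$y, group = .data$ring, fill = .data$interior),
      colour = "grey30", linewidth = 0.2, alpha = 0.4
    ) +
    ggplot2::geom_point(
      data = object$points, ggplot2::aes(.data$x, .data$y), size = 0.6
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = NA),
                               na.value = NA, guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' Box plots of the four QTP features by group
#'
#' The standard summary figure: one panel per feature, groups on the x axis
#' in disease order.
#'
#' @param features Feature tibble (rows from [compute_qtp()]) with a group
#'   column.
#' @param group Tidy-eval column giving the grouping (default `truth`).
#' @return A ggplot.
#' @export
plot_qtp_features <- function(features, group = truth) {
  g <- rlang::enquo(group)
  long <- features |>
    dplyr::mutate(.group = collapse_grade(rlang::eval_tidy(g, features))) |>
    tidyr::pivot_longer(
      cols = c("nuclear_area_um2", "cell_density_per_mm2", "enc_ratio", "nddn3_um"),
      names_to = "feature", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$.group, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
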