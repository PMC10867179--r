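#' Overlay plot of an ROI
#'
#' Shows a background channel as a raster with vessel centroids (colored by
#' subtype, HEV-like flagged by shape) and, optionally, cell centroids
#' colored by class. Intended for quick QC of a segmented ROI.
#'
#' @param stack A [channel_stack()].
#' @param vessels Classified vessel table (optional).
#' @param cells Gated cell table (optional).
#' @param background Marker to show underneath (default hematoxylin).
#' @param downsample Integer stride for the raster (default 4).
#' @return A ggplot object.
#' @export
plot_roi_overlay <- function(stack, vessels = NULL, cells = NULL,
                             background = "hematoxylin", downsample = 4L) {
  ch <- stack$channels[[background]]
  if (is.null(ch)) abort(paste0("no channel '", background, "'"))
  ri <- seq(1L, nrow(ch), by = downsample)
  ci <- seq(1L, ncol(ch), by = downsample)
  df <- tidyr::expand_grid(row = ri, col = ci)
  df$value <- ch[cbind(df$row, df$col)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$col, y = .data$row,
                                                 fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "grey90",
                                 name = background) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = paste0("ROI ", stack$roi_id)) +
    ggplot2::theme_minimal()
  if (!is.null(cells) && nrow(cells)) {
    p <- p + ggplot2::geom_point(
      data = cells,
      ggplot2::aes(x = .data$col_px, y = .data$row_px, color = .data$class),
      size = 0.6, alpha = 0.8)
  }
  if (!is.null(vessels) && nrow(vessels)) {
    p <- p + ggplot2::geom_point(
      data = vessels,
      ggplot2::aes(x = .data$col_px, y = .data$row_px,
                   color = .data$subtype,
                   shape = .data$hev_like), size = 3, stroke = 1.2) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 8),
                                  name = "HEV-like")
  }
  p
}

#' Bar chart of per-region densities
#'
#' @param densities A [cell_densities()] tibble (or any tibble with
#'   `class`/`subtype`, `region`, `density_per_mm2`).
#' @return A ggplot object.
#' @export
plot_region_densities <- function(densities) {
  grp <- if ("class" %in% names(densities)) "class" else "subtype"
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = .data[[grp]], y = .data$density_per_mm2,
                               fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "density (per mm²)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Heatmap of inflammatory subtypes
#'
#' Row-scaled leukocyte-density profiles ordered by the clustering
#' dendrogram, annotated with the subtype labels.
#'
#' @param object An [inflammatory_subtypes()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inflam_subtypes <- function(object, ...) {
  sc <- object$scaled[object$order, , drop = FALSE]
  df <- as_tibble(sc, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "marker",
                        values_to = "z") |>
    mutate(sample_id = factor(.data$sample_id,
                              levels = rownames(sc)),
           subtype = factor(object$labels[as.character(.data$sample_id)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$marker,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "row z") +
    ggplot2::facet_grid(. ~ subtype, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
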