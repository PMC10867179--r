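#' Segment single cells from the hematoxylin channel
#'
#' Nuclei are detected by Gaussian smoothing, local background removal
#' (white top-hat, so diffuse parenchymal hematoxylin does not drown the
#' nuclei), Otsu binarization and a distance-transform watershed to split
#' touching nuclei. For every nucleus the mean intensity of each available
#' marker channel is measured over the nucleus dilated by `halo_px` pixels
#' (a membrane/cytoplasm proxy, since the chromogenic markers here are not
#' nuclear); dilated footprints of neighboring cells are kept disjoint by
#' geodesic label propagation. Nuclei outside the `[10, 200]` um^2 sanity
#' band are flagged `size_flag`, not dropped.
#'
#' @param stack A [channel_stack()] with a `hematoxylin` channel.
#' @param masks Optional [make_region_masks()] result; when given, each cell
#'   is assigned IT/PT by its nucleus pixels (cells wholly outside tissue
#'   are excluded and counted in attribute `removed`).
#' @param sigma Gaussian smoothing sd in px.
#' @param tophat_radius_px Top-hat disc radius (must exceed the nucleus
#'   radius; default 12).
#' @param halo_px Dilation of the nucleus for intensity measurement.
#' @param min_area_um2 Minimum nucleus area retained (debris filter).
#' @param tolerance Watershed merge tolerance.
#' @return Tibble, one row per cell: `cell_id`, `row_px`, `col_px`,
#'   `nucleus_area_um2`, `size_flag`, `region` (if masks given) and
#'   `mean_<marker>` intensity columns. Label matrix in attribute `label`.
#' @export
segment_cells <- function(stack, masks = NULL, sigma = 1,
                          tophat_radius_px = 12, halo_px = 2,
                          min_area_um2 = 5, tolerance = 1) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!"hematoxylin" %in% names(stack$channels))
    abort("missing required channel(s): hematoxylin")
  ps <- stack$pixel_size
  hema <- stack$channels$hematoxylin
  if (diff(range(hema)) == 0)
    return(empty_cell_table(stack, masks))
  sm <- EBImage::gblur(hema, sigma = sigma)
  sm <- preprocess_channel(matrix(pmax(as.numeric(sm), 0), nrow(hema)),
                           median = FALSE,
                           tophat_radius_px = tophat_radius_px)
  bz <- binarize_channel(sm)
  if (!any(bz$mask)) return(empty_cell_table(stack, masks))
  dm <- EBImage::distmap(bz$mask)
  lab <- EBImage::watershed(dm, tolerance = tolerance)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  objs <- label_pixels(lab)
  objs <- objs[lengths(objs) * ps^2 >= min_area_um2]
  if (!length(objs)) return(empty_cell_table(stack, masks))
  # disjoint dilated footprints via geodesic propagation of nucleus labels
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(objs)) lab2[objs[[i]]] <- i
  halo <- EBImage::dilate(lab2 > 0,
                          EBImage::makeBrush(2L * halo_px + 1L, "disc"))
  grown <- EBImage::propagate(matrix(0, nrow(lab), ncol(lab)),
                              seeds = lab2, mask = halo > 0)
  grown <- matrix(as.integer(grown), nrow(lab), ncol(lab))
  gobjs <- label_pixels(grown)

  nr <- nrow(lab)
  cen <- t(vapply(objs, centroid_rc, numeric(2), nrow = nr))
  area <- unname(lengths(objs)) * ps^2
  markers <- intersect(cell_profile_markers(), names(stack$channels))
  ints <- purrr::map(stack$channels[markers], function(chan) {
    vapply(seq_along(objs), function(i) {
      g <- gobjs[[as.character(i)]]
      mean(chan[if (is.null(g)) objs[[i]] else g])
    }, numeric(1))
  })
  tbl <- tibble(cell_id = seq_along(objs),
                row_px = cen[, 1], col_px = cen[, 2],
                nucleus_area_um2 = area,
                size_flag = area < 10 | area > 200,
                !!!stats::setNames(ints, sprintf("mean_%s", markers)))
  removed <- 0L
  if (!is.null(masks)) {
    reg <- vapply(objs, region_of_pixels, character(1), masks = masks)
    removed <- sum(is.na(reg))
    tbl$region <- reg
    tbl <- tbl[!is.na(reg), , drop = FALSE]
    tbl$cell_id <- seq_len(nrow(tbl))
  }
  attr(tbl, "label") <- lab2
  attr(tbl, "removed") <- removed
  attr(tbl, "pixel_size") <- ps
  tbl
}

empty_cell_table <- function(stack, masks) {
  markers <- intersect(cell_profile_markers(), names(stack$channels))
  tbl <- tibble(cell_id = integer(), row_px = numeric(), col_px = numeric(),
                nucleus_area_um2 = numeric(), size_flag = logical(),
                !!!stats::setNames(purrr::map(markers, ~numeric()),
                                   sprintf("mean_%s", markers)))
  if (!is.null(masks)) tbl$region <- character()
  attr(tbl, "pixel_size") <- stack$pixel_size
  tbl
}

#' Gate cells into mutually exclusive leukocyte classes
#'
#' Priority gating over per-cell mean intensities: CD68 above threshold
#' takes the macrophage class without requiring CD45 (myeloid cells stain
#' weakly for CD45 and are gated separately); otherwise CD45+ cells split
#' into CD8 T cells, CD20 B cells, or other CD45+ leukocytes; everything
#' else is a non-leukocyte. Cells eligible for more than one lineage are
#' assigned to the lineage whose marker has the highest z-scored intensity
#' (logged). Thresholds default to a per-marker Otsu over the cell means,
#' with the separation guard declaring a marker absent rather than slicing
#' noise.
#'
#' @param cells A [segment_cells()] table with `mean_CD45`, `mean_CD8`,
#'   `mean_CD20`, `mean_CD68` columns.
#' @param thresholds Optional named numeric vector (CD45, CD8, CD20, CD68);
#'   any missing entry is derived by Otsu.
#' @param min_separation Separation guard for derived thresholds, in
#'   background-SD units.
#' @return The input tibble with a `class` factor column (levels
#'   [cell_classes()]) and a `multi_lineage` flag.
#' @export
gate_cells <- function(cells, thresholds = NULL, min_separation = 4) {
  need <- paste0("mean_", c("CD45", "CD8", "CD20", "CD68"))
  missing <- setdiff(need, names(cells))
  if (length(missing))
    abort(paste0("missing intensity column(s): ",
                 paste(missing, collapse = ", ")))
  if (nrow(cells) == 0) {
    cells$class <- factor(character(), levels = cell_classes())
    cells$multi_lineage <- logical()
    return(cells)
  }
  mk <- c("CD45", "CD8", "CD20", "CD68")
  thr <- purrr::map_dbl(stats::setNames(mk, mk), function(m) {
    if (!is.null(thresholds) && m %in% names(thresholds))
      return(thresholds[[m]])
    derive_cell_threshold(cells[[paste0("mean_", m)]], min_separation)
  })
  z <- purrr::map(stats::setNames(mk, mk), function(m) {
    v <- cells[[paste0("mean_", m)]]
    if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, length(v))
  })
  cd45 <- cells$mean_CD45 >= thr["CD45"]
  elig <- cbind(CD8_T = cd45 & cells$mean_CD8 >= thr["CD8"],
                B_CELL = cd45 & cells$mean_CD20 >= thr["CD20"],
                MACROPHAGE = cells$mean_CD68 >= thr["CD68"])
  zmat <- cbind(CD8_T = z$CD8, B_CELL = z$CD20, MACROPHAGE = z$CD68)
  n_elig <- rowSums(elig)
  cls <- ifelse(cd45, "OTHER_CD45", "NON_LEUKOCYTE")
  pick <- which(n_elig >= 1L)
  if (length(pick)) {
    zz <- zmat[pick, , drop = FALSE]
    zz[!elig[pick, , drop = FALSE]] <- -Inf
    cls[pick] <- colnames(elig)[max.col(zz, ties.method = "first")]
  }
  if (any(n_elig > 1L))
    inform(sprintf(
      "%d cell(s) above threshold for multiple lineages assigned by z-score",
      sum(n_elig > 1L)))
  cells$class <- factor(cls, levels = cell_classes())
  cells$multi_lineage <- n_elig > 1L
  attr(cells, "thresholds") <- thr
  cells
}

# Otsu over a vector of cell means with a separation guard; Inf = marker
# absent from this ROI
derive_cell_threshold <- function(v, min_separation = 4) {
  if (length(unique(v)) < 3L || diff(range(v)) == 0) return(Inf)
  t <- tryCatch(otsu_image(matrix(v, 1), n_bins = min(256L, length(v))),
                error = function(e) Inf)
  if (!is.finite(t)) return(Inf)
  fg <- v > t
  if (!any(fg) || all(fg)) return(Inf)
  sd_bg <- stats::sd(v[!fg])
  if (is.finite(sd_bg) && sd_bg > 0 &&
      (mean(v[fg]) - mean(v[!fg])) < min_separation * sd_bg) return(Inf)
  t
}

#' Per-class, per-region cell densities
#'
#' Density = cell count in region / region area (cells/mm^2). Regions with
#' zero area yield `NA`, never a division error; every class in
#' [cell_classes()] is reported in both regions even when absent.
#'
#' @param cells A gated cell table with `class` and `region` columns.
#' @param masks A [make_region_masks()] result.
#' @return Tibble (class, region, n, area_mm2, density_per_mm2).
#' @export
cell_densities <- function(cells, masks) {
  stopifnot(inherits(masks, "region_masks"))
  grid <- tidyr::expand_grid(class = cell_classes(), region = c("IT", "PT"))
  counts <- cells |>
    mutate(class = as.character(.data$class)) |>
    count(.data$class, .data$region)
  out <- grid |>
    left_join(counts, by = c("class", "region")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           area_mm2 = region_area(masks, .data$region),
           density_per_mm2 = ifelse(.data$area_mm2 > 0,
                                    .data$n / .data$area_mm2, NA_real_))
  as_tibble(out)
}
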