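#' Region masks for one ROI
#'
#' Boolean tissue, intratumoral (IT) and peritumoral (PT) masks on the ROI
#' pixel grid, with areas in mm^2. The invariants are enforced on
#' construction: IT is a subset of tissue (clipped and logged otherwise) and
#' PT is exactly `tissue & !IT`, so IT and PT partition the tissue pixels.
#'
#' @param tissue,intratumoral Logical matrices of identical dimensions.
#' @param pixel_size um/px.
#' @return A `region_masks` object with elements `tissue`, `intratumoral`,
#'   `peritumoral`, `pixel_size` and an `areas` tibble (region, area_mm2).
#' @export
make_region_masks <- function(tissue, intratumoral, pixel_size) {
  stopifnot(is.matrix(tissue), is.matrix(intratumoral),
            all(dim(tissue) == dim(intratumoral)), pixel_size > 0)
  tissue <- tissue != 0
  intratumoral <- intratumoral != 0
  if (any(intratumoral & !tissue)) {
    inform(sprintf(
      "intratumoral mask clipped to tissue (%d px outside tissue)",
      sum(intratumoral & !tissue)))
    intratumoral <- intratumoral & tissue
  }
  peritumoral <- tissue & !intratumoral
  areas <- tibble(
    region = c("tissue", "IT", "PT"),
    area_mm2 = px_to_mm2(c(sum(tissue), sum(intratumoral), sum(peritumoral)),
                         pixel_size))
  structure(list(tissue = tissue, intratumoral = intratumoral,
                 peritumoral = peritumoral, pixel_size = pixel_size,
                 areas = areas),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat("<region_masks>", nrow(x$tissue), "x", ncol(x$tissue), "px\n")
  print(x$areas)
  invisible(x)
}

region_area <- function(masks, region) {
  masks$areas$area_mm2[match(region, masks$areas$region)]
}

#' Alternating sequential filter
#'
#' Morphological smoothing by closing-then-opening with disc structuring
#' elements of increasing radius. Suppresses speckle (isolated single cells,
#' debris) at scales up to the largest radius while preserving larger
#' structures; applied to S100 before thresholding tumor nests.
#'
#' @param x Numeric matrix.
#' @param radii Integer radii schedule in pixels (default 1, 2, 3).
#' @return Filtered matrix.
#' @export
alternating_sequential_filter <- function(x, radii = c(1, 2, 3)) {
  stopifnot(is.matrix(x))
  for (r in radii) {
    b <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
    x <- EBImage::opening(EBImage::closing(x, b), b)
    x <- matrix(as.numeric(x), nrow(x), ncol(x))
  }
  x
}

#' Segment tissue from the hematoxylin channel
#'
#' Tissue is everything above the triangle threshold of the hematoxylin
#' histogram, hole-filled, with specks below a minimum area removed. An ROI
#' whose hematoxylin yields an empty mask gets a warning; downstream
#' densities over its regions are reported as missing.
#'
#' @param hema Non-negative numeric matrix (hematoxylin channel; the caller
#'   must supply nuclei-bright contrast, pre-inverting brightfield images if
#'   needed).
#' @param pixel_size um/px.
#' @param min_speck_area_um2 Components smaller than this are dropped.
#' @return Logical tissue mask.
#' @export
segment_tissue <- function(hema, pixel_size, min_speck_area_um2 = 100) {
  stopifnot(is.matrix(hema), all(hema >= 0))
  if (diff(range(hema)) == 0) {
    warn("hematoxylin channel is constant: empty tissue mask")
    return(matrix(FALSE, nrow(hema), ncol(hema)))
  }
  thr <- triangle_image(hema)
  mask <- hema > thr
  if (!any(mask)) {
    warn("empty tissue mask: no pixels above triangle threshold")
    return(mask)
  }
  mask <- EBImage::fillHull(mask) > 0
  drop_small_components(mask, min_speck_area_um2 / pixel_size^2)
}

#' Segment intratumoral area from the S100 channel
#'
#' Tumor nests are S100+ area detected by an alternating sequential filter
#' followed by triangle thresholding; connected components smaller than
#' `min_nest_area_um2` are removed so that single S100+ cells (Langerhans
#' cells, dendritic cells, macrophages, neural cells) do not define tumor
#' area. Components of exactly the minimum area are kept. If a tissue mask
#' is supplied the result is intersected with it.
#'
#' @param s100 Non-negative numeric matrix.
#' @param pixel_size um/px.
#' @param min_nest_area_um2 Minimum nest area retained (default 500 um^2).
#' @param tissue Optional logical tissue mask.
#' @param radii ASF radii schedule in px.
#' @return Logical intratumoral mask.
#' @export
segment_tumor <- function(s100, pixel_size, min_nest_area_um2 = 500,
                          tissue = NULL, radii = c(1, 2, 3)) {
  stopifnot(is.matrix(s100), all(s100 >= 0))
  if (diff(range(s100)) == 0)
    return(matrix(FALSE, nrow(s100), ncol(s100)))
  f <- alternating_sequential_filter(s100, radii)
  if (diff(range(f)) == 0)
    return(matrix(FALSE, nrow(s100), ncol(s100)))
  mask <- f > triangle_image(f)
  mask <- drop_small_components(mask, min_nest_area_um2 / pixel_size^2)
  if (!is.null(tissue)) mask <- mask & (tissue != 0)
  mask
}

# remove 8-connected components with pixel count < min_px (>= kept)
drop_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
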