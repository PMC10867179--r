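#' Classify an ROI as CD8-infiltrated or excluded
#'
#' Uses the ratio of intratumoral to peritumoral CD8 T-cell density:
#' INFILTRATED when `it / pt >= cutoff` (default 1), EXCLUDED otherwise. A
#' tumor with intratumoral CD8s but an empty peritumoral compartment is
#' INFILTRATED; with neither (or a missing region) the call is UNDEFINED.
#' The classification is invariant to common rescaling of both densities.
#'
#' @param cd8_it_density,cd8_pt_density Densities (cells/mm^2), `NA` when a
#'   region is missing.
#' @param cutoff Ratio cutoff (default 1.0).
#' @return Tibble with `ratio` and `infiltration`
#'   (INFILTRATED/EXCLUDED/UNDEFINED).
#' @export
classify_infiltration <- function(cd8_it_density, cd8_pt_density,
                                  cutoff = 1.0) {
  it <- cd8_it_density; pt <- cd8_pt_density
  if (is.na(it) || is.na(pt) || (it == 0 && pt == 0))
    return(tibble(ratio = NA_real_, infiltration = "UNDEFINED"))
  if (pt == 0)
    return(tibble(ratio = Inf, infiltration = "INFILTRATED"))
  r <- it / pt
  tibble(ratio = r,
         infiltration = if (r >= cutoff) "INFILTRATED" else "EXCLUDED")
}

#' Detect tertiary lymphoid structures
#'
#' TLS are defined by co-aggregation of CD8 T cells and CD20 B cells:
#' single-linkage clusters (all links within `link_radius_um`) over the
#' union of CD8_T and B_CELL cells, kept when they contain at least
#' `min_cd8` T cells and `min_cd20` B cells. Cluster membership is monotone
#' in the link radius. The region is taken at the cluster centroid.
#'
#' @param cells Gated cell table (`class`, `row_px`, `col_px`, and `region`
#'   or a `masks` argument).
#' @param pixel_size um/px (taken from the table attribute if absent).
#' @param link_radius_um Single-linkage radius (default 50 um).
#' @param min_cd8,min_cd20 Minimum member counts (default 10 each).
#' @param masks Optional [make_region_masks()] for centroid regions.
#' @return Tibble, one row per TLS: `tls_id`, `n_cd8`, `n_cd20`, centroid
#'   (`x_um`, `y_um`), `radius_um` (max member distance to centroid),
#'   `region`; member cell ids in list-columns `cd8_ids`, `cd20_ids`.
#' @export
detect_tls <- function(cells, pixel_size = NULL, link_radius_um = 50,
                       min_cd8 = 10, min_cd20 = 10, masks = NULL) {
  ps <- pixel_size %||% attr(cells, "pixel_size") %||%
    abort("pixel_size required")
  lymph <- filter(cells, .data$class %in% c("CD8_T", "B_CELL"))
  empty <- tibble(tls_id = integer(), n_cd8 = integer(), n_cd20 = integer(),
                  x_um = numeric(), y_um = numeric(), radius_um = numeric(),
                  region = character(), cd8_ids = list(), cd20_ids = list(),
                  member_xy = list())
  if (nrow(lymph) == 0) return(empty)
  xy <- cbind(x = lymph$col_px * ps, y = lymph$row_px * ps)
  cl <- if (nrow(lymph) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"),
                  h = link_radius_um)
  out <- purrr::map_dfr(unique(cl), function(k) {
    mem <- lymph[cl == k, ]
    n8 <- sum(mem$class == "CD8_T"); n20 <- sum(mem$class == "B_CELL")
    if (n8 < min_cd8 || n20 < min_cd20) return(NULL)
    cx <- mean(mem$col_px * ps); cy <- mean(mem$row_px * ps)
    reg <- if (!is.null(masks)) {
      pr <- round(cy / ps); pc <- round(cx / ps)
      if (pr >= 1 && pr <= nrow(masks$tissue) && pc >= 1 &&
          pc <= ncol(masks$tissue) && masks$intratumoral[pr, pc]) "IT"
      else "PT"
    } else if ("region" %in% names(mem)) {
      names(sort(table(mem$region), decreasing = TRUE))[1]
    } else NA_character_
    tibble(n_cd8 = n8, n_cd20 = n20, x_um = cx, y_um = cy,
           radius_um = max(sqrt((mem$col_px * ps - cx)^2 +
                                  (mem$row_px * ps - cy)^2)),
           region = reg,
           cd8_ids = list(mem$cell_id[mem$class == "CD8_T"]),
           cd20_ids = list(mem$cell_id[mem$class == "B_CELL"]),
           member_xy = list(xy[cl == k, , drop = FALSE]))
  })
  if (nrow(out) == 0) return(empty)
  mutate(out, tls_id = row_number(), .before = 1)
}

#' Associate vessels with TLS
#'
#' A vessel is associated with a TLS when its centroid lies within
#' `assoc_radius_um` of the convex hull of the aggregate's member cells
#' (vessels at the aggregate margin sit just outside the hull). Populates
#' per-TLS lists of associated HEV-like vessel ids and PDPN+ lymphatic
#' vessel ids, and returns the per-ROI counts used to correlate TLS burden
#' with HEV-like vessel burden.
#'
#' @param tls A [detect_tls()] table.
#' @param vessels A classified vessel table ([classify_vessels()]).
#' @param pixel_size um/px.
#' @param assoc_radius_um Association distance to the hull (default 100).
#' @return List: `tls` (input plus `hev_ids`, `pdpn_ids` list-columns and
#'   counts) and `counts` (tibble: n_tls, n_hev_vessels,
#'   n_tls_with_hev, n_tls_with_pdpn).
#' @export
associate_tls_vessels <- function(tls, vessels, pixel_size,
                                  assoc_radius_um = 100) {
  hev <- vessels[["hev_like"]] %||% rep(FALSE, nrow(vessels))
  lymph <- as.character(vessels$subtype) %in% lymphatic_subtypes()
  vx <- vessels$col_px * pixel_size
  vy <- vessels$row_px * pixel_size
  if (nrow(tls)) {
    assoc <- purrr::map(seq_len(nrow(tls)), function(i) {
      pts <- tls$member_xy[[i]]
      hull <- pts[grDevices::chull(pts), , drop = FALSE]
      d <- vapply(seq_len(nrow(vessels)), function(j) {
        dist_point_polygon(c(vx[j], vy[j]), hull)
      }, numeric(1))
      which(d <= assoc_radius_um)
    })
    tls$hev_ids <- purrr::map(assoc, ~ vessels$vessel_id[intersect(.x, which(hev))])
    tls$pdpn_ids <- purrr::map(assoc, ~ vessels$vessel_id[intersect(.x, which(lymph))])
    tls$n_hev_assoc <- lengths(tls$hev_ids)
    tls$n_pdpn_assoc <- lengths(tls$pdpn_ids)
  }
  counts <- tibble(n_tls = nrow(tls),
                   n_hev_vessels = sum(hev),
                   n_tls_with_hev = if (nrow(tls)) sum(tls$n_hev_assoc > 0) else 0L,
                   n_tls_with_pdpn = if (nrow(tls)) sum(tls$n_pdpn_assoc > 0) else 0L)
  list(tls = tls, counts = counts)
}

#' Summarize one ROI
#'
#' Collapses the vessel, cell and TLS tables of one ROI into a single wide
#' row: per-region cell-class densities, per-region vessel-subtype densities
#' (region-area denominator; whole-tissue-area densities are included as
#' `density_tissue_*`), subtype proportions within the blood (AQP1+) and
#' lymphatic (PDPN+) families, the intratumoral CD8:CD68 density ratio, the
#' CD8 IT:PT ratio with its infiltration call, and TLS/HEV counts.
#' Proportions over an empty family are `NA`, never 0/0.
#'
#' @param vessels Classified vessel table.
#' @param cells Gated cell table with `region`.
#' @param masks A [make_region_masks()] result.
#' @param tls A [detect_tls()] table (optional).
#' @param roi_id Identifier stored in the row.
#' @param infiltration_cutoff Passed to [classify_infiltration()].
#' @param pixel_size um/px for the TLS/vessel association.
#' @return One-row tibble (an `RoiSummary`).
#' @export
summarize_roi <- function(vessels, cells, masks, tls = NULL, roi_id = "roi",
                          infiltration_cutoff = 1.0, pixel_size = NULL) {
  stopifnot(inherits(masks, "region_masks"))
  ps <- pixel_size %||% attr(vessels, "pixel_size") %||% masks$pixel_size
  cd <- cell_densities(cells, masks)
  cell_wide <- cd |>
    mutate(key = paste0("density_", .data$class, "_", .data$region)) |>
    select("key", "density_per_mm2") |>
    tidyr::pivot_wider(names_from = "key", values_from = "density_per_mm2")

  vt <- vessels |> mutate(subtype = as.character(.data$subtype))
  named_subtypes <- c(blood_subtypes(), lymphatic_subtypes())
  vgrid <- tidyr::expand_grid(subtype = named_subtypes,
                              region = c("IT", "PT"))
  vcounts <- vt |> count(.data$subtype, .data$region)
  vdens <- vgrid |>
    left_join(vcounts, by = c("subtype", "region")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           area_mm2 = region_area(masks, .data$region),
           density = ifelse(.data$area_mm2 > 0, .data$n / .data$area_mm2,
                            NA_real_))
  vessel_wide <- vdens |>
    mutate(key = paste0("density_", .data$subtype, "_", .data$region)) |>
    select("key", "density") |>
    tidyr::pivot_wider(names_from = "key", values_from = "density")
  tissue_area <- region_area(masks, "tissue")
  vessel_tissue <- vt |>
    filter(.data$subtype %in% named_subtypes) |>
    count(.data$subtype) |>
    tidyr::complete(subtype = named_subtypes, fill = list(n = 0L)) |>
    mutate(key = paste0("density_tissue_", .data$subtype),
           density = ifelse(tissue_area > 0, .data$n / tissue_area,
                            NA_real_)) |>
    select("key", "density") |>
    tidyr::pivot_wider(names_from = "key", values_from = "density")

  prop_family <- function(fam, prefix) {
    n <- vapply(fam, function(s) sum(vt$subtype == s), numeric(1))
    tot <- sum(n)
    p <- if (tot > 0) n / tot else rep(NA_real_, length(fam))
    as_tibble(stats::setNames(as.list(p), paste0(prefix, fam)))
  }
  props <- bind_cols(prop_family(blood_subtypes(), "prop_blood_"),
                     prop_family(lymphatic_subtypes(), "prop_lymph_"))

  dens_of <- function(cl, reg) {
    cd$density_per_mm2[cd$class == cl & cd$region == reg]
  }
  infil <- classify_infiltration(dens_of("CD8_T", "IT"),
                                 dens_of("CD8_T", "PT"),
                                 cutoff = infiltration_cutoff)
  mac_it <- dens_of("MACROPHAGE", "IT")
  cd8_cd68 <- if (!is.na(mac_it) && mac_it > 0)
    dens_of("CD8_T", "IT") / mac_it else NA_real_

  tls <- tls %||% tibble()
  assoc <- if (nrow(tls)) {
    associate_tls_vessels(tls, vt, pixel_size = ps)$counts
  } else {
    tibble(n_tls = 0L,
           n_hev_vessels = sum(vt[["hev_like"]] %||% logical(0)),
           n_tls_with_hev = 0L, n_tls_with_pdpn = 0L)
  }
  bind_cols(
    tibble(roi_id = roi_id,
           tissue_area_mm2 = tissue_area,
           it_area_mm2 = region_area(masks, "IT"),
           pt_area_mm2 = region_area(masks, "PT"),
           n_vessels = nrow(vt), n_cells = nrow(cells)),
    cell_wide, vessel_wide, vessel_tissue, props,
    tibble(cd8_it_pt_ratio = infil$ratio,
           infiltration = infil$infiltration,
           cd8_cd68_ratio_it = cd8_cd68),
    assoc)
}
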