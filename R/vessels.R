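#' Denoise and locally flatten a marker channel
#'
#' Median denoise (3x3) followed by a white top-hat with a disc structuring
#' element: subtracts the morphological opening, removing slowly varying
#' background and illumination gradients while preserving structures
#' narrower than the disc (vessel walls, cell clusters). Output is
#' nonnegative; a flat field maps to zero.
#'
#' @param channel Non-negative numeric matrix.
#' @param median Apply the median denoise (default TRUE).
#' @param tophat_radius_px Disc radius of the top-hat in pixels; must exceed
#'   the half-width of the structures to keep (default 25).
#' @return Preprocessed matrix, same dimensions.
#' @export
preprocess_channel <- function(channel, median = TRUE, tophat_radius_px = 25) {
  stopifnot(is.matrix(channel), all(channel >= 0))
  x <- if (median) median3x3(channel) else channel
  b <- EBImage::makeBrush(2L * as.integer(tophat_radius_px) + 1L, "disc")
  th <- EBImage::whiteTopHat(x, b)
  pmax(matrix(as.numeric(th), nrow(x), ncol(x)), 0)
}

#' Segment candidate vascular objects
#'
#' Vessel candidates are found on the AQP1, CD34 and PDPN channels: each is
#' preprocessed ([preprocess_channel()]) and binarized by Otsu's method; the
#' union of the three binaries is labeled (8-connectivity) and components
#' with area outside `[min_area_um2, max_area_um2]` are removed as technical
#' artifacts or single cells. For every survivor a per-marker profile is
#' measured over the full vessel-marker panel (AQP1, CD34, aSMA, PDPN,
#' LYVE1, MECA79, panCK when present): positive-pixel coverage (fraction of
#' object pixels inside the marker's own Otsu binary) and mean preprocessed
#' intensity. PDPN-positive components whose panCK coverage exceeds
#' `panck_max_coverage` are removed as basal epithelium. Each object is
#' assigned a region (IT if strictly more than half its pixels lie in the
#' intratumoral mask, else PT; objects with no tissue overlap are excluded
#' and counted) and morphology features are attached.
#'
#' @param stack A [channel_stack()] containing at least AQP1, CD34, PDPN.
#' @param masks A [make_region_masks()] result.
#' @param min_area_um2,max_area_um2 Size filter bounds (default 100, 1e6).
#' @param panck_max_coverage panCK coverage above which a PDPN+ object is
#'   excluded (default 0.5).
#' @param coverage_min,intensity_factor Marker-positivity rule: positive if
#'   coverage >= `coverage_min` and mean intensity >= `intensity_factor`
#'   times the channel threshold (defaults 0.10 and 0.5).
#' @param tophat_radius_px,median Passed to [preprocess_channel()].
#' @param min_separation Otsu separation guard (see package docs); channels
#'   with no real signal yield no positive pixels instead of noise masks.
#' @return Tibble with one row per vessel object: `vessel_id`, centroid
#'   (`row_px`, `col_px`), `region`, `area_um2`, per-marker `coverage_*`,
#'   `mean_*`, `pos_*`, and morphology columns. The label matrix is attached
#'   as attribute `label`; counts of removed objects as attribute `removed`.
#' @export
segment_vessels <- function(stack, masks,
                            min_area_um2 = 100, max_area_um2 = 1e6,
                            panck_max_coverage = 0.5,
                            coverage_min = 0.10, intensity_factor = 0.5,
                            tophat_radius_px = 25, median = TRUE,
                            min_separation = 4) {
  stopifnot(inherits(stack, "channel_stack"), inherits(masks, "region_masks"))
  ps <- stack$pixel_size
  required <- c("AQP1", "CD34", "PDPN")
  missing <- setdiff(required, names(stack$channels))
  if (length(missing))
    abort(paste0("missing required channel(s): ",
                 paste(missing, collapse = ", ")))
  markers <- intersect(vessel_profile_markers(), names(stack$channels))
  pre <- purrr::map(stack$channels[markers], preprocess_channel,
                    median = median, tophat_radius_px = tophat_radius_px)
  bin <- purrr::map(pre, binarize_channel, min_separation = min_separation)

  fg <- Reduce(`|`, purrr::map(bin[required], "mask"))
  lab <- label8(fg)
  objs <- label_pixels(lab)
  removed <- c(size = 0L, panck = 0L, no_tissue = 0L)
  if (length(objs)) {
    apx <- lengths(objs) * ps^2
    keep <- apx >= min_area_um2 & apx <= max_area_um2
    removed["size"] <- sum(!keep)
    objs <- objs[keep]
  }
  nr <- nrow(fg)
  rows <- purrr::imap(objs, function(idx, id) {
    prof <- purrr::map(markers, function(m) {
      cov <- mean(bin[[m]]$mask[idx])
      mn <- mean(pre[[m]][idx])
      thr <- bin[[m]]$threshold
      pos <- is.finite(thr) && cov >= coverage_min &&
        mn >= intensity_factor * thr
      stats::setNames(list(cov, mn, pos),
                      paste0(c("coverage_", "mean_", "pos_"), m))
    })
    cen <- centroid_rc(idx, nr)
    tibble(row_px = cen[["row"]], col_px = cen[["col"]],
           n_px = length(idx), !!!purrr::flatten(prof))
  })
  tbl <- if (length(rows)) bind_rows(rows) else empty_vessel_table(markers)
  if (nrow(tbl)) {
    # panCK exclusion of PDPN+ basal epithelium
    if ("panCK" %in% markers) {
      drop <- tbl$pos_PDPN & tbl$coverage_panCK > panck_max_coverage
      removed["panck"] <- sum(drop)
      objs <- objs[!drop]
      tbl <- tbl[!drop, , drop = FALSE]
    }
    if (nrow(tbl)) {
      reg <- vapply(objs, region_of_pixels, character(1), masks = masks)
      removed["no_tissue"] <- sum(is.na(reg))
      if (any(is.na(reg)))
        inform(sprintf("%d object(s) entirely outside tissue excluded",
                       sum(is.na(reg))))
      objs <- objs[!is.na(reg)]
      tbl <- tbl[!is.na(reg), , drop = FALSE]
      reg <- reg[!is.na(reg)]
      morph <- purrr::map_dfr(objs, compute_morphology, dim = dim(fg),
                              pixel_size = ps)
      tbl <- bind_cols(
        tibble(vessel_id = seq_len(nrow(tbl)), region = reg),
        tbl, morph)
    }
  }
  # rebuild label image over surviving objects
  lab2 <- matrix(0L, nr, ncol(fg))
  for (i in seq_along(objs)) lab2[objs[[i]]] <- i
  if (!nrow(tbl)) tbl <- bind_cols(tibble(vessel_id = integer(),
                                          region = character()),
                                   empty_vessel_table(markers),
                                   empty_morphology_table())
  attr(tbl, "label") <- lab2
  attr(tbl, "removed") <- removed
  attr(tbl, "pixel_size") <- ps
  tbl
}

empty_vessel_table <- function(markers) {
  cols <- c("row_px", "col_px", "n_px",
            as.vector(t(outer(c("coverage_", "mean_", "pos_"), markers,
                              paste0))))
  as_tibble(stats::setNames(
    purrr::map(cols, ~ if (grepl("^pos_", .x)) logical() else numeric()),
    cols))
}

empty_morphology_table <- function() {
  tibble(area_um2 = numeric(), filled_area_um2 = numeric(),
         lumen_area_um2 = numeric(), perimeter_um = numeric(),
         eccentricity = numeric(), solidity = numeric(),
         form_factor = numeric())
}

# region of a pixel index set: IT if > 50% of pixels intratumoral, else PT;
# NA if the object has no pixel in tissue
region_of_pixels <- function(idx, masks) {
  if (!any(masks$tissue[idx])) return(NA_character_)
  if (mean(masks$intratumoral[idx]) > 0.5) "IT" else "PT"
}

#' Hierarchical marker gating of a vessel object
#'
#' Implements the supervised gate over marker positivity: AQP1+ objects take
#' the blood branch and split on CD34/aSMA into immature neovasculature
#' (CD34+aSMA+), activated capillaries/postcapillary venules (CD34+aSMA-)
#' and arterioles (CD34-aSMA+); AQP1+CD34-aSMA- objects are rejected as
#' single cells. AQP1- PDPN+ objects take the lymphatic branch and split on
#' LYVE1 (LYVE1+ lymphatic capillary, LYVE1- inflamed lymphatic capillary).
#' Remaining LYVE1+ panCK- objects, and everything else, are unclassified
#' anomalies. AQP1 takes precedence over PDPN on double positives (logged by
#' [classify_vessels()]). The HEV-like flag is MECA79 positivity and is only
#' meaningful on the blood branch.
#'
#' @param aqp1,cd34,asma,pdpn,lyve1,meca79,panck Logical positivity calls.
#' @return List with `subtype` (see [vessel_subtypes()]) and `hev_like`.
#' @export
classify_vessel <- function(aqp1, cd34, asma, pdpn, lyve1,
                            meca79 = FALSE, panck = FALSE) {
  subtype <- if (aqp1) {
    if (cd34 && asma) "IMMATURE_NEOVASC"
    else if (cd34) "ACTIVATED_CAP_PCV"
    else if (asma) "ARTERIOLE"
    else "REJECTED_SINGLE_CELL"
  } else if (pdpn) {
    if (lyve1) "LYMPHATIC_CAP" else "INFLAMED_LYMPHATIC_CAP"
  } else {
    "UNCLASSIFIED_ANOMALY"   # includes PDPN- LYVE1+ panCK- structures
  }
  list(subtype = subtype, hev_like = isTRUE(aqp1) && isTRUE(meca79))
}

#' Gate a vessel table into subtypes
#'
#' Vectorized [classify_vessel()] over the `pos_*` columns of a
#' [segment_vessels()] table; adds `subtype` and `hev_like` columns and
#' logs AQP1/PDPN double positives.
#'
#' @param vessels Tibble with logical columns `pos_AQP1`, `pos_CD34`,
#'   `pos_aSMA`, `pos_PDPN`, `pos_LYVE1` and optionally `pos_MECA79`,
#'   `pos_panCK`.
#' @return The input with `subtype` and `hev_like` columns added.
#' @export
classify_vessels <- function(vessels) {
  need <- c("pos_AQP1", "pos_CD34", "pos_aSMA", "pos_PDPN", "pos_LYVE1")
  missing <- setdiff(need, names(vessels))
  if (length(missing))
    abort(paste0("missing positivity column(s): ",
                 paste(missing, collapse = ", ")))
  meca <- vessels[["pos_MECA79"]] %||% rep(FALSE, nrow(vessels))
  pck <- vessels[["pos_panCK"]] %||% rep(FALSE, nrow(vessels))
  dbl <- vessels$pos_AQP1 & vessels$pos_PDPN
  if (any(dbl))
    inform(sprintf(
      "%d AQP1+PDPN+ double-positive object(s): AQP1 branch takes precedence",
      sum(dbl)))
  res <- purrr::pmap(
    list(vessels$pos_AQP1, vessels$pos_CD34, vessels$pos_aSMA,
         vessels$pos_PDPN, vessels$pos_LYVE1, meca, pck),
    classify_vessel)
  vessels$subtype <- factor(purrr::map_chr(res, "subtype"),
                            levels = vessel_subtypes())
  vessels$hev_like <- purrr::map_lgl(res, "hev_like")
  vessels
}

#' Morphology features of a labeled object
#'
#' Area, hole-filled area and their difference (the lumen area of an annular
#' vessel), perimeter (count of exposed 4-neighbor pixel edges), eccentricity
#' from the second central moments, solidity (area over the area of the
#' convex hull of the pixel squares) and form factor `4*pi*area/perimeter^2`.
#'
#' @param idx Linear pixel indices of one object.
#' @param dim Dimensions of the image the indices refer to.
#' @param pixel_size um/px.
#' @return One-row tibble of features in physical units (um^2, um).
#' @export
compute_morphology <- function(idx, dim, pixel_size) {
  stopifnot(length(idx) > 0)
  nr <- dim[1]
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  # work in a padded bounding box
  r0 <- min(r) - 1L; c0 <- min(c) - 1L
  bb <- matrix(FALSE, max(r) - r0 + 2L, max(c) - c0 + 2L)
  bb[cbind(r - r0, c - c0)] <- TRUE
  filled <- EBImage::fillHull(bb) > 0
  area_px <- length(idx)
  filled_px <- sum(filled)
  # perimeter: exposed 4-neighbor edges
  n <- nrow(bb); m <- ncol(bb)
  exposed <- sum(bb & !rbind(bb[-1, ], FALSE)) +
    sum(bb & !rbind(FALSE, bb[-n, ])) +
    sum(bb & !cbind(bb[, -1], FALSE)) +
    sum(bb & !cbind(FALSE, bb[, -m]))
  # eccentricity from second central moments
  mu20 <- stats::var(r) * (area_px - 1) / area_px + 1 / 12
  mu02 <- stats::var(c) * (area_px - 1) / area_px + 1 / 12
  mu11 <- if (area_px > 1)
    stats::cov(r, c) * (area_px - 1) / area_px else 0
  tr2 <- (mu20 + mu02) / 2
  det <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det; l2 <- max(tr2 - det, 0)
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  sol <- min(area_px / convex_area_px(idx, nr), 1)
  per_um <- exposed * pixel_size
  area_um2 <- area_px * pixel_size^2
  tibble(
    area_um2 = area_um2,
    filled_area_um2 = filled_px * pixel_size^2,
    lumen_area_um2 = (filled_px - area_px) * pixel_size^2,
    perimeter_um = per_um,
    eccentricity = min(ecc, 1 - 1e-12),
    solidity = sol,
    form_factor = 4 * pi * area_um2 / per_um^2)
}
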