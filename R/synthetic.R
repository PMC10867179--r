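#' Specification of a synthetic ROI
#'
#' Describes a ground-truth-annotated synthetic ROI: a tissue disk on a
#' non-tissue background, S100+ tumor nests, annular vessels whose walls are
#' positive for the marker set of their subtype, disk-shaped cells with
#' class-specific marker sets, and optional TLS-like lymphocyte aggregates.
#' All geometry is in micrometres; intensities are background + contrast
#' with additive Gaussian noise, so the default contrast/noise ratio of 10
#' emulates the high-SNR regime of chromogenic staining. A fixed seed makes
#' [generate_roi()] pixel-reproducible.
#'
#' @param image_shape Height and width in pixels.
#' @param pixel_size um/px.
#' @param tissue `NULL` for a centered disk covering ~45% of the frame
#'   (background must dominate the hematoxylin histogram for triangle
#'   thresholding), `"all"` for whole-frame tissue, or a list
#'   `(x_um, y_um, radius_um)`.
#' @param tumor_nests Tibble `(x_um, y_um, radius_um)`.
#' @param vessels Tibble `(x_um, y_um, outer_radius_um, wall_um, subtype,
#'   hev)`; `subtype` must be one of the five plantable subtypes (see
#'   [vessel_subtypes()]).
#' @param cells Tibble `(x_um, y_um, radius_um, class, tls_id)`; `class`
#'   from [cell_classes()]; `tls_id` NA for scattered cells.
#' @param tls Tibble `(tls_id, x_um, y_um, radius_um, n_cd8, n_cd20,
#'   hev_vessel)` describing planted aggregates (member cells must appear in
#'   `cells` carrying the `tls_id`).
#' @param background_level,contrast,tissue_contrast,noise_sd Intensity
#'   model; the background sits two noise-SDs above zero so clipping does
#'   not pile probability mass at 0, and `macrophage_cd45` is the relative
#'   CD45 level given to macrophages (weak staining).
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_shape = c(1000L, 1000L), pixel_size = 1,
                           tissue = NULL,
                           tumor_nests = empty_nests(),
                           vessels = empty_spec_vessels(),
                           cells = empty_spec_cells(),
                           tls = empty_spec_tls(),
                           background_level = 0.2, contrast = 1,
                           tissue_contrast = 0.4, noise_sd = 0.1,
                           macrophage_cd45 = 0.3, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8), pixel_size > 0,
            noise_sd >= 0, contrast > 0)
  if (is.null(tissue)) {
    half <- min(image_shape) * pixel_size / 2
    tissue <- list(x_um = image_shape[2] * pixel_size / 2,
                   y_um = image_shape[1] * pixel_size / 2,
                   radius_um = 0.76 * half)
  }
  if (nrow(tumor_nests) && any(tumor_nests$radius_um <= 0))
    abort("nest radii must be positive")
  if (nrow(vessels)) {
    stopifnot(all(vessels$outer_radius_um > 0),
              all(vessels$wall_um > 0),
              all(vessels$wall_um < vessels$outer_radius_um))
    bad <- setdiff(vessels$subtype, names(subtype_marker_sets()))
    if (length(bad))
      abort(paste0("unknown vessel subtype(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(cells)) {
    stopifnot(all(cells$radius_um > 0))
    bad <- setdiff(cells$class, cell_classes())
    if (length(bad))
      abort(paste0("unknown cell class(es): ", paste(bad, collapse = ", ")))
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    tissue = tissue, tumor_nests = tumor_nests, vessels = vessels,
    cells = cells, tls = tls, background_level = background_level,
    contrast = contrast, tissue_contrast = tissue_contrast,
    noise_sd = noise_sd, macrophage_cd45 = macrophage_cd45,
    seed = as.integer(seed)), class = "synthetic_spec")
}

empty_nests <- function() tibble(x_um = numeric(), y_um = numeric(),
                                 radius_um = numeric())
empty_spec_vessels <- function() {
  tibble(x_um = numeric(), y_um = numeric(), outer_radius_um = numeric(),
         wall_um = numeric(), subtype = character(), hev = logical())
}
empty_spec_cells <- function() {
  tibble(x_um = numeric(), y_um = numeric(), radius_um = numeric(),
         class = character(), tls_id = integer())
}
empty_spec_tls <- function() {
  tibble(tls_id = integer(), x_um = numeric(), y_um = numeric(),
         radius_um = numeric(), n_cd8 = integer(), n_cd20 = integer(),
         hev_vessel = logical())
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d x %d px @ %g um/px; %d nest(s), %d vessel(s), %d cell(s), %d TLS; seed %d\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size, nrow(x$tumor_nests),
    nrow(x$vessels), nrow(x$cells), nrow(x$tls), x$seed))
  invisible(x)
}

# um (x, y) -> px (row, col)
um_to_px <- function(x_um, y_um, pixel_size) {
  c(y_um / pixel_size, x_um / pixel_size)
}

#' Render a synthetic ROI and its ground truth
#'
#' Draws the spec onto one grayscale channel per panel marker: hematoxylin
#' carries the tissue field and cell nuclei, S100 the tumor nests and any
#' planted S100+ single cells, vessel walls are set to background + contrast
#' in the markers of their subtype with the lumen held at background, and
#' each cell paints its marker set over a slightly dilated nucleus
#' footprint. Gaussian noise (sd `noise_sd`) is then added channel by
#' channel in panel order and clipped at zero, so two runs of the same spec
#' are pixel-identical. Planted vessels whose outer circles intersect are
#' flagged `merged` in the truth table rather than dropped.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `stack` (a [channel_stack()]) and `truth`: tibbles
#'   `vessels`, `cells`, `tls`, plus `masks` (a [make_region_masks()] built
#'   from the drawn tissue and nest geometry).
#' @export
generate_roi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  ps <- spec$pixel_size
  bg <- spec$background_level; ct <- spec$contrast
  shape <- c(H, W)
  ch <- stats::setNames(
    purrr::map(marker_panel(), ~ matrix(bg, H, W)), marker_panel())

  tissue <- if (identical(spec$tissue, "all")) matrix(TRUE, H, W) else
    disk_mask(shape, um_to_px(spec$tissue$x_um, spec$tissue$y_um, ps),
              spec$tissue$radius_um / ps)
  ch$hematoxylin[tissue] <- bg + spec$tissue_contrast

  it <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(spec$tumor_nests))) {
    nst <- spec$tumor_nests[i, ]
    d <- disk_mask(shape, um_to_px(nst$x_um, nst$y_um, ps), nst$radius_um / ps)
    ch$S100[d] <- bg + ct
    it <- it | d
  }
  it <- it & tissue

  sets <- subtype_marker_sets()
  vtruth <- spec$vessels
  if (nrow(vtruth)) {
    vtruth$vessel_id <- seq_len(nrow(vtruth))
    vtruth$area_px <- NA_real_
    vtruth$region <- NA_character_
    for (i in seq_len(nrow(vtruth))) {
      v <- vtruth[i, ]
      cen <- um_to_px(v$x_um, v$y_um, ps)
      ring <- annulus_mask(shape, cen, v$outer_radius_um / ps, v$wall_um / ps)
      lumen <- disk_mask(shape, cen, (v$outer_radius_um - v$wall_um) / ps)
      mk <- sets[[v$subtype]]
      if (isTRUE(v$hev)) mk <- union(mk, "MECA79")
      for (m in mk) {
        ch[[m]][ring] <- bg + ct
        ch[[m]][lumen] <- bg
      }
      vtruth$area_px[i] <- sum(ring)
      cr <- round(cen)
      vtruth$region[i] <- if (cr[1] >= 1 && cr[1] <= H && cr[2] >= 1 &&
                              cr[2] <= W && it[cr[1], cr[2]]) "IT" else "PT"
    }
    # overlapping vessels that would merge into one component are flagged
    d2 <- as.matrix(stats::dist(cbind(vtruth$x_um, vtruth$y_um)))
    ov <- d2 < outer(vtruth$outer_radius_um, vtruth$outer_radius_um, `+`)
    diag(ov) <- FALSE
    vtruth$merged <- unname(apply(ov, 1, any))
  } else {
    vtruth <- mutate(vtruth, vessel_id = integer(), area_px = numeric(),
                     region = character(), merged = logical())
  }

  csets <- class_marker_sets()
  ctruth <- spec$cells
  if (nrow(ctruth)) {
    ctruth$cell_id <- seq_len(nrow(ctruth))
    ctruth$region <- NA_character_
    for (i in seq_len(nrow(ctruth))) {
      cc <- ctruth[i, ]
      cen <- um_to_px(cc$x_um, cc$y_um, ps)
      nuc <- disk_mask(shape, cen, cc$radius_um / ps)
      halo <- disk_mask(shape, cen, cc$radius_um / ps + 2)
      ch$hematoxylin[nuc] <- bg + spec$tissue_contrast + ct
      for (m in csets[[cc$class]]) {
        lev <- if (m == "CD45lo") spec$macrophage_cd45 * ct else ct
        mm <- if (m == "CD45lo") "CD45" else m
        ch[[mm]][halo] <- pmax(ch[[mm]][halo], bg + lev)
      }
      cr <- round(cen)
      ctruth$region[i] <- if (cr[1] >= 1 && cr[1] <= H && cr[2] >= 1 &&
                              cr[2] <= W && it[cr[1], cr[2]]) "IT" else "PT"
    }
  } else {
    ctruth <- mutate(ctruth, cell_id = integer(), region = character())
  }

  if (spec$noise_sd > 0) {
    for (m in marker_panel())
      ch[[m]] <- pmax(ch[[m]] + matrix(stats::rnorm(H * W, 0, spec$noise_sd),
                                       H, W), 0)
  }
  masks <- make_region_masks(tissue, it, ps)
  list(stack = channel_stack(ch, ps, roi_id = paste0("synthetic_seed",
                                                     spec$seed)),
       truth = list(vessels = vtruth, cells = ctruth, tls = spec$tls,
                    masks = masks))
}
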