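#' Read a channel stack from single-marker TIFF files
#'
#' @param paths Named character vector (marker name -> TIFF path).
#' @param pixel_size um/px.
#' @param roi_id Identifier.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(paths, pixel_size, roi_id = "roi") {
  ch <- purrr::map(paths, function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.numeric(img), nrow(img), ncol(img))
  })
  channel_stack(ch, pixel_size, roi_id)
}

#' Write a channel stack as one float TIFF per marker
#'
#' @param stack A [channel_stack()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_channel_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mx <- max(1, max(vapply(stack$channels, max, numeric(1))))
  paths <- purrr::imap_chr(stack$channels, function(ch, nm) {
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(pmin(pmax(ch / mx, 0), 1), p, bits.per.sample = 32L)
    p
  })
  invisible(paths)
}

# write the region masks as 0/255 8-bit TIFFs plus an area CSV
write_region_masks <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("tissue", "intratumoral", "peritumoral")) {
    tiff::writeTIFF(masks[[nm]] * 1.0, file.path(dir, paste0("mask_", nm,
                                                             ".tif")))
  }
  utils::write.csv(masks$areas, file.path(dir, "region_areas.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline on one ROI
#'
#' Executes the stages in order — input (synthetic generation or channel
#' TIFFs, with optional deconvolution of RGB rounds), registration QC,
#' region segmentation, vessel segmentation and gating, cell segmentation
#' and gating, TLS detection and vessel association, and the ROI summary —
#' and optionally writes every table and mask under `out_dir` together with
#' a run log of all effective parameters. Any stage failure aborts with the
#' stage name. Reruns of the same config are deterministic.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `seed`; `input` (either `type: synthetic` with `n_vessels`, `n_cells`,
#'   `n_tls`, `image_shape`, `pixel_size`, `noise_sd`, or `type: files`
#'   with `channels` (marker -> TIFF path) and `pixel_size`); optional
#'   parameter blocks `registration` (`threshold`), `regions`
#'   (`min_nest_area_um2`), `vessels`, `cells`, `tls`
#'   (`link_radius_um`, `min_cd8`, `min_cd20`), `infiltration` (`cutoff`).
#' @param out_dir Output directory; `NULL` for no file output.
#' @return List: `stack`, `masks`, `vessels`, `cells`, `tls`, `summary`,
#'   `qc`, and `truth` (synthetic input only), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  inp <- config$input %||% list(type = "synthetic")
  loaded <- stage("input", {
    if (identical(inp$type %||% "synthetic", "synthetic")) {
      spec <- random_roi_spec(
        n_vessels = inp$n_vessels %||% 20,
        n_cells = inp$n_cells %||% 300,
        n_tls = inp$n_tls %||% 1,
        seed = seed,
        image_shape = unlist(inp$image_shape %||% c(1000L, 1000L)),
        pixel_size = inp$pixel_size %||% 1,
        noise_sd = inp$noise_sd %||% 0.1)
      generate_roi(spec)
    } else {
      if (is.null(inp$channels)) abort("input$channels missing")
      list(stack = read_channel_stack(
        unlist(inp$channels),
        inp$pixel_size %||% abort("input$pixel_size missing")),
        truth = NULL)
    }
  })
  stk <- loaded$stack
  truth <- loaded$truth
  qc <- stage("registration", {
    qc_registration(stk, threshold = config$registration$threshold %||% 0.5)
  })
  if (!qc$pass)
    warn(sprintf("registration QC failed for %d channel(s); ROI flagged",
                 sum(!qc$report$pass)))
  masks <- stage("regions", {
    tissue <- segment_tissue(stk$channels$hematoxylin, stk$pixel_size)
    it <- segment_tumor(stk$channels$S100, stk$pixel_size,
                        min_nest_area_um2 =
                          config$regions$min_nest_area_um2 %||% 500,
                        tissue = tissue)
    make_region_masks(tissue, it, stk$pixel_size)
  })
  vessels <- stage("vessels", {
    vp <- config$vessels %||% list()
    do.call(segment_vessels, c(list(stack = stk, masks = masks), vp)) |>
      classify_vessels()
  })
  cells <- stage("cells", {
    cp <- config$cells %||% list()
    do.call(segment_cells, c(list(stack = stk, masks = masks), cp)) |>
      gate_cells()
  })
  tls <- stage("tls", {
    tp <- config$tls %||% list()
    detect_tls(cells, pixel_size = stk$pixel_size,
               link_radius_um = tp$link_radius_um %||% 50,
               min_cd8 = tp$min_cd8 %||% 10,
               min_cd20 = tp$min_cd20 %||% 10, masks = masks)
  })
  summary <- stage("summary", {
    summarize_roi(vessels, cells, masks, tls = tls, roi_id = stk$roi_id,
                  infiltration_cutoff = config$infiltration$cutoff %||% 1.0,
                  pixel_size = stk$pixel_size)
  })
  res <- list(stack = stk, qc = qc, masks = masks, vessels = vessels,
              cells = cells, tls = tls, summary = summary, truth = truth)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) {
    drop <- vapply(x, is.list, logical(1))
    utils::write.csv(x[, !drop, drop = FALSE],
                     file.path(out_dir, nm), row.names = FALSE)
  }
  wr(res$vessels, "vessels.csv")
  wr(res$cells, "cells.csv")
  wr(res$tls, "tls.csv")
  wr(res$summary, "roi_summary.csv")
  wr(res$qc$report, "registration_qc.csv")
  write_region_masks(res$masks, out_dir)
  if (!is.null(res$truth)) {
    wr(res$truth$vessels, "truth_vessels.csv")
    wr(res$truth$cells, "truth_cells.csv")
  }
  yaml::write_yaml(list(seed = config$seed %||% 1L,
                        effective_config = config),
                   file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
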