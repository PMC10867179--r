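#' Co-registered per-marker channel stack for one ROI
#'
#' Container for the aligned single-marker grayscale images of one region of
#' interest: a named list of equal-dimension matrices, the pixel size in
#' micrometres per pixel, an ROI identifier, and the per-round translation
#' offsets recorded when the stack was aligned.
#'
#' @param channels Named list of numeric matrices, identical dimensions;
#'   names must be unique and drawn from [marker_panel()].
#' @param pixel_size Pixel edge length, um/px (> 0).
#' @param roi_id Identifier string.
#' @param offsets Optional tibble of provenance offsets (marker, dy, dx).
#' @return A `channel_stack` object.
#' @export
channel_stack <- function(channels, pixel_size, roi_id = "roi",
                          offsets = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, pixel_size > 0)
  nm <- names(channels)
  if (is.null(nm) || anyDuplicated(nm))
    abort("channels must be uniquely named")
  bad <- setdiff(nm, marker_panel())
  if (length(bad))
    abort(paste0("unknown marker(s): ", paste(bad, collapse = ", ")))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all channels must share the same dimensions")
  structure(list(channels = channels, pixel_size = pixel_size,
                 roi_id = roi_id,
                 offsets = offsets %||%
                   tibble(marker = nm, dy = 0L, dx = 0L)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %s: %d x %d px @ %.3g um/px, %d marker(s)\n",
              x$roi_id, d[1], d[2], x$pixel_size, length(x$channels)))
  cat("  ", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Square ROI box
#'
#' A square region of interest on the registered pixel grid, specified by its
#' top-left pixel (1-based row/col) and side length. `roi_side_px()` converts
#' the configured physical ROI area to a side length; the 6.25 mm^2 preset
#' used for whole-slide analysis corresponds to a 2.5 mm square.
#'
#' @param row,col Top-left pixel (1-based).
#' @param side Side length in pixels.
#' @return A `roi_box` list.
#' @export
roi_box <- function(row, col, side) {
  stopifnot(row >= 1, col >= 1, side >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 side = as.integer(side)), class = "roi_box")
}

#' @rdname roi_box
#' @param area_mm2 ROI area in mm^2 (default the 6.25 mm^2 preset).
#' @param pixel_size um/px.
#' @export
roi_side_px <- function(area_mm2 = 6.25, pixel_size = 0.5) {
  as.integer(round(sqrt(area_mm2) * 1000 / pixel_size))
}

#' Estimate the translation between two staining rounds
#'
#' Integer-pixel translation maximizing the cross-correlation of the
#' mean-subtracted images (computed by FFT with zero padding); the returned
#' quality is the normalized correlation coefficient of the overlapping
#' region at the chosen offset, clipped to \[0, 1\]. The estimated `(dy, dx)`
#' is the shift to apply to `moving` so that
#' `moving[i - dy, j - dx] == fixed[i, j]`.
#'
#' @param fixed,moving Numeric matrices of identical dimensions, nonconstant.
#' @return Tibble with one row: `dy`, `dx`, `quality`.
#' @export
estimate_offset <- function(fixed, moving) {
  stopifnot(is.matrix(fixed), is.matrix(moving), all(dim(fixed) == dim(moving)))
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    abort("degenerate input: constant image")
  h <- nrow(fixed); w <- ncol(fixed)
  ph <- 2L * h; pw <- 2L * w
  fp <- matrix(0, ph, pw); mp <- matrix(0, ph, pw)
  fp[1:h, 1:w] <- fixed - mean(fixed)
  mp[1:h, 1:w] <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(mp)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  to_lag <- function(i, p) { s <- i - 1L; if (s >= p / 2) s - p else s }
  dy <- to_lag(pk[1], ph); dx <- to_lag(pk[2], pw)
  # normalized correlation over the overlap at the chosen integer offset
  fr <- max(1L, 1L + dy):min(h, h + dy)
  fc <- max(1L, 1L + dx):min(w, w + dx)
  q <- stats::cor(as.numeric(fixed[fr, fc]),
                  as.numeric(moving[fr - dy, fc - dx]))
  tibble(dy = as.integer(dy), dx = as.integer(dx),
         quality = min(max(q, 0), 1))
}

#' Shift rounds into alignment and crop a common ROI
#'
#' Applies per-channel integer offsets (as estimated by [estimate_offset()])
#' and crops every channel to the same [roi_box()], so all markers share one
#' pixel grid. Offsets are recorded in the stack's provenance.
#'
#' @param stack A [channel_stack()].
#' @param offsets Tibble (marker, dy, dx); channels absent from it get (0,0).
#' @param box A [roi_box()]; must lie inside every shifted image.
#' @return A new `channel_stack` cropped to the box.
#' @export
apply_offset_and_crop <- function(stack, offsets, box) {
  stopifnot(inherits(stack, "channel_stack"), inherits(box, "roi_box"))
  h <- nrow(stack$channels[[1]]); w <- ncol(stack$channels[[1]])
  rows <- box$row:(box$row + box$side - 1L)
  cols <- box$col:(box$col + box$side - 1L)
  if (max(rows) > h || max(cols) > w)
    abort("ROI box exceeds image bounds")
  out <- purrr::imap(stack$channels, function(ch, nm) {
    o <- offsets[offsets$marker == nm, , drop = FALSE]
    dy <- if (nrow(o)) o$dy[1] else 0L
    dx <- if (nrow(o)) o$dx[1] else 0L
    sr <- rows - dy; sc <- cols - dx
    if (min(sr) < 1L || max(sr) > h || min(sc) < 1L || max(sc) > w)
      abort(sprintf("ROI box exceeds bounds of shifted channel '%s'", nm))
    ch[sr, sc]
  })
  prov <- tibble(marker = names(out),
                 dy = vapply(names(out), function(nm) {
                   o <- offsets[offsets$marker == nm, ]
                   if (nrow(o)) as.integer(o$dy[1]) else 0L
                 }, integer(1), USE.NAMES = FALSE),
                 dx = vapply(names(out), function(nm) {
                   o <- offsets[offsets$marker == nm, ]
                   if (nrow(o)) as.integer(o$dx[1]) else 0L
                 }, integer(1), USE.NAMES = FALSE))
  channel_stack(out, stack$pixel_size, stack$roi_id, offsets = prov)
}

#' Registration quality control for a stack
#'
#' Estimates the residual offset of every channel against a reference round
#' and fails the ROI if any channel's correlation quality falls below the
#' threshold. Poorly registered ROIs are meant to be excluded from all
#' downstream tables.
#'
#' @param stack A [channel_stack()] with at least 2 channels.
#' @param threshold Minimum acceptable normalized correlation (default 0.5).
#' @param reference Reference marker name (default hematoxylin if present,
#'   otherwise the first channel).
#' @return List with `pass` (logical) and `report` (tibble: marker, dy, dx,
#'   quality, pass).
#' @export
qc_registration <- function(stack, threshold = 0.5, reference = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  nm <- names(stack$channels)
  if (length(nm) < 2L) abort("need at least 2 rounds for registration QC")
  reference <- reference %||%
    (if ("hematoxylin" %in% nm) "hematoxylin" else nm[1])
  fixed <- stack$channels[[reference]]
  rep <- purrr::map_dfr(setdiff(nm, reference), function(m) {
    est <- estimate_offset(fixed, stack$channels[[m]])
    mutate(est, marker = m, .before = 1)
  })
  rep <- mutate(rep, pass = .data$quality >= threshold)
  list(pass = all(rep$pass), report = rep)
}
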