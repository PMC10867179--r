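#' Stain model for hematoxylin/AEC deconvolution
#'
#' Holds unit optical-density (OD) RGB vectors for the two chromogens of a
#' sequential chromogenic IHC round — the hematoxylin counterstain and the
#' AEC detection chromogen — plus the white (background) reference. Defaults
#' are the published Ruifrok–Johnston-convention vectors for H and AEC.
#'
#' @param hema,aec Length-3 nonzero RGB OD vectors (normalized internally).
#' @param white Length-3 positive white reference (transmitted light with no
#'   absorber), default 1 for images scaled to \[0, 1\].
#' @return A `stain_model` object.
#' @export
stain_model <- function(hema = c(0.650, 0.704, 0.286),
                        aec = c(0.2743, 0.6796, 0.6803),
                        white = c(1, 1, 1)) {
  stopifnot(length(hema) == 3, length(aec) == 3, length(white) == 3,
            all(white > 0))
  if (sum(hema^2) == 0 || sum(aec^2) == 0)
    abort("stain vectors must be nonzero")
  m <- structure(
    list(hema = hema / sqrt(sum(hema^2)),
         aec = aec / sqrt(sum(aec^2)),
         white = white),
    class = "stain_model")
  m
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model> hematoxylin/AEC optical-density basis\n")
  cat("  hema :", sprintf("%.4f", x$hema), "\n")
  cat("  aec  :", sprintf("%.4f", x$aec), "\n")
  invisible(x)
}

#' Render an RGB chromogenic round from density maps
#'
#' Beer–Lambert forward model: per pixel, transmitted intensity in channel
#' \eqn{c} is \eqn{I_c = W_c \exp(-(d_H v_{H,c} + d_A v_{A,c}))} where
#' \eqn{d_H, d_A} are the hematoxylin and AEC density maps and \eqn{v} the
#' unit OD vectors. Zero density renders pure white.
#'
#' @param hema,aec Non-negative numeric matrices (optical densities) of equal
#'   dimensions.
#' @param stains A [stain_model()].
#' @return An H x W x 3 array of transmitted intensities in `(0, white]`.
#' @seealso [deconvolve_h_aec()] for the inverse.
#' @export
render_rgb_round <- function(hema, aec, stains = stain_model()) {
  stopifnot(is.matrix(hema), is.matrix(aec), all(dim(hema) == dim(aec)))
  if (any(hema < 0) || any(aec < 0))
    abort("negative optical densities are not physical")
  rgb <- array(0, c(dim(hema), 3L))
  for (ch in 1:3) {
    od <- hema * stains$hema[ch] + aec * stains$aec[ch]
    rgb[, , ch] <- stains$white[ch] * exp(-od)
  }
  rgb
}

#' Separate hematoxylin and AEC densities from an RGB image
#'
#' Optical-density color deconvolution: each pixel's RGB is log-transformed
#' against the white reference into OD space and projected onto the two-stain
#' basis (least squares via the pseudo-inverse). Negative projections are
#' clipped to zero. Saturated-black pixels, whose OD is unbounded, are
#' assigned the maximum finite density observed in the image and flagged.
#'
#' @param rgb H x W x 3 array of transmitted intensities in `[0, white]`.
#' @param stains A [stain_model()].
#' @return List with matrices `hema` and `aec` (densities, >= 0) and a
#'   logical matrix `saturated` flagging black pixels.
#' @export
deconvolve_h_aec <- function(rgb, stains = stain_model()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  d <- dim(rgb)[1:2]
  sat <- rgb[, , 1] <= 0 | rgb[, , 2] <= 0 | rgb[, , 3] <= 0
  od <- matrix(0, prod(d), 3L)
  for (ch in 1:3) {
    v <- pmax(rgb[, , ch], .Machine$double.xmin) / stains$white[ch]
    od[, ch] <- -log(pmin(v, 1))
  }
  basis <- cbind(stains$hema, stains$aec)        # 3 x 2
  proj <- od %*% basis %*% solve(crossprod(basis))   # pseudo-inverse
  hema <- matrix(pmax(proj[, 1], 0), d[1], d[2])
  aec <- matrix(pmax(proj[, 2], 0), d[1], d[2])
  if (any(sat)) {
    cap <- function(m) {
      mx <- suppressWarnings(max(m[!sat & is.finite(m)]))
      m[sat] <- if (is.finite(mx)) mx else 0
      m
    }
    hema <- cap(hema); aec <- cap(aec)
    warn(sprintf("%d saturated-black pixel(s): density capped and flagged",
                 sum(sat)))
  }
  list(hema = hema, aec = aec, saturated = sat)
}

#' Clean background from a deconvolved density channel
#'
#' Post-deconvolution signal cleaning: values at or below a background
#' threshold are set to zero; optionally, residual impulse noise is first
#' removed with a 3x3 median filter. With `median = FALSE` (the default) the
#' operation is exactly idempotent; the median step trades that guarantee
#' for impulse suppression and slightly erodes corners of sharp blocks. No
#' pixel is ever raised above the input maximum.
#'
#' @param channel Non-negative numeric matrix.
#' @param threshold Background level; pixels `<= threshold` become 0. If
#'   `NULL` and `blank` is given, `mean(blank) + 2*sd(blank)` is used;
#'   with neither, 0 (no thresholding).
#' @param blank Optional numeric vector or matrix of pixels from a
#'   user-designated blank (signal-free) region.
#' @param median Logical; apply the 3x3 median denoise first.
#' @return Cleaned matrix, same dimensions, nonnegative.
#' @export
clean_background <- function(channel, threshold = NULL, blank = NULL,
                             median = FALSE) {
  stopifnot(is.matrix(channel))
  if (any(channel < 0)) abort("density channel must be nonnegative")
  if (is.null(threshold)) {
    threshold <- if (is.null(blank)) 0 else
      mean(blank) + 2 * stats::sd(as.numeric(blank))
  }
  out <- if (median) median3x3(channel) else channel
  out <- pmin(out, max(channel))
  out[out <= threshold] <- 0
  out
}

#' Render one staining round of a channel stack
#'
#' Convenience wrapper around [render_rgb_round()]: a chromogenic round
#' images the hematoxylin counterstain together with one AEC-detected
#' marker, so the round's RGB image is the Beer-Lambert mix of the stack's
#' hematoxylin channel and the chosen marker channel.
#'
#' @param stack A [channel_stack()] containing `hematoxylin` and `marker`.
#' @param marker Marker name imaged in this round.
#' @param stains A [stain_model()].
#' @return H x W x 3 RGB array.
#' @export
render_round <- function(stack, marker, stains = stain_model()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!all(c("hematoxylin", marker) %in% names(stack$channels)))
    abort("stack must contain 'hematoxylin' and the requested marker")
  render_rgb_round(stack$channels$hematoxylin, stack$channels[[marker]],
                   stains)
}
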