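#' Otsu threshold of a histogram
#'
#' Exhaustive-search Otsu: over every cut point t the histogram is split into
#' bins `<= t` and `> t` and the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} is maximized. Ties are broken toward the
#' lowest bin, so the result is deterministic.
#'
#' @param counts Non-negative histogram counts, one per bin.
#' @param values Optional numeric bin values (defaults to `0:(nbins-1)`,
#'   i.e. 8-bit gray levels when `length(counts) == 256`).
#' @return The bin value `t` of the optimal cut; foreground is `value > t`.
#' @seealso [triangle_threshold()], [otsu_image()]
#' @export
otsu_threshold <- function(counts, values = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(values), all(counts >= 0))
  counts <- as.numeric(counts)     # avoid integer overflow in the moments
  nz <- which(counts > 0)
  if (length(unique(values[nz])) < 2L)
    abort("degenerate histogram: fewer than 2 distinct populated values")
  n <- sum(counts)
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * values)
  total <- s0[length(s0)]
  w1 <- n - w0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  values[which.max(bcv)]            # which.max takes the first (lowest) tie
}

#' Triangle threshold of a histogram
#'
#' Geometric (Zack) triangle method: a line is drawn from the histogram peak
#' to the far end of the longer tail (the last populated bin on that side),
#' and the threshold is the bin maximizing perpendicular distance to that
#' line. Axes are normalized (bins by range, counts by the peak count) so the
#' rule is invariant to intensity and count scaling. Ties break toward the
#' lower intensity bin; the peak itself ties toward the lowest bin.
#'
#' @inheritParams otsu_threshold
#' @return The bin value of the maximum-distance bin; foreground is
#'   `value > t` for a right-tailed histogram.
#' @export
triangle_threshold <- function(counts, values = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(values), all(counts >= 0))
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    abort("degenerate histogram: fewer than 2 populated bins")
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  # far end = populated endpoint farther from the peak; ties go right
  end <- if ((peak - lo) > (hi - peak)) lo else hi
  span <- seq(min(peak, end), max(peak, end))
  # normalized coordinates
  bx <- (span - peak) / (length(counts) - 1)
  by <- (counts[span] - counts[peak]) / max(counts)
  ex <- (end - peak) / (length(counts) - 1)
  ey <- (counts[end] - counts[peak]) / max(counts)
  # perpendicular distance of each (bx, by) from line through (0,0)-(ex,ey)
  d <- abs(bx * ey - by * ex) / sqrt(ex^2 + ey^2)
  best <- span[which.max(d)]       # first max = lowest intensity on the span
  values[best]
}

# histogram an image into n_bins equal-width bins over its range; returns
# counts and bin-center values
image_histogram <- function(x, n_bins = 256L) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0)
    abort("degenerate input: image is constant")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  list(counts = counts, values = (br[-1] + br[-length(br)]) / 2, breaks = br)
}

#' Otsu threshold of an image
#'
#' Convenience wrapper: histograms a numeric matrix into `n_bins` bins and
#' applies [otsu_threshold()]; returns a numeric intensity threshold.
#'
#' @param x Numeric matrix.
#' @param n_bins Number of histogram bins.
#' @return Numeric threshold; foreground is `x > threshold`. The threshold
#'   is the upper edge of the selected cut bin, so every value binned at or
#'   below the cut is background regardless of where it falls inside the
#'   bin.
#' @export
otsu_image <- function(x, n_bins = 256L) {
  h <- image_histogram(x, n_bins)
  t <- otsu_threshold(h$counts, h$values)
  h$breaks[match(t, h$values) + 1L]
}

#' Triangle threshold of an image
#'
#' @inheritParams otsu_image
#' @return Numeric threshold (upper edge of the selected bin); foreground is
#'   `x > threshold`.
#' @export
triangle_image <- function(x, n_bins = 256L) {
  h <- image_histogram(x, n_bins)
  t <- triangle_threshold(h$counts, h$values)
  h$breaks[match(t, h$values) + 1L]
}

# Binarize a channel by Otsu with a separation guard: if the Otsu split does
# not separate foreground from background by at least `min_separation`
# background-SDs, fall back to the triangle threshold (Otsu degrades when
# the foreground fraction is tiny, e.g. a single positive vessel in the
# field; the triangle rule hugs the background peak instead). If neither
# split passes the guard the channel is declared signal-free (all-FALSE
# mask, threshold Inf) rather than slicing pure noise.
binarize_channel <- function(x, min_separation = 4, n_bins = 256L) {
  none <- list(mask = matrix(FALSE, nrow(x), ncol(x)), threshold = Inf)
  if (diff(range(x, finite = TRUE)) == 0) return(none)
  guard_ok <- function(thr) {
    fg <- x > thr
    if (!any(fg) || all(fg)) return(FALSE)
    sd_bg <- stats::sd(x[!fg])
    !(is.finite(sd_bg) && sd_bg > 0 &&
        (mean(x[fg]) - mean(x[!fg])) < min_separation * sd_bg)
  }
  thr <- otsu_image(x, n_bins)
  if (guard_ok(thr)) return(list(mask = x > thr, threshold = thr))
  thr <- tryCatch(triangle_image(x, n_bins), error = function(e) Inf)
  if (is.finite(thr) && guard_ok(thr))
    return(list(mask = x > thr, threshold = thr))
  none
}
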