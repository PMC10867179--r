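# shared in-code fixtures; everything is generated, nothing is stored

# smooth random field with spatial structure (for registration/correlation)
smooth_field <- function(n, m = n, sigma = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

# brute-force Otsu oracle: explicit loop over all cut points
otsu_oracle <- function(counts, values = seq_along(counts) - 1) {
  best <- -Inf; best_t <- NA
  for (t in seq_len(length(counts) - 1)) {
    lo <- seq_len(t); hi <- (t + 1):length(counts)
    w0 <- sum(counts[lo]); w1 <- sum(counts[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * values[lo]) / w0
    mu1 <- sum(counts[hi] * values[hi]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-9) { best <- bcv; best_t <- values[t] }
  }
  best_t
}

# brute-force triangle oracle: point-line distance formula at every bin
triangle_oracle <- function(counts, values = seq_along(counts) - 1) {
  nz <- which(counts > 0)
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  end <- if ((peak - lo) > (hi - peak)) lo else hi
  span <- seq(min(peak, end), max(peak, end))
  p1 <- c((peak - 1) / (length(counts) - 1), counts[peak] / max(counts))
  p2 <- c((end - 1) / (length(counts) - 1), counts[end] / max(counts))
  dmax <- -Inf; best <- NA
  for (b in span) {
    p <- c((b - 1) / (length(counts) - 1), counts[b] / max(counts))
    d <- abs((p2[1] - p1[1]) * (p1[2] - p[2]) -
               (p1[1] - p[1]) * (p2[2] - p1[2])) /
      sqrt(sum((p2 - p1)^2))
    if (d > dmax + 1e-12) { dmax <- d; best <- b }
  }
  values[best]
}

# a small ready-made stack: one annular vessel per family + background
tiny_vessel_stack <- function(shape = c(300, 300), noise_sd = 0,
                              seed = 42) {
  spec <- synthetic_spec(
    image_shape = shape, pixel_size = 1, tissue = "all",
    vessels = tibble::tibble(
      x_um = c(80, 220), y_um = c(80, 200),
      outer_radius_um = c(25, 22), wall_um = c(8, 7),
      subtype = c("ACTIVATED_CAP_PCV", "LYMPHATIC_CAP"),
      hev = c(FALSE, FALSE)),
    noise_sd = noise_sd, seed = seed)
  generate_roi(spec)
}

# whole-frame region masks with a square IT block
square_masks <- function(n = 200, it_rows = 1:100, pixel_size = 1) {
  tissue <- matrix(TRUE, n, n)
  it <- matrix(FALSE, n, n)
  it[it_rows, ] <- TRUE
  make_region_masks(tissue, it, pixel_size)
}
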