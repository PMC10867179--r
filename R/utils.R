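#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# ---- small image helpers -----------------------------------------------

# logical disk mask over an H x W grid; center = (row, col) in px, radius in px
disk_mask <- function(shape, center, radius) {
  r <- seq_len(shape[1]) - center[1]
  c <- seq_len(shape[2]) - center[2]
  outer(r^2, c^2, `+`) <= radius^2
}

# annulus: outer disk minus strictly interior lumen disk
annulus_mask <- function(shape, center, outer_radius, wall_thickness) {
  disk_mask(shape, center, outer_radius) &
    !disk_mask(shape, center, outer_radius - wall_thickness)
}

clip01 <- function(x) pmin(pmax(x, 0), Inf)

# replicate-pad a matrix by k pixels on each side
pad_replicate <- function(x, k) {
  ri <- c(rep(1L, k), seq_len(nrow(x)), rep(nrow(x), k))
  ci <- c(rep(1L, k), seq_len(ncol(x)), rep(ncol(x), k))
  x[ri, ci]
}

#' Fast 3x3 median filter
#'
#' Vectorized 3x3 median via a 9-input sorting network on shifted copies of
#' the (replicate-padded) image. Used as the denoising step ahead of
#' thresholding; exact median, no intensity quantization.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same dimensions holding the 3x3 neighborhood median.
#' @export
median3x3 <- function(x) {
  stopifnot(is.matrix(x))
  p <- pad_replicate(x, 1L)
  n <- nrow(x); m <- ncol(x)
  s <- vector("list", 9L)
  k <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    s[[k]] <- p[dr + seq_len(n), dc + seq_len(m)]
    k <- k + 1L
  }
  # 19-comparator median-of-9 sorting network; after swap(i, j),
  # s[[i]] <= s[[j]] elementwise
  swap <- function(i, j) {
    lo <- pmin(s[[i]], s[[j]]); hi <- pmax(s[[i]], s[[j]])
    s[[i]] <<- lo; s[[j]] <<- hi
  }
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  s[[5]]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally via union-find over the label adjacency pairs
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-n, -m]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -m]), as.vector(lab[-n, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# split label matrix into a list of pixel index vectors (linear indices)
label_pixels <- function(lab) {
  idx <- which(lab > 0L)
  split(idx, lab[idx])
}

# centroid (row, col) of a set of linear indices in an n-row matrix
centroid_rc <- function(idx, nrow) {
  c(row = mean((idx - 1L) %% nrow + 1L), col = mean((idx - 1L) %/% nrow + 1L))
}

# area of the convex hull of a pixel index set, counting pixels as unit
# squares (hull over the 4 corners of every pixel, shoelace formula)
convex_area_px <- function(idx, nrow) {
  r <- (idx - 1L) %% nrow + 1L
  c <- (idx - 1L) %/% nrow + 1L
  pts <- cbind(rep(c, 4) + rep(c(-0.5, -0.5, 0.5, 0.5), each = length(idx)),
               rep(r, 4) + rep(c(-0.5, 0.5, -0.5, 0.5), each = length(idx)))
  h <- grDevices::chull(pts)
  xy <- pts[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Euclidean distance from point p = c(x, y) to the convex polygon given by
# hull vertices (matrix, columns x, y, in hull order); 0 if inside
dist_point_polygon <- function(p, poly) {
  n <- nrow(poly)
  if (n == 1L) return(sqrt(sum((p - poly[1, ])^2)))
  if (n == 2L) return(dist_point_segment(p, poly[1, ], poly[2, ]))
  # inside test for convex polygon: consistent sign of cross products
  nxt <- c(seq_len(n)[-1], 1L)
  cr <- (poly[nxt, 1] - poly[, 1]) * (p[2] - poly[, 2]) -
        (poly[nxt, 2] - poly[, 2]) * (p[1] - poly[, 1])
  if (all(cr >= 0) || all(cr <= 0)) return(0)
  min(vapply(seq_len(n), function(i) {
    dist_point_segment(p, poly[i, ], poly[nxt[i], ])
  }, numeric(1)))
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((a + t * ab - p)^2))
}

# mm^2 from a pixel count
px_to_mm2 <- function(n_px, pixel_size) n_px * pixel_size^2 / 1e6
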