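#' Randomized study-condition layout for a synthetic ROI
#'
#' Builds a [synthetic_spec()] emulating the tissue content the pipeline
#' assumes: a tissue disk with two S100+ tumor nests, `n_vessels` annular
#' vessels spread over the five lymphovascular subtypes (a subset of the
#' blood vessels placed intratumorally, all lymphatics peritumoral),
#' `n_cells` leukocyte/non-leukocyte disks split over the five classes in
#' both regions, and `n_tls` peritumoral lymphocyte aggregates each with an
#' associated MECA79+ (HEV-like) blood vessel drawn from the vessel budget.
#' Objects are placed by rejection sampling with non-overlap margins so the
#' planted layout is exactly recoverable at zero noise; the spec seed fixes
#' the layout and the rendered noise.
#'
#' @param n_vessels Total vessels (default 20).
#' @param n_cells Total cells including TLS members (default 300).
#' @param n_tls Number of TLS aggregates (default 1).
#' @param seed Integer seed.
#' @param image_shape,pixel_size Frame geometry (defaults 1000 x 1000 px at
#'   1 um/px, i.e. a 1 mm^2 desk-scale ROI; use
#'   `image_shape = c(5000, 5000), pixel_size = 0.5` for the 6.25 mm^2
#'   whole-slide preset).
#' @param it_cell_frac Fraction of scattered cells placed intratumorally.
#' @param ... Passed on to [synthetic_spec()] (noise, contrast, ...).
#' @return A `synthetic_spec`.
#' @export
random_roi_spec <- function(n_vessels = 20, n_cells = 300, n_tls = 1,
                            seed = 1L, image_shape = c(1000L, 1000L),
                            pixel_size = 1, it_cell_frac = 0.4, ...) {
  set.seed(seed)
  fov <- min(image_shape) * pixel_size
  cx <- image_shape[2] * pixel_size / 2
  cy <- image_shape[1] * pixel_size / 2
  tis_r <- 0.38 * fov
  scl <- fov / 1000           # geometry scales with the field of view
  nest_r <- 150 * scl
  nests <- tibble(x_um = c(cx - 180 * scl, cx + 180 * scl),
                  y_um = c(cy, cy), radius_um = nest_r)

  tls_r <- 100 * scl
  tls <- empty_spec_tls()
  if (n_tls > 0) {
    ang <- seq(-pi / 2, by = 2 * pi / max(n_tls, 3), length.out = n_tls)
    tls <- tibble(tls_id = seq_len(n_tls),
                  x_um = cx + (tis_r - tls_r - 30 * scl) * cos(ang),
                  y_um = cy + (tis_r - tls_r - 30 * scl) * sin(ang),
                  radius_um = tls_r,
                  n_cd8 = 15L, n_cd20 = 20L, hev_vessel = TRUE)
  }

  # ---- vessels ----------------------------------------------------------
  subtype_cycle <- rep(names(subtype_marker_sets()),
                       length.out = n_vessels)
  blood_idx <- which(subtype_cycle %in% blood_subtypes())
  n_it <- min(6L, max(0L, length(blood_idx) - n_tls))
  it_idx <- blood_idx[seq_len(n_it)]
  hev_idx <- integer(0)
  if (n_tls > 0 && sum(tls$hev_vessel) > 0) {
    cand <- setdiff(which(subtype_cycle == "ACTIVATED_CAP_PCV"), it_idx)
    hev_idx <- utils::head(cand, sum(tls$hev_vessel))
  }
  placed <- tibble(x_um = numeric(), y_um = numeric(), r_um = numeric())
  vs <- vector("list", n_vessels)
  hev_k <- 0L
  for (i in seq_len(n_vessels)) {
    ro <- stats::runif(1, 18, 28) * scl
    wall <- stats::runif(1, 6, 9) * scl
    if (i %in% hev_idx) {
      hev_k <- hev_k + 1L
      trow <- tls[which(tls$hev_vessel)[hev_k], ]
      # sit just outside the aggregate margin, biased back toward the
      # tissue center so the vessel stays inside tissue
      base <- atan2(cy - trow$y_um, cx - trow$x_um)
      p <- place_point(
        function() {
          th <- base + stats::runif(1, -pi / 3, pi / 3)
          c(trow$x_um + (trow$radius_um + ro + 10 * scl) * cos(th),
            trow$y_um + (trow$radius_um + ro + 10 * scl) * sin(th))
        },
        function(p) min_gap_ok(p, ro, placed, 10 * scl))
    } else if (i %in% it_idx) {
      nst <- nests[1L + (match(i, it_idx) %% 2L), ]
      p <- place_point(
        function() jitter_in_disk(nst$x_um, nst$y_um, nest_r - ro - 15 * scl),
        function(p) min_gap_ok(p, ro, placed, 10 * scl))
    } else {
      p <- place_point(
        function() jitter_in_disk(cx, cy, tis_r - ro - 10 * scl),
        function(p) min_gap_ok(p, ro, placed, 10 * scl) &&
          all(sqrt((p[1] - nests$x_um)^2 + (p[2] - nests$y_um)^2) >
                nest_r + ro + 15 * scl) &&
          all(sqrt((p[1] - tls$x_um)^2 + (p[2] - tls$y_um)^2) >
                tls_r + ro + 15 * scl))
    }
    placed <- bind_rows(placed, tibble(x_um = p[1], y_um = p[2], r_um = ro))
    vs[[i]] <- tibble(x_um = p[1], y_um = p[2], outer_radius_um = ro,
                      wall_um = wall, subtype = subtype_cycle[i],
                      hev = i %in% hev_idx)
  }
  vessels <- if (n_vessels > 0) bind_rows(vs) else empty_spec_vessels()

  # ---- cells ------------------------------------------------------------
  cell_r <- 4 * scl
  spacing <- 14 * scl
  n_members <- if (n_tls > 0) sum(tls$n_cd8 + tls$n_cd20) else 0L
  n_scatter <- n_cells - n_members
  if (n_scatter < 0) abort("n_cells smaller than TLS membership")
  props <- c(CD8_T = 0.20, B_CELL = 0.12, MACROPHAGE = 0.23,
             OTHER_CD45 = 0.22, NON_LEUKOCYTE = 0.23)
  counts <- round(props * n_scatter)
  counts[1] <- n_scatter - sum(counts[-1])
  classes <- rep(names(counts), counts)
  in_it <- seq_along(classes) %in%
    unlist(purrr::map(split(seq_along(classes), classes),
                      ~ utils::head(.x, round(length(.x) * it_cell_frac))))
  cpts <- tibble(x_um = numeric(), y_um = numeric())
  vkeep <- function(p) {
    all(sqrt((p[1] - vessels$x_um)^2 + (p[2] - vessels$y_um)^2) >
          vessels$outer_radius_um + cell_r + 8 * scl) &&
      (nrow(cpts) == 0 ||
         min(sqrt((p[1] - cpts$x_um)^2 + (p[2] - cpts$y_um)^2)) > spacing)
  }
  # scattered peritumoral lymphocytes are dispersed beyond the TLS link
  # radius so the planted aggregates are the only true co-aggregates
  # (otherwise the TLS ground truth would be ill-defined)
  disperse <- 52 * scl
  lpts <- tibble(x_um = numeric(), y_um = numeric())
  cl <- vector("list", n_scatter)
  for (i in seq_len(n_scatter)) {
    lymph_pt <- classes[i] %in% c("CD8_T", "B_CELL") && !in_it[i]
    if (in_it[i]) {
      nst <- nests[1L + (i %% 2L), ]
      p <- place_point(
        function() jitter_in_disk(nst$x_um, nst$y_um,
                                  nest_r - cell_r - 12 * scl),
        vkeep)
    } else {
      p <- place_point(
        function() jitter_in_disk(cx, cy, tis_r - cell_r - 12 * scl),
        function(p) vkeep(p) &&
          all(sqrt((p[1] - nests$x_um)^2 + (p[2] - nests$y_um)^2) >
                nest_r + cell_r + 12 * scl) &&
          all(sqrt((p[1] - tls$x_um)^2 + (p[2] - tls$y_um)^2) >
                tls_r + cell_r + 12 * scl) &&
          (!lymph_pt || nrow(lpts) == 0 ||
             min(sqrt((p[1] - lpts$x_um)^2 + (p[2] - lpts$y_um)^2)) >
               disperse))
    }
    cpts <- bind_rows(cpts, tibble(x_um = p[1], y_um = p[2]))
    if (lymph_pt) lpts <- bind_rows(lpts, tibble(x_um = p[1], y_um = p[2]))
    cl[[i]] <- tibble(x_um = p[1], y_um = p[2], radius_um = cell_r,
                      class = classes[i], tls_id = NA_integer_)
  }
  cells <- bind_rows(cl)

  # TLS members: CD8 T and CD20 B cells co-aggregated inside each TLS disk
  for (t in seq_len(nrow(tls))) {
    trow <- tls[t, ]
    mcl <- c(rep("CD8_T", trow$n_cd8), rep("B_CELL", trow$n_cd20))
    for (k in seq_along(mcl)) {
      p <- place_point(
        function() jitter_in_disk(trow$x_um, trow$y_um,
                                  trow$radius_um - cell_r),
        vkeep)
      cpts <- bind_rows(cpts, tibble(x_um = p[1], y_um = p[2]))
      cells <- bind_rows(cells,
                         tibble(x_um = p[1], y_um = p[2], radius_um = cell_r,
                                class = mcl[k], tls_id = trow$tls_id))
    }
  }

  synthetic_spec(image_shape = image_shape, pixel_size = pixel_size,
                 tumor_nests = nests, vessels = vessels, cells = cells,
                 tls = tls, seed = seed, ...)
}

# uniform point in a disk
jitter_in_disk <- function(cx, cy, r) {
  th <- stats::runif(1, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(1))
  c(cx + rr * cos(th), cy + rr * sin(th))
}

# rejection sampling with a hard cap on attempts
place_point <- function(proposal, ok, max_tries = 20000L) {
  for (i in seq_len(max_tries)) {
    p <- proposal()
    if (ok(p)) return(p)
  }
  abort("could not place object without overlap; reduce object count")
}

min_gap_ok <- function(p, r, placed, margin) {
  nrow(placed) == 0 ||
    all(sqrt((p[1] - placed$x_um)^2 + (p[2] - placed$y_um)^2) >
          r + placed$r_um + margin)
}
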