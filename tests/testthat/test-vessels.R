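test_that("preprocessing flattens fields and preserves vessel contrast", {
  flat <- matrix(0.7, 120, 120)
  expect_equal(max(abs(preprocess_channel(flat, median = FALSE,
                                          tophat_radius_px = 10))), 0)
  # linear illumination gradient + one annulus
  grad <- outer(seq(0, 0.3, length.out = 200), rep(1, 200))
  ring <- lymphovasc:::annulus_mask(c(200, 200), c(100, 100), 25, 8)
  x <- grad + ring * 1.0
  out <- preprocess_channel(x, median = FALSE, tophat_radius_px = 25)
  inner <- out[30:170, 30:170]
  ring_in <- ring[30:170, 30:170]
  expect_lt(max(inner[!ring_in]), 0.1)              # gradient removed
  expect_gt(median(inner[ring_in]), 0.9)            # contrast within 10%
})

test_that("median denoise leaves monotone structure unchanged", {
  ramp <- outer(rep(1, 40), seq(0, 1, length.out = 40))   # linear in x
  expect_equal(lymphovasc:::median3x3(ramp), ramp, tolerance = 1e-12)
  flat <- matrix(0.7, 30, 30)
  expect_identical(lymphovasc:::median3x3(flat), flat)
})

test_that("planted vessels are segmented with accurate areas at zero noise", {
  set.seed(41)
  n <- 12L
  ang <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  vs <- tibble::tibble(
    x_um = 400 + 280 * cos(ang), y_um = 400 + 280 * sin(ang),
    outer_radius_um = runif(n, 18, 26), wall_um = runif(n, 6, 9),
    subtype = rep(names(lymphovasc:::subtype_marker_sets()),
                  length.out = n),
    hev = FALSE)
  spec <- synthetic_spec(image_shape = c(800, 800), tissue = "all",
                         vessels = vs, noise_sd = 0, seed = 2)
  roi <- generate_roi(spec)
  masks <- make_region_masks(matrix(TRUE, 800, 800),
                             matrix(FALSE, 800, 800), 1)
  v <- segment_vessels(roi$stack, masks, median = FALSE)
  expect_identical(nrow(v), n)
  ev <- evaluate_vessels(roi$truth$vessels, classify_vessels(v), 1)
  expect_identical(ev$tp, n)
  expect_lt(ev$max_area_rel_err, 0.05)
})

test_that("PDPN+panCK+ epithelium is excluded, PDPN+panCK- vessels kept", {
  shape <- c(300, 300)
  ribbon <- matrix(FALSE, 300, 300); ribbon[140:160, 20:280] <- TRUE
  ring <- lymphovasc:::annulus_mask(shape, c(70, 70), 22, 7)
  mk <- function(on, lvl = 1) matrix(0.2, 300, 300) + on * lvl
  stack <- channel_stack(list(
    AQP1 = mk(matrix(FALSE, 300, 300)),
    CD34 = mk(matrix(FALSE, 300, 300)),
    PDPN = mk(ribbon | ring),
    panCK = mk(ribbon),
    LYVE1 = mk(ring),
    aSMA = mk(matrix(FALSE, 300, 300))), 1)
  masks <- make_region_masks(matrix(TRUE, 300, 300),
                             matrix(FALSE, 300, 300), 1)
  v <- classify_vessels(segment_vessels(stack, masks, median = FALSE))
  expect_identical(nrow(v), 1L)
  expect_identical(as.character(v$subtype), "LYMPHATIC_CAP")
  expect_identical(attr(v, "removed")[["panck"]], 1L)
})

test_that("specks below the size filter are removed", {
  shape <- c(200, 200)
  speck <- lymphovasc:::disk_mask(shape, c(50, 50), 2.5)   # ~20 um^2
  ring <- lymphovasc:::annulus_mask(shape, c(140, 140), 20, 7)
  base <- matrix(0.2, 200, 200)
  stack <- channel_stack(list(AQP1 = base + speck + ring,
                              CD34 = base + ring, PDPN = base), 1)
  masks <- make_region_masks(matrix(TRUE, 200, 200),
                             matrix(FALSE, 200, 200), 1)
  v <- segment_vessels(stack, masks, min_area_um2 = 100, median = FALSE)
  expect_identical(nrow(v), 1L)
  expect_identical(attr(v, "removed")[["size"]], 1L)
})

test_that("shrinking the size window never increases the object count", {
  spec <- random_roi_spec(n_vessels = 10, n_cells = 0, n_tls = 0, seed = 9,
                          image_shape = c(700L, 700L))
  roi <- generate_roi(spec)
  masks <- roi$truth$masks
  wins <- list(c(50, 1e6), c(100, 1e5), c(300, 5e4), c(500, 5e3))
  ns <- vapply(wins, function(w) {
    nrow(segment_vessels(roi$stack, masks, min_area_um2 = w[1],
                         max_area_um2 = w[2]))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("missing required channels are reported by name", {
  stack <- channel_stack(list(AQP1 = matrix(runif(100), 10)), 1)
  masks <- make_region_masks(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10), 1)
  expect_error(segment_vessels(stack, masks), "CD34")
})

test_that("the hierarchical gate matches an independent truth table", {
  combos <- expand.grid(aqp1 = c(FALSE, TRUE), cd34 = c(FALSE, TRUE),
                        asma = c(FALSE, TRUE), pdpn = c(FALSE, TRUE),
                        lyve1 = c(FALSE, TRUE), meca79 = c(FALSE, TRUE))
  # independent oracle written as flat rules over the marker combinations
  oracle <- function(r) {
    if (r$aqp1 && r$cd34 && r$asma) return("IMMATURE_NEOVASC")
    if (r$aqp1 && r$cd34 && !r$asma) return("ACTIVATED_CAP_PCV")
    if (r$aqp1 && !r$cd34 && r$asma) return("ARTERIOLE")
    if (r$aqp1 && !r$cd34 && !r$asma) return("REJECTED_SINGLE_CELL")
    if (!r$aqp1 && r$pdpn && r$lyve1) return("LYMPHATIC_CAP")
    if (!r$aqp1 && r$pdpn && !r$lyve1) return("INFLAMED_LYMPHATIC_CAP")
    "UNCLASSIFIED_ANOMALY"
  }
  for (i in seq_len(nrow(combos))) {
    r <- combos[i, ]
    got <- classify_vessel(r$aqp1, r$cd34, r$asma, r$pdpn, r$lyve1, r$meca79)
    expect_identical(got$subtype, oracle(r))
    expect_identical(got$hev_like, r$aqp1 && r$meca79)
  }
})

test_that("named gate examples give the published subtype calls", {
  expect_identical(
    classify_vessel(TRUE, TRUE, FALSE, FALSE, FALSE)$subtype,
    "ACTIVATED_CAP_PCV")
  expect_identical(
    classify_vessel(FALSE, FALSE, FALSE, TRUE, FALSE)$subtype,
    "INFLAMED_LYMPHATIC_CAP")
  expect_identical(
    classify_vessel(TRUE, FALSE, FALSE, FALSE, FALSE)$subtype,
    "REJECTED_SINGLE_CELL")
  expect_identical(
    classify_vessel(FALSE, FALSE, FALSE, FALSE, FALSE)$subtype,
    "UNCLASSIFIED_ANOMALY")
})

test_that("gating partitions the object set across all subtypes", {
  spec <- random_roi_spec(n_vessels = 14, n_cells = 60, n_tls = 1, seed = 10,
                          image_shape = c(800L, 800L))
  roi <- generate_roi(spec)
  v <- classify_vessels(segment_vessels(roi$stack, roi$truth$masks))
  expect_false(any(is.na(v$subtype)))
  expect_identical(sum(table(v$subtype)), nrow(v))
  # family proportions sum to one when the family is present
  s <- summarize_roi(v, tibble::tibble(class = factor(character(),
                                                      levels = cell_classes()),
                                       region = character()),
                     roi$truth$masks, pixel_size = 1)
  blood <- unlist(s[paste0("prop_blood_", lymphovasc:::blood_subtypes())])
  lymph <- unlist(s[paste0("prop_lymph_", lymphovasc:::lymphatic_subtypes())])
  expect_equal(sum(blood), 1, tolerance = 1e-9)
  expect_equal(sum(lymph), 1, tolerance = 1e-9)
})

test_that("morphology features are accurate on analytic shapes", {
  shape <- c(100, 100)
  disc <- which(lymphovasc:::disk_mask(shape, c(50, 50), 20))
  m <- compute_morphology(disc, shape, pixel_size = 1)
  expect_lt(abs(m$area_um2 - pi * 400) / (pi * 400), 0.02)
  expect_lt(m$eccentricity, 0.1)
  expect_lt(m$lumen_area_um2 / m$area_um2, 0.02)
  expect_gt(m$solidity, 0.95)
  expect_lte(m$solidity, 1)

  ring <- which(lymphovasc:::annulus_mask(shape, c(50, 50), 20, 10))
  ma <- compute_morphology(ring, shape, 1)
  expect_lt(abs(ma$lumen_area_um2 - pi * 100) / (pi * 100), 0.05)
  expect_equal(ma$filled_area_um2 - ma$area_um2, ma$lumen_area_um2)

  line <- which(matrix(seq_len(100^2), 100) %in% (100 * (0:99) + 50))
  ml <- compute_morphology(line[1:100], shape, 1)
  expect_gt(ml$eccentricity, 0.99)
})

test_that("region assignment uses the strict majority rule", {
  masks <- square_masks(100, it_rows = 1:50)
  obj_in <- which(lymphovasc:::disk_mask(c(100, 100), c(25, 50), 10))
  expect_identical(lymphovasc:::region_of_pixels(obj_in, masks), "IT")
  # a 10-px column crossing the boundary at 40/60 -> PT
  col_idx <- function(rows, col) (col - 1) * 100 + rows
  expect_identical(
    lymphovasc:::region_of_pixels(col_idx(47:56, 10), masks), "PT")
  # exactly 50% -> PT (tie rule)
  expect_identical(
    lymphovasc:::region_of_pixels(col_idx(46:55, 10), masks), "PT")
  # entirely outside tissue -> NA
  out <- make_region_masks(matrix(FALSE, 100, 100),
                           matrix(FALSE, 100, 100), 1)
  expect_identical(lymphovasc:::region_of_pixels(col_idx(1:5, 1), out),
                   NA_character_)
})
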