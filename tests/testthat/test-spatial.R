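test_that("infiltration classification follows the ratio and edge rules", {
  expect_identical(classify_infiltration(10, 5)$infiltration, "INFILTRATED")
  expect_equal(classify_infiltration(10, 5)$ratio, 2)
  expect_identical(classify_infiltration(0, 8)$infiltration, "EXCLUDED")
  expect_identical(classify_infiltration(0, 0)$infiltration, "UNDEFINED")
  expect_identical(classify_infiltration(NA, 5)$infiltration, "UNDEFINED")
  expect_identical(classify_infiltration(3, 0)$infiltration, "INFILTRATED")
  # invariant to uniform rescaling
  for (s in c(0.01, 1, 250)) {
    expect_identical(classify_infiltration(4 * s, 9 * s)$infiltration,
                     classify_infiltration(4, 9)$infiltration)
  }
})

# build a gated cell table directly (px == um at pixel_size 1)
cell_table <- function(x, y, class) {
  tibble::tibble(cell_id = seq_along(x), row_px = y, col_px = x,
                 class = factor(class, levels = cell_classes()),
                 region = "PT")
}

test_that("a planted co-aggregate is detected as exactly one TLS", {
  set.seed(51)
  th <- runif(50, 0, 2 * pi); rr <- 100 * sqrt(runif(50))
  agg <- cell_table(500 + rr * cos(th), 500 + rr * sin(th),
                    rep(c("CD8_T", "B_CELL"), c(20, 30)))
  tls <- detect_tls(agg, pixel_size = 1)
  expect_identical(nrow(tls), 1L)
  expect_identical(tls$n_cd8, 20L)
  expect_identical(tls$n_cd20, 30L)
})

test_that("sparse uniform cells produce no TLS", {
  set.seed(52)
  sparse <- cell_table(runif(200, 0, 5000), runif(200, 0, 5000),
                       rep(c("CD8_T", "B_CELL"), 100))
  expect_identical(nrow(detect_tls(sparse, pixel_size = 1)), 0L)
})

test_that("co-aggregation of both lineages is required", {
  set.seed(53)
  th <- runif(30, 0, 2 * pi); rr <- 80 * sqrt(runif(30))
  t_only <- cell_table(300 + rr * cos(th), 300 + rr * sin(th),
                       rep("CD8_T", 30))
  expect_identical(nrow(detect_tls(t_only, pixel_size = 1)), 0L)
})

test_that("single-linkage clustering matches graph connected components", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (rep in 1:5) {
    n <- 150
    xy <- cbind(runif(n, 0, 1500), runif(n, 0, 1500))
    r <- 60
    cl <- stats::cutree(stats::hclust(dist(xy), method = "single"), h = r)
    d <- as.matrix(dist(xy))
    g <- igraph::graph_from_adjacency_matrix(d <= r, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # identical partitions (up to label names)
    expect_identical(length(unique(cl)), length(unique(comp)))
    expect_true(all(tapply(comp, cl, function(v) length(unique(v))) == 1))
  }
})

test_that("raising the link radius never shrinks a cluster", {
  set.seed(55)
  xy <- cbind(runif(80, 0, 800), runif(80, 0, 800))
  cells <- cell_table(xy[, 1], xy[, 2], rep(c("CD8_T", "B_CELL"), 40))
  members <- function(radius) {
    tls <- detect_tls(cells, pixel_size = 1, link_radius_um = radius,
                      min_cd8 = 1, min_cd20 = 1)
    sort(unlist(c(tls$cd8_ids, tls$cd20_ids)))
  }
  m1 <- members(40); m2 <- members(80); m3 <- members(160)
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))
})

test_that("vessels associate with a TLS by hull distance", {
  set.seed(56)
  th <- runif(40, 0, 2 * pi); rr <- 90 * sqrt(runif(40))
  cells <- cell_table(400 + rr * cos(th), 400 + rr * sin(th),
                      rep(c("CD8_T", "B_CELL"), 20))
  tls <- detect_tls(cells, pixel_size = 1)
  vessels <- tibble::tibble(
    vessel_id = 1:2,
    row_px = c(400, 900), col_px = c(400 + 110, 400),
    subtype = factor(c("ACTIVATED_CAP_PCV", "ACTIVATED_CAP_PCV"),
                     levels = vessel_subtypes()),
    hev_like = c(TRUE, TRUE))
  out <- associate_tls_vessels(tls, vessels, pixel_size = 1,
                               assoc_radius_um = 100)
  expect_identical(out$tls$hev_ids[[1]], 1L)    # ~20 um from hull
  expect_identical(out$counts$n_tls_with_hev, 1L)
  expect_identical(out$counts$n_hev_vessels, 2L)
})

test_that("three planted TLS each with one HEV-like vessel give counts (3,3)", {
  set.seed(57)
  centers <- cbind(c(300, 1200, 700), c(300, 400, 1300))
  cells <- NULL; vessels <- NULL
  for (i in 1:3) {
    th <- runif(30, 0, 2 * pi); rr <- 80 * sqrt(runif(30))
    cells <- dplyr::bind_rows(
      cells, cell_table(centers[i, 1] + rr * cos(th),
                        centers[i, 2] + rr * sin(th),
                        rep(c("CD8_T", "B_CELL"), 15)))
    vessels <- dplyr::bind_rows(
      vessels, tibble::tibble(row_px = centers[i, 2] + 95,
                              col_px = centers[i, 1],
                              subtype = factor("ACTIVATED_CAP_PCV",
                                               levels = vessel_subtypes()),
                              hev_like = TRUE))
  }
  cells$cell_id <- seq_len(nrow(cells))
  vessels$vessel_id <- seq_len(nrow(vessels))
  tls <- detect_tls(cells, pixel_size = 1)
  expect_identical(nrow(tls), 3L)
  out <- associate_tls_vessels(tls, vessels, pixel_size = 1)
  expect_identical(out$counts$n_tls, 3L)
  expect_identical(out$counts$n_hev_vessels, 3L)
  expect_identical(out$counts$n_tls_with_hev, 3L)
})

test_that("ROI summary proportions and ratios behave at the edges", {
  masks <- square_masks(200, it_rows = 1:100, pixel_size = 100)
  vessels <- tibble::tibble(
    vessel_id = 1:8, row_px = 50, col_px = seq(10, 80, by = 10),
    subtype = factor(rep(c("ACTIVATED_CAP_PCV", "IMMATURE_NEOVASC"), 4),
                     levels = vessel_subtypes()),
    hev_like = FALSE, region = "IT",
    area_um2 = 500)
  cells <- tibble::tibble(class = factor(c("CD8_T", "CD8_T", "MACROPHAGE"),
                                         levels = cell_classes()),
                          region = c("IT", "PT", "IT"),
                          row_px = 1, col_px = 1, cell_id = 1:3)
  s <- summarize_roi(vessels, cells, masks, pixel_size = 1)
  expect_equal(s$prop_blood_ACTIVATED_CAP_PCV, 0.5)
  expect_equal(s$prop_blood_IMMATURE_NEOVASC, 0.5)
  expect_equal(s$prop_blood_ARTERIOLE, 0)
  expect_true(is.na(s$prop_lymph_LYMPHATIC_CAP))   # empty family -> NA
  expect_equal(s$cd8_it_pt_ratio, 1)               # equal areas, 1 cell each
  expect_identical(s$infiltration, "INFILTRATED")
  expect_equal(s$cd8_cd68_ratio_it, 1)

  s0 <- summarize_roi(vessels[0, ], cells[0, ], masks, pixel_size = 1)
  expect_true(is.na(s0$prop_blood_ACTIVATED_CAP_PCV))
  expect_identical(s0$infiltration, "UNDEFINED")
  expect_true(is.na(s0$cd8_cd68_ratio_it))
})

test_that("summary densities recover the planted layout", {
  spec <- random_roi_spec(n_vessels = 12, n_cells = 150, n_tls = 1,
                          seed = 13, image_shape = c(800L, 800L))
  roi <- generate_roi(spec)
  v <- classify_vessels(segment_vessels(roi$stack, roi$truth$masks))
  cells <- gate_cells(segment_cells(roi$stack, roi$truth$masks))
  ed <- evaluate_densities(roi$truth, v, cells, roi$truth$masks)
  expect_true(all(ed$rel_err < 0.05))
})
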