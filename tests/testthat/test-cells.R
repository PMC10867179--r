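cell_grid_spec <- function(n = 50, classes = "OTHER_CD45", shape = c(500, 500),
                           noise_sd = 0, seed = 3, spacing = 40) {
  pos <- expand.grid(x = seq(40, shape[2] - 40, by = spacing),
                     y = seq(40, shape[1] - 40, by = spacing))[seq_len(n), ]
  synthetic_spec(
    image_shape = shape, tissue = "all",
    cells = tibble::tibble(x_um = pos$x, y_um = pos$y, radius_um = 4,
                           class = rep(classes, length.out = n),
                           tls_id = NA_integer_),
    noise_sd = noise_sd, seed = seed)
}

test_that("all planted non-touching nuclei are detected", {
  roi <- generate_roi(cell_grid_spec(50))
  cells <- segment_cells(roi$stack)
  expect_identical(nrow(cells), 50L)
  expect_true(all(!cells$size_flag))
  ev <- evaluate_cells(roi$truth$cells, gate_cells(cells), 1)
  expect_identical(ev$matched, 50L)
})

test_that("an empty image yields zero cells", {
  stack <- channel_stack(list(hematoxylin = matrix(0.3, 100, 100)), 1)
  expect_identical(nrow(segment_cells(stack)), 0L)
})

test_that("watershed splits touching nuclei with distinct centers", {
  shape <- c(120, 120)
  hema <- matrix(0.2, 120, 120)
  # two overlapping disks, centers 1.5 radii apart
  hema[lymphovasc:::disk_mask(shape, c(60, 55), 8)] <- 1.2
  hema[lymphovasc:::disk_mask(shape, c(60, 67), 8)] <- 1.2
  stack <- channel_stack(list(hematoxylin = hema), 1)
  cells <- segment_cells(stack)
  expect_identical(nrow(cells), 2L)
})

test_that("priority gating follows the lineage rules", {
  base <- tibble::tibble(cell_id = 1:5, row_px = 1:5, col_px = 1:5,
                         nucleus_area_um2 = 50, size_flag = FALSE,
                         mean_CD45 = c(1.0, 0.1, 1.0, 1.0, 0.0),
                         mean_CD8 = c(1.0, 0.0, 0.0, 0.0, 0.0),
                         mean_CD20 = c(0.0, 0.0, 1.0, 0.0, 0.0),
                         mean_CD68 = c(0.0, 1.0, 0.0, 0.0, 0.0))
  thr <- c(CD45 = 0.5, CD8 = 0.5, CD20 = 0.5, CD68 = 0.5)
  out <- gate_cells(base, thresholds = thr)
  expect_identical(as.character(out$class),
                   c("CD8_T",       # CD45 hi CD8 hi
                     "MACROPHAGE",  # CD45 lo CD68 hi: myeloid gate
                     "B_CELL", "OTHER_CD45", "NON_LEUKOCYTE"))
  expect_false(any(out$multi_lineage))
})

test_that("multi-lineage cells resolve to the strongest z-scored marker", {
  set.seed(44)
  n <- 60
  tb <- tibble::tibble(cell_id = 1:n, row_px = 1, col_px = 1,
                       nucleus_area_um2 = 50, size_flag = FALSE,
                       mean_CD45 = 1,
                       mean_CD8 = c(2.0, runif(n - 1, 0, 0.2)),
                       mean_CD20 = c(0.9, runif(n - 1, 0, 0.2)),
                       mean_CD68 = 0)
  thr <- c(CD45 = 0.5, CD8 = 0.5, CD20 = 0.5, CD68 = 0.5)
  expect_message(out <- gate_cells(tb, thresholds = thr), "multiple lineages")
  expect_identical(as.character(out$class[1]), "CD8_T")
  expect_true(out$multi_lineage[1])
})

test_that("planted class proportions are recovered on simulated cells", {
  spec <- random_roi_spec(n_vessels = 0, n_cells = 250, n_tls = 0,
                          seed = 12, image_shape = c(900L, 900L))
  roi <- generate_roi(spec)
  cells <- gate_cells(segment_cells(roi$stack, roi$truth$masks))
  ev <- evaluate_cells(roi$truth$cells, cells, 1)
  expect_gte(ev$recovery, 0.98)
  # class counts within binomial error of the planted proportions
  planted <- table(factor(roi$truth$cells$class, levels = cell_classes()))
  got <- table(cells$class)
  for (cl in cell_classes()) {
    p <- planted[[cl]] / 250
    se <- sqrt(p * (1 - p) * 250)
    expect_lt(abs(got[[cl]] - planted[[cl]]), max(3 * se, 3))
  }
})

test_that("cell densities divide counts by region area, NA when empty", {
  masks <- square_masks(200, it_rows = 1:100, pixel_size = 10)  # 2 mm2 IT
  cells <- tibble::tibble(
    class = factor(rep("CD8_T", 10), levels = cell_classes()),
    region = rep("IT", 10))
  d <- cell_densities(cells, masks)
  expect_equal(d$density_per_mm2[d$class == "CD8_T" & d$region == "IT"], 5)
  expect_equal(d$density_per_mm2[d$class == "CD8_T" & d$region == "PT"], 0)
  expect_identical(sum(d$n), 10L)

  none <- make_region_masks(matrix(TRUE, 10, 10), matrix(TRUE, 10, 10), 1)
  d0 <- cell_densities(cells[0, ], none)   # PT area zero
  expect_true(all(is.na(d0$density_per_mm2[d0$region == "PT"])))
})

test_that("densities are invariant to pixel size at fixed physical layout", {
  mk <- function(ps) {
    spec <- synthetic_spec(
      image_shape = c(800, 800) / ps, pixel_size = ps,
      tissue = list(x_um = 400, y_um = 400, radius_um = 300),
      tumor_nests = tibble::tibble(x_um = 400, y_um = 400, radius_um = 120),
      cells = tibble::tibble(
        x_um = c(seq(340, 460, by = 20), seq(150, 650, by = 50)),
        y_um = c(rep(400, 7), rep(180, 11)),
        radius_um = 4, class = "CD8_T", tls_id = NA_integer_),
      noise_sd = 0, seed = 1)
    roi <- generate_roi(spec)
    cells <- gate_cells(segment_cells(roi$stack, roi$truth$masks),
                        thresholds = c(CD45 = 0.6, CD8 = 0.6, CD20 = 0.6,
                                       CD68 = 0.6))
    cell_densities(cells, roi$truth$masks)
  }
  d1 <- mk(1); d2 <- mk(2)
  it1 <- d1$density_per_mm2[d1$class == "CD8_T" & d1$region == "IT"]
  it2 <- d2$density_per_mm2[d2$class == "CD8_T" & d2$region == "IT"]
  expect_lt(abs(it1 - it2) / it1, 0.05)
})

test_that("nuclei outside the sanity band are flagged, not dropped", {
  shape <- c(200, 200)
  hema <- matrix(0.2, 200, 200)
  hema[lymphovasc:::disk_mask(shape, c(60, 60), 4)] <- 1.2    # ~50 um^2
  hema[lymphovasc:::disk_mask(shape, c(140, 140), 12)] <- 1.2 # ~450 um^2
  stack <- channel_stack(list(hematoxylin = hema), 1)
  cells <- segment_cells(stack)
  expect_identical(nrow(cells), 2L)
  expect_identical(sort(cells$size_flag), c(FALSE, TRUE))
})
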