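#' Greedy centroid matching between planted and detected objects
#'
#' Pairs truth and detected objects by increasing centroid distance,
#' accepting a pair when both partners are still free and the distance is
#' within `max_dist`. Used to score detection against the generator's
#' ground truth.
#'
#' @param truth_xy,det_xy Two-column matrices (x, y) in um.
#' @param max_dist Maximum pairing distance in um.
#' @return Tibble (`truth_idx`, `det_idx`, `dist`).
#' @export
match_objects <- function(truth_xy, det_xy, max_dist) {
  if (nrow(truth_xy) == 0 || nrow(det_xy) == 0)
    return(tibble(truth_idx = integer(), det_idx = integer(),
                  dist = numeric()))
  d <- outer(seq_len(nrow(truth_xy)), seq_len(nrow(det_xy)),
             Vectorize(function(i, j) {
               sqrt(sum((truth_xy[i, ] - det_xy[j, ])^2))
             }))
  ord <- order(d)
  used_t <- logical(nrow(truth_xy)); used_d <- logical(nrow(det_xy))
  out <- list()
  for (k in ord) {
    if (d[k] > max_dist) break
    ij <- arrayInd(k, dim(d))
    if (used_t[ij[1]] || used_d[ij[2]]) next
    used_t[ij[1]] <- TRUE; used_d[ij[2]] <- TRUE
    out[[length(out) + 1L]] <- tibble(truth_idx = ij[1], det_idx = ij[2],
                                      dist = d[k])
  }
  if (length(out)) bind_rows(out) else
    tibble(truth_idx = integer(), det_idx = integer(), dist = numeric())
}

#' Score vessel detection and subtyping against planted truth
#'
#' A detected vessel is a true positive when it matches a planted vessel
#' within `max_dist_um` *and* carries its subtype; matched vessels with the
#' wrong subtype count as both a false positive and a false negative.
#'
#' @param truth Truth vessel table from [generate_roi()].
#' @param vessels Classified vessel table ([classify_vessels()]).
#' @param pixel_size um/px.
#' @param max_dist_um Matching radius (default 15 um).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `subtype_accuracy` (among position matches), `max_area_rel_err` over
#'   position matches.
#' @export
evaluate_vessels <- function(truth, vessels, pixel_size, max_dist_um = 15) {
  t_xy <- cbind(truth$x_um, truth$y_um)
  d_xy <- cbind(vessels$col_px * pixel_size, vessels$row_px * pixel_size)
  m <- match_objects(t_xy, d_xy, max_dist_um)
  sub_ok <- if (nrow(m)) {
    as.character(truth$subtype[m$truth_idx]) ==
      as.character(vessels$subtype[m$det_idx])
  } else logical(0)
  tp <- sum(sub_ok)
  fp <- nrow(vessels) - tp
  fn <- nrow(truth) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
  area_err <- if (nrow(m)) {
    max(abs(vessels$area_um2[m$det_idx] -
              truth$area_px[m$truth_idx] * pixel_size^2) /
          (truth$area_px[m$truth_idx] * pixel_size^2))
  } else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1,
         subtype_accuracy = if (nrow(m)) mean(sub_ok) else NA_real_,
         max_area_rel_err = area_err)
}

#' Score cell detection and classing against planted truth
#'
#' @param truth Truth cell table from [generate_roi()].
#' @param cells Gated cell table.
#' @param pixel_size um/px.
#' @param max_dist_um Matching radius (default 6 um).
#' @return One-row tibble: `n_truth`, `n_detected`, `matched`,
#'   `class_correct`, `recovery` (fraction of planted cells recovered with
#'   the correct class).
#' @export
evaluate_cells <- function(truth, cells, pixel_size, max_dist_um = 6) {
  t_xy <- cbind(truth$x_um, truth$y_um)
  d_xy <- cbind(cells$col_px * pixel_size, cells$row_px * pixel_size)
  m <- match_objects(t_xy, d_xy, max_dist_um)
  ok <- if (nrow(m)) {
    truth$class[m$truth_idx] == as.character(cells$class[m$det_idx])
  } else logical(0)
  tibble(n_truth = nrow(truth), n_detected = nrow(cells),
         matched = nrow(m), class_correct = sum(ok),
         recovery = if (nrow(truth)) sum(ok) / nrow(truth) else NA_real_)
}

#' Compare measured region densities with planted truth
#'
#' Computes per-region cell-class and vessel-subtype densities from the
#' ground-truth tables over the true region areas, and the same quantities
#' from the pipeline's tables over the segmented region areas, for every
#' quantity with a nonzero planted count.
#'
#' @param truth Truth list from [generate_roi()].
#' @param vessels,cells,masks Pipeline outputs for the same ROI.
#' @return Tibble (`quantity`, `truth`, `measured`, `rel_err`).
#' @export
evaluate_densities <- function(truth, vessels, cells, masks) {
  t_area <- function(reg) region_area(truth$masks, reg)
  m_area <- function(reg) region_area(masks, reg)
  rows <- list()
  for (reg in c("IT", "PT")) {
    for (cl in cell_classes()) {
      nt <- sum(truth$cells$class == cl & truth$cells$region == reg)
      if (nt == 0) next
      nm <- sum(as.character(cells$class) == cl & cells$region == reg)
      rows[[length(rows) + 1L]] <- tibble(
        quantity = paste0("cells_", cl, "_", reg),
        truth = nt / t_area(reg), measured = nm / m_area(reg))
    }
    for (st in names(subtype_marker_sets())) {
      nt <- sum(truth$vessels$subtype == st & truth$vessels$region == reg)
      if (nt == 0) next
      nm <- sum(as.character(vessels$subtype) == st & vessels$region == reg)
      rows[[length(rows) + 1L]] <- tibble(
        quantity = paste0("vessels_", st, "_", reg),
        truth = nt / t_area(reg), measured = nm / m_area(reg))
    }
  }
  bind_rows(rows) |>
    mutate(rel_err = abs(.data$measured - .data$truth) / .data$truth)
}
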