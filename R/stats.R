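#' Aggregate ROI summaries to samples
#'
#' Per-sample plain means over each sample's ROIs, excluding missing ROI
#' values pairwise; records the number of ROIs per sample and carries any
#' covariate columns of the manifest through unchanged.
#'
#' @param roi_summaries Tibble of [summarize_roi()] rows (one per ROI) with
#'   a `roi_id` column.
#' @param manifest Tibble mapping `roi_id` to `sample_id` (plus optional
#'   covariates such as sentinel-LN status, ulceration, thickness, stage).
#' @return Tibble, one row per sample: covariates, `n_rois`, and the mean of
#'   every numeric ROI field.
#' @export
aggregate_samples <- function(roi_summaries, manifest) {
  stopifnot("roi_id" %in% names(roi_summaries),
            all(c("roi_id", "sample_id") %in% names(manifest)))
  unmapped <- setdiff(roi_summaries$roi_id, manifest$roi_id)
  if (length(unmapped))
    abort(paste0("ROI(s) not in manifest: ", paste(unmapped, collapse = ", ")))
  if (anyDuplicated(manifest$roi_id))
    abort("manifest maps some roi_id to more than one sample")
  joined <- left_join(roi_summaries, manifest, by = "roi_id")
  covars <- setdiff(names(manifest), c("roi_id", "sample_id"))
  num <- setdiff(names(roi_summaries)[vapply(roi_summaries, is.numeric,
                                             logical(1))], "roi_id")
  out <- joined |>
    group_by(.data$sample_id) |>
    summarize(n_rois = n(),
              across(all_of(covars), ~ .x[1]),
              across(all_of(num), ~ {
                m <- mean(.x, na.rm = TRUE)
                if (is.nan(m)) NA_real_ else m
              }),
              .groups = "drop")
  out
}

#' Compare two groups with normality-guided test selection
#'
#' Each group is tested for normality (Shapiro-Wilk at alpha = 0.05); if
#' both pass, a Student's t test is used (paired when requested), otherwise
#' the rank test (Mann-Whitney, or Wilcoxon signed-rank when paired). The
#' chosen test is reported with its statistic and raw p value; no
#' multiplicity correction is applied.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param paired Logical; paired design (lengths must match).
#' @return One-row tibble: `method`, `statistic`, `p_value`, `normal_a`,
#'   `normal_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    abort("insufficient data: each group needs n >= 3")
  if (paired && length(values_a) != length(values_b))
    abort("paired comparison needs equal lengths")
  norm_a <- shapiro_ok(values_a)
  norm_b <- shapiro_ok(values_b)
  if (norm_a && norm_b) {
    ht <- stats::t.test(values_a, values_b, paired = paired)
    method <- if (paired) "paired t test" else "t test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = paired))
    method <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  tibble(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value, normal_a = norm_a, normal_b = norm_b,
         n_a = length(values_a), n_b = length(values_b))
}

shapiro_ok <- function(x, alpha = 0.05) {
  if (stats::sd(x) == 0) return(FALSE)   # degenerate: treat as non-normal
  stats::shapiro.test(x)$p.value > alpha
}

#' Correlate two variables with normality-guided method selection
#'
#' Pearson when both variables pass Shapiro-Wilk normality (alpha 0.05),
#' Spearman otherwise; pairwise deletion of missing values. Constant input
#' yields an undefined (NA) coefficient with a flag rather than an error.
#'
#' @param x,y Numeric vectors of equal length; n >= 4 after deletion.
#' @return One-row tibble: `method`, `estimate`, `p_value`, `n`, `degenerate`.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) abort("insufficient data: need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: correlation undefined")
    return(tibble(method = NA_character_, estimate = NA_real_,
                  p_value = NA_real_, n = length(x), degenerate = TRUE))
  }
  method <- if (shapiro_ok(x) && shapiro_ok(y)) "pearson" else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble(method = method, estimate = unname(ht$estimate),
         p_value = ht$p.value, n = length(x), degenerate = FALSE)
}

#' One-way ANOVA across groups
#'
#' Classical one-way ANOVA for three or more groups; with exactly two
#' groups the comparison is delegated to [compare_groups()].
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character vector of group labels, same length.
#' @return One-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2) abort("degenerate input: need >= 2 groups")
  if (any(sizes < 2)) abort("degenerate input: every group needs n >= 2")
  if (length(sizes) == 2) {
    cg <- compare_groups(values[groups == levels(groups)[1]],
                         values[groups == levels(groups)[2]])
    return(tibble(method = cg$method, statistic = cg$statistic,
                  df1 = NA_real_, df2 = NA_real_, p_value = cg$p_value))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tibble(method = "one-way ANOVA", statistic = s[["F value"]][1],
         df1 = s[["Df"]][1], df2 = s[["Df"]][2],
         p_value = s[["Pr(>F)"]][1])
}

#' Cluster samples into inflammatory subtypes
#'
#' Operationalizes the three observed inflammatory environments: each
#' sample's leukocyte-density profile (CD8, CD68, CD20, other CD45) is
#' z-scored within the sample (row scaling; constant rows become all-zero
#' and are flagged), samples are clustered by Ward's method on Euclidean
#' distance, and the tree is cut at `k`. Cluster labels are renumbered by
#' descending mean raw CD8 density so label 1 is always the most
#' CD8-inflamed subtype.
#'
#' @param mat Numeric matrix or data frame, samples x markers; must contain
#'   a CD8 column (matched by name, case-insensitive, else column 1).
#' @param k Number of subtypes (default 3).
#' @return An `inflam_subtypes` object: `labels` (named integer vector),
#'   `scaled` matrix, `order` (dendrogram order), `hclust`, `k`,
#'   `constant_rows` flags. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
inflammatory_subtypes <- function(mat, k = 3) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sample", seq_len(nrow(mat)))
  if (k > nrow(mat)) abort("k exceeds the number of samples")
  sds <- apply(mat, 1, stats::sd)
  const <- sds == 0
  scaled <- t(apply(mat, 1, function(r) {
    if (stats::sd(r) == 0) rep(0, length(r)) else (r - mean(r)) / stats::sd(r)
  }))
  colnames(scaled) <- colnames(mat)
  if (any(const))
    warn(sprintf("%d constant row(s) scaled to zero", sum(const)))
  hc <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  raw_labels <- if (k == 1) rep(1L, nrow(mat)) else stats::cutree(hc, k = k)
  cd8_col <- grep("cd8", colnames(mat), ignore.case = TRUE)[1]
  if (is.na(cd8_col)) cd8_col <- 1L
  cd8_mean <- vapply(seq_len(k), function(g) {
    mean(mat[raw_labels == g, cd8_col])
  }, numeric(1))
  remap <- match(seq_len(k), order(cd8_mean, decreasing = TRUE))
  labels <- stats::setNames(remap[raw_labels], rownames(mat))
  structure(list(labels = labels, scaled = scaled, order = hc$order,
                 hclust = hc, k = k, constant_rows = const),
            class = "inflam_subtypes")
}

#' @export
print.inflam_subtypes <- function(x, ...) {
  cat(sprintf("<inflam_subtypes> %d sample(s) in %d subtype(s): ",
              length(x$labels), x$k))
  cat(paste(sprintf("%d (n=%d)", seq_len(x$k), tabulate(x$labels, x$k)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.inflam_subtypes <- function(x, ...) {
  tibble(sample_id = names(x$labels), subtype = unname(x$labels),
         constant_profile = unname(x$constant_rows),
         dendrogram_position = match(seq_along(x$labels), x$order))
}

#' @export
glance.inflam_subtypes <- function(x, ...) {
  tibble(n_samples = length(x$labels), k = x$k,
         n_constant = sum(x$constant_rows),
         merge_height_max = max(x$hclust$height))
}

#' Sample accounting for a cohort
#'
#' Bookkeeping for cohort assembly: how many samples passed quality
#' assessment per group, how many were excluded afterwards, and the
#' resulting analyzed cohort size. Errors if exclusions exceed intake.
#'
#' @param passed Named integer vector of samples passing quality assessment
#'   per group (e.g. sentinel-LN negative/positive).
#' @param excluded Total samples excluded after quality assessment.
#' @return One-row tibble with per-group intake, `n_passed`, `n_excluded`,
#'   `n_analyzed`.
#' @export
cohort_accounting <- function(passed, excluded = 0L) {
  stopifnot(all(passed >= 0), excluded >= 0)
  n_passed <- sum(passed)
  if (excluded > n_passed) abort("cannot exclude more samples than passed")
  bind_cols(
    as_tibble(as.list(stats::setNames(as.integer(passed),
                                      paste0("passed_", names(passed) %||%
                                               seq_along(passed))))),
    tibble(n_passed = as.integer(n_passed),
           n_excluded = as.integer(excluded),
           n_analyzed = as.integer(n_passed - excluded)))
}
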