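test_that("sample aggregation takes plain means with pairwise deletion", {
  rois <- tibble::tibble(roi_id = c("r1", "r2", "r3", "r4"),
                         d = c(2, 4, 2, NA), e = c(1, NA, 4, 8))
  man <- tibble::tibble(roi_id = paste0("r", 1:4),
                        sample_id = c("s1", "s1", "s2", "s2"),
                        sln = c("Neg", "Neg", "Pos", "Pos"))
  out <- aggregate_samples(rois, man)
  expect_equal(out$d[out$sample_id == "s1"], 3)
  expect_equal(out$e[out$sample_id == "s1"], 1)     # single non-missing
  expect_equal(out$d[out$sample_id == "s2"], 2)     # [2, NA] -> 2
  expect_identical(out$n_rois, c(2L, 2L))
  expect_identical(out$sln, c("Neg", "Pos"))

  expect_error(aggregate_samples(rois, man[-1, ]), "not in manifest")
})

test_that("single-ROI samples aggregate to themselves", {
  rois <- tibble::tibble(roi_id = "r1", v = 7.5)
  man <- tibble::tibble(roi_id = "r1", sample_id = "s1")
  expect_equal(aggregate_samples(rois, man)$v, 7.5)
})

test_that("test selection follows per-group normality", {
  set.seed(61)
  a <- rnorm(50); b <- rnorm(50, 1)
  out <- compare_groups(a, b)
  expect_identical(out$method, "t test")
  expect_lt(out$p_value, 0.01)

  la <- rlnorm(50, sdlog = 1.5); lb <- rlnorm(50, sdlog = 1.5)
  out2 <- compare_groups(la, lb)
  expect_identical(out2$method, "Mann-Whitney")

  outp <- compare_groups(a, b, paired = TRUE)
  expect_identical(outp$method, "paired t test")
})

test_that("identical groups give a null t statistic", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.05, 6.1, 2.2, 3.3)
  out <- compare_groups(x, x)
  expect_lt(abs(out$statistic), 1e-12)
  expect_equal(out$p_value, 1)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient")
})

test_that("correlation method tracks normality and handles monotone data", {
  set.seed(62)
  x <- rnorm(30)
  out <- correlate(x, 2 * x)
  expect_identical(out$method, "pearson")
  expect_equal(out$estimate, 1)

  xs <- rlnorm(30, sdlog = 1.4)
  out2 <- correlate(xs, exp(xs / max(xs) * 3))   # monotone nonlinear
  expect_identical(out2$method, "spearman")
  expect_equal(out2$estimate, 1)

  expect_warning(out3 <- correlate(rep(1, 10), rnorm(10)), "constant")
  expect_true(out3$degenerate)
  expect_error(correlate(1:3, 1:3), "insufficient")
})

test_that("one-way ANOVA matches the hand-computed 3x3 example", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  out <- anova_oneway(vals, grp)
  expect_identical(out$method, "one-way ANOVA")
  expect_equal(out$statistic, 3)            # SSB/2 / (SSW/6) = 3/1
  expect_equal(out$p_value, pf(3, 2, 6, lower.tail = FALSE))

  same <- anova_oneway(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$statistic, 1e-12)
})

test_that("two groups delegate to the pairwise comparison", {
  set.seed(63)
  out <- anova_oneway(c(rnorm(10), rnorm(10, 2)), rep(c("a", "b"), each = 10))
  expect_true(out$method %in% c("t test", "Mann-Whitney"))
  expect_error(anova_oneway(1:4, c("a", "a", "a", "b")), "degenerate")
})

test_that("row scaling leaves zero-mean unit-sd rows and flags constants", {
  set.seed(64)
  m <- matrix(rexp(40, 0.1), 10, 4,
              dimnames = list(paste0("s", 1:10),
                              c("CD8", "CD68", "CD20", "OTHER_CD45")))
  m[3, ] <- 5                                # constant profile
  expect_warning(fit <- inflammatory_subtypes(m, k = 2), "constant")
  sc <- fit$scaled
  for (i in seq_len(nrow(sc))) {
    if (i == 3) { expect_true(all(sc[i, ] == 0)); next }
    expect_lt(abs(mean(sc[i, ])), 1e-9)
    expect_lt(abs(sd(sc[i, ]) - 1), 1e-9)
  }
  expect_true(fit$constant_rows[3])
})

test_that("planted inflammatory archetypes are recovered", {
  skip_if_not_installed("mclust")
  set.seed(65)
  mk <- function(mu, n) {
    t(replicate(n, pmax(rnorm(4, mu, c(25, 25, 25, 25)), 0)))
  }
  m <- rbind(mk(c(800, 600, 500, 700), 10),   # inflamed: high everything
             mk(c(800, 60, 40, 80), 10),      # T-cell rich only
             mk(c(40, 300, 30, 60), 10))      # uninflamed, moderate CD68
  colnames(m) <- c("CD8", "CD68", "CD20", "OTHER_CD45")
  rownames(m) <- paste0("p", 1:30)
  truth <- rep(1:3, each = 10)
  fit <- inflammatory_subtypes(m, k = 3)
  ari <- mclust::adjustedRandIndex(fit$labels, truth)
  expect_gte(ari, 0.9)
  # duplicated rows always co-cluster
  m2 <- rbind(m, m[1, , drop = FALSE])
  rownames(m2)[31] <- "dup"
  fit2 <- inflammatory_subtypes(m2, k = 3)
  expect_identical(fit2$labels[["dup"]], fit2$labels[["p1"]])
})

test_that("subtype labels are ordered by CD8 and k is validated", {
  set.seed(66)
  m <- matrix(rnorm(20, 100, 10), 5, 4,
              dimnames = list(paste0("s", 1:5),
                              c("CD8", "CD68", "CD20", "OTHER_CD45")))
  expect_error(inflammatory_subtypes(m, k = 9), "exceeds")
  one <- inflammatory_subtypes(m, k = 1)
  expect_true(all(one$labels == 1L))
  td <- generics::tidy(one)
  expect_identical(nrow(td), 5L)
  gl <- generics::glance(one)
  expect_identical(gl$k, 1)
})

test_that("cohort accounting conserves sample counts", {
  out <- cohort_accounting(c(neg = 20, pos = 10), excluded = 5)
  expect_identical(out$n_passed, 30L)
  expect_identical(out$n_analyzed, 25L)
  expect_identical(out$passed_neg, 20L)
  expect_error(cohort_accounting(c(a = 2), excluded = 5), "exclude")
})
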