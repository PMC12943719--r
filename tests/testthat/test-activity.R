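act <- load_activity_table()

test_that("the packaged table loads with printed values and missing cells", {
  expect_equal(act$pde4b1_nM[act$compound_id == "2a"], 29.01)
  expect_equal(act$pde4a4_nM[act$compound_id == "2f"], 40.01)
  expect_true(is.na(act$pde4b1_nM[act$compound_id == "2b"]))
  expect_false(anyDuplicated(act$compound_id) > 0)
  expect_true(all(act$pde4b1_nM > 0, na.rm = TRUE))
})

test_that("loader rejects bad cells and accepts empty tables", {
  tmp <- tempfile(fileext = ".tsv")
  hdr <- paste(c("compound_id", "series", "pde4b1_nM", "pde4a4_nM",
                 "pde4d3_nM", "harbs_nM", "tnfa_hwb_nM", "tnfa_hpbmc_nM",
                 "caco2_nM", "mned_mgkg"), collapse = "\t")
  writeLines(c(hdr, paste(c("x1", "2", "-5", rep("nd", 7)),
                          collapse = "\t")), tmp)
  expect_error(load_activity_table(tmp), "non-positive")
  writeLines(hdr, tmp)
  expect_equal(nrow(load_activity_table(tmp)), 0L)
})

test_that("pic50 transforms and scales as a logarithm", {
  expect_equal(pic50(1), 9.0)
  expect_equal(pic50(1000), 6.0)
  expect_equal(pic50(0.73), 9.136677, tolerance = 1e-6)
  expect_error(pic50(0), "positive")
  set.seed(8)
  x <- 10^runif(50, -1, 4)
  expect_true(all(diff(pic50(sort(x))) <= 0))
  expect_equal(pic50(10 * x), pic50(x) - 1, tolerance = 1e-12)
})

test_that("series extremes reproduce the printed best-in-series values", {
  s3 <- series_extreme(act, "3", "pde4b1_nM", "min")
  expect_equal(s3$compound_id, "3f")
  expect_equal(s3$value, 0.36)
  s5 <- series_extreme(act, "5", "pde4b1_nM", "min")
  expect_equal(s5$compound_id, "5i")
  expect_equal(s5$value, 82.51)
  expect_error(series_extreme(act, "4", "pde4b1_nM"), "no record")
})

test_that("the 100 nM potency screen is inclusive and monotone", {
  keep <- filter_potent(act)$compound_id
  expect_true("2a" %in% keep)      # 29.01 nM
  expect_false("2g" %in% keep)     # 229.21 nM
  edge <- data.frame(compound_id = "x", series = "2", pde4b1_nM = 100)
  expect_equal(nrow(filter_potent(edge)), 1L)  # boundary included
  for (thr in c(1, 10, 100, 1000)) {
    expect_true(all(filter_potent(act, threshold_nM = thr)$compound_id
                    %in% filter_potent(act, threshold_nM = 10 * thr)$compound_id))
  }
  expect_equal(nrow(filter_potent(act, threshold_nM = Inf)),
               sum(!is.na(act$pde4b1_nM)))
})

test_that("selectivity ratios match the printed IC50 quotients", {
  r2f <- act[act$compound_id == "2f", ]
  expect_equal(selectivity_ratio(r2f, "pde4d3_nM", "pde4b1_nM"),
               17.0 / 0.73, tolerance = 1e-9)
  expect_equal(selectivity_ratio(r2f, "pde4a4_nM", "pde4b1_nM"),
               40.01 / 0.73, tolerance = 1e-9)
  expect_equal(selectivity_ratio(r2f, "pde4b1_nM", "pde4b1_nM"), 1.0)
  expect_error(selectivity_ratio(act[act$compound_id == "2b", ],
                                 "pde4d3_nM", "pde4b1_nM"), "missing")
})

test_that("MNED folds versus the reference land in the printed 3-10x band", {
  rof <- act[act$compound_id == "Roflumilast", ]
  f3a <- mned_fold(act[act$compound_id == "3a", ], rof)
  f3k <- mned_fold(act[act$compound_id == "3k", ], rof)
  expect_equal(f3a, 9.0, tolerance = 1e-9)
  expect_equal(f3k, 1.1 / 0.3, tolerance = 1e-9)
  expect_true(all(c(f3a, f3k) >= 3 & c(f3a, f3k) <= 10))
  expect_equal(mned_fold(rof, rof), 1.0)
  expect_error(mned_fold(act[act$compound_id == "2a", ], rof), "missing")
})

test_that("modeling classes: membership lists first, ranges as fallback", {
  cls <- assign_modeling_class(act)
  expect_equal(cls[act$compound_id == "Roflumilast"], "A")
  expect_equal(cls[act$compound_id == "10a"], "I")
  expect_equal(sum(cls == "A"), 8L)
  expect_equal(sum(cls == "I"), 8L)
  hypo <- data.frame(compound_id = "zz", series = "2", pde4b1_nM = 50)
  expect_equal(assign_modeling_class(hypo), "unassigned")
  ranged <- data.frame(compound_id = c("in_a", "in_i"), series = "2",
                       pde4b1_nM = c(5, 1000))
  expect_equal(assign_modeling_class(ranged, use_ranges = TRUE),
               c("A", "I"))
  expect_equal(assign_modeling_class(ranged), rep("unassigned", 2))
  expect_error(class_definition(active_members = "x",
                                inactive_members = "x"),
               "both classes")
})

test_that("compare_classes: identical samples, symmetry, affine invariance", {
  same <- compare_classes(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  set.seed(13)
  a <- rnorm(30, 2.6, 0.2); b <- rnorm(40, 2.2, 0.25)
  r1 <- compare_classes(a, b)
  r2 <- compare_classes(b, a)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  r3 <- compare_classes(a + 5, b + 5)
  expect_equal(r1$statistic, r3$statistic, tolerance = 1e-9)
  expect_error(compare_classes(1, c(1, 2)), "at least 2")
  # rank-sum alternative is available
  expect_s3_class(compare_classes(a, b, method = "wilcoxon"),
                  "dockhb_comparison")
})

test_that("compare_classes detects the planted shift and holds its size", {
  # power at the class-default effect (2.64 vs 2.18, sd 0.2, n = 50)
  rej <- 0L
  for (s in 1:200) {
    set.seed(s)
    p <- compare_classes(rnorm(50, 2.64, 0.2), rnorm(50, 2.18, 0.2))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 200, 0.95)
  # type-I error under the null
  rej0 <- 0L
  for (s in 1:1000) {
    set.seed(10000 + s)
    p <- compare_classes(rnorm(50, 2.4, 0.2), rnorm(50, 2.4, 0.2))$p_value
    rej0 <- rej0 + (p < 0.05)
  }
  expect_gte(rej0 / 1000, 0.03)
  expect_lte(rej0 / 1000, 0.07)
})
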