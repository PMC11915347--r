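test_that("global covariate is the OLS residual of the global median", {
  co <- small_cohort()
  tb <- co$metrics[["FT"]]
  gcv <- compute_global_covariate(tb, "FA")
  expect_lt(abs(mean(gcv)), 1e-10)
  expect_lt(abs(cor(gcv, tb$subjects$pma_scan_weeks)), 1e-8)
  expect_lt(abs(cor(gcv, tb$subjects$ga_birth_weeks)), 1e-8)
  # global medians exactly linear in PMA -> zero residuals
  tb2 <- tb
  tb2$values[] <- 0.1 + 0.01 * tb$subjects$pma_scan_weeks  # same for all rois
  gcv2 <- compute_global_covariate(tb2, "FA")
  expect_lt(max(abs(gcv2)), 1e-10)
})

test_that("rank-deficient confound designs are rejected by name", {
  co <- small_cohort()
  tb <- co$metrics[["FT"]]
  tb$subjects$pma_scan_weeks <- 40
  tb$subjects$ga_birth_weeks <- 39
  expect_error(compute_global_covariate(tb, "FA"), "collinear")
})

test_that("residualization orthogonalizes every (roi, metric) column", {
  co <- small_cohort()
  tb <- residualize_metrics(co$metrics[["PT:ses1"]])
  pma <- tb$subjects$pma_scan_weeks
  ga <- tb$subjects$ga_birth_weeks
  for (m in c("FA", "MD", "ODI")) {
    cors_p <- apply(tb$values[, , m], 2L, cor, y = pma)
    cors_g <- apply(tb$values[, , m], 2L, cor, y = ga)
    expect_lt(max(abs(cors_p)), 1e-8)
    expect_lt(max(abs(cors_g)), 1e-8)
    expect_lt(max(abs(colMeans(tb$values[, , m]))), 1e-10)
  }
  # precondition: needs at least 5 subjects
  few <- co$metrics[["FT"]]
  few$subjects <- few$subjects[1:4, ]
  few$values <- few$values[1:4, , , drop = FALSE]
  expect_error(residualize_metrics(few), ">= 5 subjects")
})

test_that("min-max scaling maps pooled range onto [0,1] and is idempotent", {
  co <- small_cohort()
  tb <- minmax_scale(residualize_metrics(co$metrics[["FT"]]))
  for (m in tb$metrics) {
    v <- tb$values[, , m]
    expect_equal(range(v), c(0, 1))
  }
  again <- minmax_scale(tb)
  expect_equal(again$values, tb$values)
  cst <- co$metrics[["FT"]]
  cst$values[, , "FA"] <- 0.5
  expect_error(minmax_scale(cst), "constant")
})

test_that("MC fingerprint correlation behaves like Pearson", {
  co <- small_cohort()
  tb <- minmax_scale(residualize_metrics(co$metrics[["FT"]]))
  # duplicate ROI 2 into ROI 1 -> r = 1; negate -> r close to -1 after rescale
  tb$values[, 1, ] <- tb$values[, 2, ]
  mc <- build_mc(tb, atlas = atlas75)
  expect_equal(unclass(mc)[1, 2], 1)
  expect_true(isSymmetric(unclass(mc)))
  expect_true(all(abs(upper_triangle(unclass(mc))) <= 1 + 1e-12))
  # zero-variance fingerprint errors with the ROI name
  tb$values[, 3, ] <- 0.5
  expect_error(build_mc(tb, atlas = atlas75), atlas75$name[3])
})

test_that("MC is invariant to a common subject permutation and affine maps", {
  co <- small_cohort()
  res <- residualize_metrics(co$metrics[["PT:ses2"]])
  tb <- minmax_scale(res)
  mc1 <- unclass(build_mc(tb))
  set.seed(31)
  perm <- sample(nrow(tb$subjects))
  tb2 <- tb
  tb2$subjects <- tb$subjects[perm, ]
  tb2$values <- tb$values[perm, , , drop = FALSE]
  mc2 <- unclass(build_mc(tb2))
  expect_equal(mc1, mc2, tolerance = 1e-12)
  # an affine map applied to one metric before the per-group pooling is
  # undone by min-max scaling, so MC cannot change
  res3 <- res
  res3$values[, , "AD"] <- 3 * res3$values[, , "AD"] + 2
  mc3 <- unclass(build_mc(minmax_scale(res3)))
  expect_equal(mc3, mc1, tolerance = 1e-12)
})

test_that("absolute MC takes elementwise magnitude only", {
  m <- edges_to_matrix(c(-0.6, 0.2, 0.5), diag_value = 1)
  cm <- conn_matrix(m, modality = "MC")
  am <- absolute_mc(cm)
  expect_equal(upper_triangle(unclass(am)), c(0.6, 0.2, 0.5))
  expect_equal(diag(unclass(am)), rep(1, 3))
  expect_false(attr(am, "signed"))
})

test_that("planted blocks produce a strong within-minus-between contrast", {
  cfg <- synthetic_config(n_subjects = 45L, mc_loading = 0.8,
                          noise_sd = 0.1, ts_length = 120L)
  co <- generate_cohort(cfg, seed = 33)
  mc <- mc_from(co$metrics[["FT"]])
  expect_gt(block_contrast(mc, co$truth$mc_blocks), 0.3)
})

test_that("metric tables round-trip through long CSV", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_tables(co$metrics["FT"], path, atlas = atlas75)
  back <- read_metric_tables(path, atlas = atlas75)
  expect_equal(back[["FT"]]$values, co$metrics[["FT"]]$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back[["FT"]]$subjects$pma_scan_weeks,
               co$metrics[["FT"]]$subjects$pma_scan_weeks)
})
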