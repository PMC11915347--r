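# independent oracles ---------------------------------------------------------

# exhaustive signed-rank distribution for small n (no ties assumed)
enumerate_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- expand.grid(rep(list(c(0, 1)), n))
  tpos <- as.matrix(signs) %*% r
  total <- n * (n + 1) / 2
  w_all <- pmin(tpos, total - tpos)
  p <- mean(w_all <= w_obs)
  list(W = w_obs, p = p)
}

# hand-coded Benjamini-Hochberg step-up rule
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

test_that("Shapiro wrapper matches calibration expectations", {
  set.seed(1)
  normal_p <- replicate(100, shapiro_normality(rnorm(300))$p_value)
  expect_gte(mean(normal_p > 0.05), 0.9)
  skewed <- exp(rnorm(500))
  expect_lt(shapiro_normality(skewed)$p_value, 0.01)
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
})

test_that("paired Wilcoxon uses the smaller-rank-sum convention", {
  # all-positive differences -> W = 0
  res <- paired_wilcoxon(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$direction, 1)
  # swapping the vectors flips direction, keeps W and p
  swp <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(swp$statistic, res$statistic)
  expect_equal(swp$p_value, res$p_value)
  expect_equal(swp$direction, -1)
  expect_error(paired_wilcoxon(1:5, 1:5), "zero")
  expect_error(paired_wilcoxon(1:4, 2:5), "5 pairs")
})

test_that("paired Wilcoxon agrees with exhaustive enumeration for n <= 10", {
  set.seed(7)
  for (n in c(6, 8, 10)) {
    for (rep in 1:20) {
      a <- rnorm(n)
      b <- rnorm(n)
      res <- paired_wilcoxon(a, b)
      oracle <- enumerate_wilcoxon(a - b)
      expect_equal(res$statistic, oracle$W)
      expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("Huber fit recovers exact lines and resists gross outliers", {
  set.seed(10)
  x <- rnorm(200)
  fit <- huber_fit(x, 3 * x + 1)
  expect_equal(fit$slope, 3, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  # contaminated data: Huber beats OLS in slope error
  y <- 3 * x + 1 + rnorm(200, sd = 0.5)
  y[1:20] <- y[1:20] + 50
  hub <- huber_fit(x, y)
  ols <- coef(lm(y ~ x))[2]
  expect_lt(abs(hub$slope - 3), abs(ols - 3))
  expect_error(huber_fit(rep(1, 50), rnorm(50)), "constant")
  expect_error(huber_fit(1:5, 1:5), ">= 10")
})

test_that("Huber fit tracks the independent MASS::rlm implementation", {
  skip_if_not_installed("MASS")
  set.seed(11)
  x <- rnorm(500)
  y <- 0.5 * x + rt(500, df = 3) * 0.3
  y[1:25] <- y[1:25] + 10
  hub <- huber_fit(x, y)
  rl <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  expect_equal(hub$slope, unname(coef(rl)[2]), tolerance = 0.02)
  expect_equal(hub$intercept, unname(coef(rl)[1]), tolerance = 0.02)
  se_rlm <- sqrt(diag(vcov(rl)))[2]
  expect_equal(hub$slope_se, unname(se_rlm), tolerance = 0.25)
})

test_that("permutation slope p is reproducible and detects exact coupling", {
  set.seed(12)
  x <- rnorm(100)
  y <- 2 * x
  fit1 <- permute_slope_p(x, y, n_perm = 1000, seed = 5)
  expect_equal(fit1$permutation_p, 1 / 1001)
  fit2 <- permute_slope_p(x, y, n_perm = 1000, seed = 5)
  expect_identical(fit1$permutation_p, fit2$permutation_p)
  # independent data: p comfortably above the add-one floor
  yy <- rnorm(100)
  fit3 <- permute_slope_p(x, yy, n_perm = 200, seed = 6)
  expect_gt(fit3$permutation_p, 0.005)
})

test_that("slope Z comparison follows the pooled-SE formula", {
  f1 <- structure(list(slope = 1, slope_se = 0.1), class = "huber_fit")
  f2 <- structure(list(slope = 0, slope_se = 0.1), class = "huber_fit")
  z <- compare_slopes_z(f1, f2)
  expect_equal(z$z, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(z$p_value, 2 * pnorm(-abs(z$z)))
  rev <- compare_slopes_z(f2, f1)
  expect_equal(rev$z, -z$z)
  expect_equal(rev$p_value, z$p_value)
  expect_equal(compare_slopes_z(f1, f1)$z, 0)
  f3 <- structure(list(slope = 1, slope_se = 0), class = "huber_fit")
  expect_error(compare_slopes_z(f3, f3), "zero")
})

test_that("BH adjustment equals the hand-coded step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("top-fraction thresholding keeps the strongest quarter", {
  m <- edges_to_matrix(c(0.1, 0.2, 0.3, 0.4, 0.15, 0.25), diag_value = 1)
  thr <- threshold_top_fraction(m, fraction = 0.25)
  kept <- upper_triangle(m)[thr$masks[[1]]]
  expect_true(all(kept >= thr$thresholds[[1]]))
  expect_equal(sort(kept), c(0.3, 0.4))  # ceil(0.25*6) with >= convention
  # 75-ROI matrix with distinct values keeps 694 edges
  set.seed(14)
  big <- edges_to_matrix(sample(seq(0, 1, length.out = 2775)), diag_value = 1)
  thr2 <- threshold_top_fraction(big, fraction = 0.25)
  expect_equal(sum(thr2$masks[[1]]), 694)
  # common mode on identical matrices = adapted thresholds
  thr3 <- threshold_top_fraction(list(a = big, b = big), mode = "common")
  thr4 <- threshold_top_fraction(list(a = big, b = big), mode = "adapted")
  expect_equal(unname(thr3$thresholds), unname(thr4$thresholds))
  expect_error(threshold_top_fraction(list()), "no matrices")
  expect_error(threshold_top_fraction(big, fraction = 1.5), "\\(0, 1\\)")
})

test_that("subset regressions report the whole family with BH correction", {
  cfg <- synthetic_config(n_subjects = 20L, ts_length = 150L)
  co <- generate_cohort(cfg, seed = 55)
  mc <- absolute_mc(mc_from(co$metrics[["FT"]]))
  pre <- preprocess_timeseries(co$timeseries[["FT"]], trim = 30L)
  fc <- group_fc(subject_fc_stack(pre), group = "FT")
  lab <- label_edges(atlas75)
  rep_df <- subset_regression_report(mc, fc, lab, n_perm = 50L, seed = 77)
  expect_setequal(rep_df$subset,
                  c("whole_brain", "cortico_subcortical", "thalamo_cortical",
                    "cc_intraH", "cc_interH_homo", "cc_interH_non_homo",
                    "SM", "VIS"))
  done <- rep_df[!rep_df$skipped, ]
  expect_true(all(done$perm_p > 0 & done$perm_p <= 1))
  expect_equal(done$perm_p_bh, bh_oracle(done$perm_p), tolerance = 1e-14)
  expect_equal(rep_df$n_edges[rep_df$subset == "whole_brain"], 2775)
  # shared planted blocks across modalities couple MC and FC
  expect_lte(done$perm_p_bh[done$subset == "whole_brain"], 0.05)
  expect_error(subset_regression_report(mc, fc, lab[1:10, ]), "labeling")
  expect_error(subset_regression_report(mc, fc, lab, subsets = "nope"),
               "unknown subset")
})
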