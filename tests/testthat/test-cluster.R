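# brute-force MI oracle over the explicit contingency table
mi_oracle <- function(a, b) {
  ta <- unique(a); tb <- unique(b)
  n <- length(a)
  mi <- 0
  for (u in ta) {
    for (v in tb) {
      pij <- sum(a == u & b == v) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / ((sum(a == u) / n) * (sum(b == v) / n)))
      }
    }
  }
  mi
}

test_that("cosine-theorem distance maps correlations onto [0, 2]", {
  r <- edges_to_matrix(c(1, 0, -1), diag_value = 1)
  d <- corr_to_distance(r)
  expect_equal(upper_triangle(d), c(0, sqrt(2), 2))
  d_abs <- corr_to_distance(r, use_abs = TRUE)
  expect_equal(upper_triangle(d_abs), c(0, sqrt(2), 0))
  expect_equal(diag(d), rep(0, 3))
  bad <- r; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(corr_to_distance(bad), "outside")
})

test_that("Ward recovers planted blocks and is permutation-equivariant", {
  set.seed(20)
  blocks <- rep(1:2, each = 6)
  d <- matrix(1.4, 12, 12)
  d[outer(blocks, blocks, `==`)] <- 0.2
  diag(d) <- 0
  h <- ward_dendrogram(d)
  expect_equal(length(h$height), 11)
  expect_true(all(diff(h$height) >= -1e-12))  # monotone merge heights
  k2 <- cut_dendrogram(h, 2)
  expect_equal(mutual_information(k2, blocks), cluster_entropy(blocks))
  # permuting leaves permutes labels consistently
  perm <- sample(12)
  h2 <- ward_dendrogram(d[perm, perm])
  k2p <- cut_dendrogram(h2, 2)
  expect_equal(mutual_information(k2p, blocks[perm]), cluster_entropy(blocks))
  expect_error(ward_dendrogram(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("dendrogram cuts are nested and span singletons to one cluster", {
  co <- small_cohort()
  mc <- mc_from(co$metrics[["FT"]])
  h <- ward_dendrogram(corr_to_distance(mc, use_abs = TRUE))
  expect_equal(length(unique(cut_dendrogram(h, 1))), 1)
  expect_equal(length(unique(cut_dendrogram(h, 75))), 75)
  for (k in c(2, 10, 40)) {
    expect_equal(length(unique(cut_dendrogram(h, k))), k)
  }
  # successive cuts differ by exactly one split
  for (k in c(3, 20, 60)) {
    a <- cut_dendrogram(h, k)
    b <- cut_dendrogram(h, k + 1)
    tab <- table(a, b)
    expect_equal(sum(rowSums(tab > 0) == 2), 1)
    expect_equal(sum(rowSums(tab > 0) == 1), k - 1)
  }
  expect_error(cut_dendrogram(h, 76), "1..75")
  # all-equal distances still produce a valid dendrogram
  deq <- matrix(1, 10, 10); diag(deq) <- 0
  heq <- ward_dendrogram(deq)
  expect_equal(length(unique(cut_dendrogram(heq, 10))), 10)
})

test_that("mutual information matches the brute-force oracle", {
  expect_equal(mutual_information(rep(1:2, each = 4), rep(1:2, each = 4)),
               log(2))
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutual_information(1:8, rep(1, 8)), 0)
  expect_error(mutual_information(integer(0), integer(0)), "empty")
  expect_error(mutual_information(1:4, 1:5), "equal length")
  set.seed(21)
  max_dev <- 0
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    a <- sample(sample(2:6, 1), n, replace = TRUE)
    b <- sample(sample(2:6, 1), n, replace = TRUE)
    max_dev <- max(max_dev, abs(mutual_information(a, b) - mi_oracle(a, b)))
  }
  expect_lt(max_dev, 1e-12)
})

test_that("MI across scales has the expected shape and symmetries", {
  co <- small_cohort()
  mc <- mc_from(co$metrics[["PT:ses1"]])
  h1 <- ward_dendrogram(corr_to_distance(mc, use_abs = TRUE))
  pre <- preprocess_timeseries(co$timeseries[["PT:ses1"]], trim = 30L)
  fc <- group_fc(subject_fc_stack(pre), group = "PT:ses1")
  h2 <- ward_dendrogram(corr_to_distance(fc))
  kr <- 2:20
  mi <- mi_across_scales(h1, h2, k_range = kr)
  expect_equal(dim(mi), c(19, 19))
  expect_true(all(mi >= -1e-12))
  # swapping the dendrograms transposes the matrix
  expect_equal(mi_across_scales(h2, h1, k_range = kr), t(mi),
               tolerance = 1e-12)
  # self-comparison diagonal equals the cut entropy
  mi_self <- mi_across_scales(h1, h1, k_range = 2:10)
  ent <- sapply(2:10, function(k) cluster_entropy(cut_dendrogram(h1, k)))
  expect_equal(diag(mi_self), ent, tolerance = 1e-12, ignore_attr = TRUE)
  # default range covers 74 x 74 cluster-size pairs
  expect_equal(dim(mi_across_scales(h1, h2)), c(74, 74))
})

test_that("MI permutation null flags aligned clusterings, not degenerate ones", {
  set.seed(22)
  lab <- sample(rep(1:5, 15))
  res <- mi_permutation_null(lab, lab, n_perm = 100, seed = 30)
  expect_gt(res$observed, res$p95)
  expect_equal(res$observed, cluster_entropy(lab))
  # all-one-cluster labeling can never be significant
  res2 <- mi_permutation_null(lab, rep(1, 75), n_perm = 100, seed = 30)
  expect_equal(res2$observed, 0)
  expect_false(res2$observed > res2$p95)
  # determinism
  res3 <- mi_permutation_null(lab, lab, n_perm = 100, seed = 30)
  expect_identical(res$null, res3$null)
})

test_that("mi_comparison summarizes significant cells; empty mask is defined", {
  co <- small_cohort()
  mc <- mc_from(co$metrics[["FT"]])
  h <- ward_dendrogram(corr_to_distance(mc, use_abs = TRUE))
  cmp <- mi_comparison(h, h, k_range = 2:15, n_perm = 50, seed = 40)
  # identical dendrograms: at least the diagonal cells are significant
  expect_gte(cmp$n_significant, length(2:15))
  expect_true(all(diag(cmp$significant)))
  expect_equal(cmp$mean_significant, mean(cmp$mi[cmp$significant]))
  # empty significance mask reports NA mean, not an error
  fake <- cmp
  fake$significant[] <- FALSE
  s <- summarize_mi(fake)
  expect_true(is.na(s$mean_significant))
  expect_equal(s$n_significant, 0)
})

test_that("dendrograms round-trip through the merge-table CSV", {
  co <- small_cohort()
  mc <- mc_from(co$metrics[["FT"]])
  h <- ward_dendrogram(corr_to_distance(mc, use_abs = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dendrogram_csv(h, path)
  back <- read_dendrogram_csv(path)
  expect_equal(back$merge, h$merge, ignore_attr = TRUE)
  expect_equal(back$height, h$height, tolerance = 1e-15)
  for (k in c(2, 5, 30)) {
    expect_equal(cut_dendrogram(back, k), cut_dendrogram(h, k))
  }
})
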