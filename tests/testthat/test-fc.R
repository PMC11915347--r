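make_ts <- function(series, tr = 0.392, group = "FT") {
  timeseries_set(series, sprintf("S%02d", seq_along(series)), group, tr)
}

test_that("preprocessing filters, standardizes and trims in order", {
  co <- small_cohort()
  pre <- preprocess_timeseries(co$timeseries[["FT"]], trim = 30L)
  y <- pre$series[[1]]
  expect_equal(ncol(y), 150 - 60)
  expect_lt(max(abs(rowMeans(y))), 1e-8)
  sds <- apply(y, 1, sd)
  expect_true(all(abs(sds - 1) < 0.05))
})

test_that("a 0.2 Hz sinusoid is attenuated >= 90% by the 0.1 Hz filter", {
  tr <- 0.392
  t <- seq(0, by = tr, length.out = 400)
  sine <- sin(2 * pi * 0.2 * t)
  slow <- sin(2 * pi * 0.02 * t)
  ts <- make_ts(list(rbind(sine, slow, rnorm(400))), tr = tr)
  fs <- 1 / tr
  bf <- signal::butter(4, 0.1 / (fs / 2), type = "low")
  filt <- signal::filtfilt(bf, sine)
  keep <- 51:350
  # amplitude ratio on the retained support
  expect_lt(sd(filt[keep]) / sd(sine[keep]), 0.1)
  # and the preprocessing pipeline keeps slow signals nearly intact
  pre <- preprocess_timeseries(ts, trim = 50L)
  expect_gt(cor(pre$series[[1]][2, ], slow[51:350]), 0.99)
})

test_that("preprocessing rejects invalid inputs", {
  flat <- make_ts(list(rbind(rep(1, 200), rnorm(200))))
  expect_error(preprocess_timeseries(flat, trim = 20L), "zero-variance")
  short <- make_ts(list(matrix(rnorm(2 * 150), 2)))
  expect_error(preprocess_timeseries(short, trim = 60L), "too short")
  ok <- make_ts(list(matrix(rnorm(2 * 300), 2)))
  expect_error(preprocess_timeseries(ok, cutoff_hz = 2), "Nyquist")
})

test_that("subject FC is a Pearson matrix with the expected extremes", {
  base <- rnorm(200)
  m <- rbind(base, base, -base + 3, rnorm(200))
  fc <- unclass(subject_fc(m))
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_true(all(abs(upper_triangle(fc)) <= 1 + 1e-12))
  m[4, ] <- 2
  expect_error(subject_fc(m), "zero-variance")
})

test_that("zero-phase filtering keeps correlations stable under small delays", {
  tr <- 0.392
  set.seed(8)
  n <- 600
  x <- as.numeric(stats::filter(rnorm(n + 2), rep(1 / 3, 3), sides = 1))[-(1:2)]
  lagged <- c(x[3:n], rnorm(2))  # common 2-sample delay
  ts <- make_ts(list(rbind(x, x, lagged)), tr = tr)
  pre <- preprocess_timeseries(ts, trim = 50L)
  y <- pre$series[[1]]
  expect_gt(cor(y[1, ], y[3, ]), cor(x, lagged))  # filtering smooths the lag
  expect_lt(abs(cor(y[1, ], y[2, ]) - 1), 1e-12)
})

test_that("group FC is the elementwise mean of subject matrices", {
  r1 <- edges_to_matrix(c(0.2, 0, 0), diag_value = 1)
  r2 <- edges_to_matrix(c(0.6, 0, 0), diag_value = 1)
  arr <- array(NA_real_, c(2, 3, 3))
  arr[1, , ] <- r1; arr[2, , ] <- r2
  g <- unclass(group_fc(arr))
  expect_equal(g[1, 2], 0.4)
  expect_true(isSymmetric(g))
  expect_equal(diag(g), rep(1, 3))
  # single subject is the identity operation
  one <- array(r1, c(1, 3, 3))
  expect_equal(unclass(group_fc(one)), r1, ignore_attr = TRUE)
  # mismatched ROI order across subjects errors
  m1 <- conn_matrix(r1, "FC", roi_names = c("a", "b", "c"))
  m2 <- conn_matrix(r2, "FC", roi_names = c("b", "a", "c"))
  expect_error(group_fc(list(m1, m2)), "mismatched")
})

test_that("planted fc_rho is recovered by subject FC at long T", {
  cfg <- synthetic_config(n_subjects = 3L, fc_rho = 0.6, ts_length = 5000L)
  co <- generate_cohort(cfg, seed = 12)
  pre <- preprocess_timeseries(co$timeseries[["FT"]])
  fc <- unclass(subject_fc(pre$series[[1]]))
  blocks <- co$truth$fc_blocks
  same <- outer(blocks, blocks, `==`) & upper.tri(fc)
  expect_lt(abs(mean(fc[same]) - 0.6), 0.05)
})

test_that("time series round-trip through TSV + sidecar", {
  co <- small_cohort()
  ts <- co$timeseries[["FT"]]
  ts$series <- ts$series[1:2]
  ts$subject_ids <- ts$subject_ids[1:2]
  dir <- withr::local_tempdir()
  write_timeseries_set(ts, dir, atlas = atlas75)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  back <- read_timeseries_set(files)
  expect_equal(back$sampling_interval, ts$sampling_interval)
  expect_equal(back$group, ts$group)
  expect_equal(unname(back$series[[1]]), unname(ts$series[[1]]),
               tolerance = 1e-10, ignore_attr = TRUE)
})
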