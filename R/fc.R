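# Functional connectivity (FC) builder: ROI BOLD series -> low-pass filter
# (0.1 Hz, 4th-order Butterworth, zero-phase) -> per-ROI z-score -> trim the
# first/last 50 samples -> subject Pearson matrix -> group average.

#' Container for one group's ROI time series
#'
#' @param series List of numeric matrices, one per subject, `ROIs x T`,
#'   rows in atlas order.
#' @param subject_ids Character vector, one id per subject.
#' @param group Group label.
#' @param sampling_interval Sampling interval in seconds (e.g. 0.392).
#' @return A list of class `timeseries_set`.
#' @export
timeseries_set <- function(series, subject_ids, group,
                           sampling_interval) {
  stopifnot(is.list(series), length(series) == length(subject_ids),
            sampling_interval > 0)
  nr <- unique(vapply(series, nrow, integer(1)))
  if (length(nr) != 1L) {
    stop("all subjects must have the same number of ROI rows", call. = FALSE)
  }
  if (any(!vapply(series, function(m) all(is.finite(m)), logical(1)))) {
    stop("time series contain non-finite values", call. = FALSE)
  }
  structure(list(series = series, subject_ids = subject_ids, group = group,
                 sampling_interval = sampling_interval),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("ROI time-series set [%s]: %d subjects, %d ROIs x %d samples, TR %.3f s\n",
              x$group, length(x$series), nrow(x$series[[1]]),
              ncol(x$series[[1]]), x$sampling_interval))
  invisible(x)
}

#' Preprocess ROI BOLD time series
#'
#' Applies, in order: a zero-phase (forward-backward) 4th-order Butterworth
#' low-pass filter with the given cutoff; per-ROI standardization to z-scores
#' using the mean and SD over the retained support; and trimming of the first
#' and last `trim` samples. Retained series therefore have mean 0 and SD 1
#' over their full (post-trim) extent. Zero-phase filtering is used so that
#' no lag-driven decorrelation is introduced between regions.
#'
#' @param ts A [timeseries_set()].
#' @param cutoff_hz Low-pass cutoff (default 0.1 Hz); must be below Nyquist.
#' @param trim Samples dropped at each end (default 50).
#' @param min_length Minimum retained length (default 50); shorter series are
#'   an error because Pearson correlations become unstable.
#' @return A `timeseries_set` of filtered, standardized, trimmed series.
#' @export
preprocess_timeseries <- function(ts, cutoff_hz = 0.1, trim = 50L,
                                  min_length = 50L) {
  stopifnot(inherits(ts, "timeseries_set"))
  fs <- 1 / ts$sampling_interval
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %.3f Hz is not below the Nyquist frequency %.3f Hz",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  len <- ncol(ts$series[[1]])
  keep <- (trim + 1L):(len - trim)
  if (len - 2L * trim < min_length) {
    stop(sprintf("series too short: %d samples leave %d after trimming %d from each end (need >= %d)",
                 len, len - 2L * trim, trim, min_length), call. = FALSE)
  }
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  out <- lapply(ts$series, function(m) {
    raw_sds <- apply(m, 1L, stats::sd)
    if (any(raw_sds == 0)) {
      stop("zero-variance ROI series (row ", which(raw_sds == 0)[1L],
           "); cannot z-score", call. = FALSE)
    }
    filt <- t(apply(m, 1L, function(row) {
      signal::filtfilt(bf, row)
    }))
    mu <- rowMeans(filt[, keep, drop = FALSE])
    sds <- apply(filt[, keep, drop = FALSE], 1L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance ROI series (row ", which(sds == 0)[1L],
           "); cannot z-score", call. = FALSE)
    }
    z <- (filt - mu) / sds
    z[, keep, drop = FALSE]
  })
  timeseries_set(out, ts$subject_ids, ts$group, ts$sampling_interval)
}

#' Subject-level functional connectivity matrix
#'
#' Pearson correlation between all ROI pairs of one subject's processed
#' series; diagonal set to 1.
#'
#' @param series One subject's `ROIs x T` matrix (already preprocessed).
#' @param group Group label recorded on the result.
#' @param roi_names Optional ROI names.
#' @return A [conn_matrix()] with modality `"FC"`.
#' @export
subject_fc <- function(series, group = NA_character_, roi_names = NULL) {
  stopifnot(is.matrix(series))
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI series (row ", which(sds == 0)[1L], ")",
         call. = FALSE)
  }
  fc <- stats::cor(t(series))
  diag(fc) <- 1
  conn_matrix(fc, modality = "FC", group = group, signed = TRUE,
              roi_names = roi_names)
}

#' Stack of subject FC matrices for a group
#'
#' @param ts A preprocessed [timeseries_set()].
#' @param roi_names Optional ROI names.
#' @return A 3-D array `subjects x R x R` of subject FC matrices.
#' @export
subject_fc_stack <- function(ts, roi_names = NULL) {
  stopifnot(inherits(ts, "timeseries_set"))
  mats <- lapply(ts$series, subject_fc, group = ts$group,
                 roi_names = roi_names)
  R <- nrow(mats[[1]])
  arr <- array(NA_real_, dim = c(length(mats), R, R),
               dimnames = list(ts$subject_ids, roi_names, roi_names))
  for (s in seq_along(mats)) arr[s, , ] <- as_plain_matrix(mats[[s]])
  arr
}

#' Group functional connectivity matrix
#'
#' Elementwise arithmetic mean of subject FC matrices. Optionally averages on
#' the Fisher-z scale (`fisher_z = TRUE`) and transforms back; the default is
#' a plain mean of correlation matrices.
#'
#' @param fc_stack A `subjects x R x R` array ([subject_fc_stack()]) or a
#'   list of subject `conn_matrix` objects with identical ROI order.
#' @param group Group label.
#' @param fisher_z Average on the arctanh scale (default `FALSE`).
#' @return A [conn_matrix()] with modality `"FC"`.
#' @export
group_fc <- function(fc_stack, group = NA_character_, fisher_z = FALSE) {
  if (is.list(fc_stack)) {
    if (!length(fc_stack)) stop("empty FC stack", call. = FALSE)
    nms <- lapply(fc_stack, rownames)
    if (length(unique(vapply(fc_stack, nrow, integer(1)))) != 1L ||
        (any(!vapply(nms, is.null, logical(1))) &&
         length(unique(nms)) != 1L)) {
      stop("subject FC matrices have mismatched ROI order", call. = FALSE)
    }
    R <- nrow(fc_stack[[1]])
    arr <- array(NA_real_, dim = c(length(fc_stack), R, R))
    for (s in seq_along(fc_stack)) arr[s, , ] <- as_plain_matrix(fc_stack[[s]])
    dimnames(arr) <- list(NULL, nms[[1]], nms[[1]])
    fc_stack <- arr
  }
  stopifnot(is.array(fc_stack), length(dim(fc_stack)) == 3L)
  if (fisher_z) {
    z <- atanh(pmin(pmax(fc_stack, -1 + 1e-15), 1 - 1e-15))
    m <- tanh(apply(z, c(2L, 3L), mean))
  } else {
    m <- apply(fc_stack, c(2L, 3L), mean)
  }
  diag(m) <- 1
  m <- (m + t(m)) / 2
  conn_matrix(m, modality = "FC", group = group, signed = TRUE,
              roi_names = dimnames(fc_stack)[[2]])
}
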