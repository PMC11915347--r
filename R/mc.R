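# Microstructural connectivity (MC) builder.
#
# Group-wise pipeline: (1) per metric, residualize each ROI's values on PMA at
# scan, GA at birth and the PMA/GA-corrected residual of the subject's global
# median metric; (2) min-max scale to [0,1] per metric, pooling values across
# all regions and subjects of the group; (3) concatenate each ROI's 6-metric
# fingerprint across subjects and correlate ROI pairs (Pearson).

# OLS residuals of y on a design X (with intercept added); errors on rank
# deficiency naming the offending columns.
.ols_residuals <- function(y, X, colnames_) {
  X <- cbind(`(Intercept)` = 1, X)
  colnames(X) <- c("(Intercept)", colnames_)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr.resid(qrX, y)
}

#' Global-median confound covariate
#'
#' For one metric, computes each subject's global median over all ROIs, then
#' residualizes that median on `[1, PMA, GA]` across subjects of the group by
#' ordinary least squares. The residual carries subject-level global variation
#' (e.g. acquisition scale) not explained by age, and enters the regional
#' residualization as a third confound regressor.
#'
#' @param table A [cohort_metrics()] table (one group).
#' @param metric Metric name, e.g. `"FA"`.
#' @return Numeric vector of per-subject residuals (mean zero).
#' @export
compute_global_covariate <- function(table, metric) {
  validate_cohort_metrics(table, check_ranges = FALSE)
  stopifnot(metric %in% table$metrics)
  gm <- apply(table$values[, , metric, drop = FALSE], 1L, stats::median)
  X <- cbind(table$subjects$pma_scan_weeks, table$subjects$ga_birth_weeks)
  as.vector(.ols_residuals(gm, X, c("pma_scan_weeks", "ga_birth_weeks")))
}

#' Residualize regional metrics for age and global confounds
#'
#' For each (ROI, metric) independently within the group, replaces the values
#' by the residuals of an OLS fit on `[1, PMA at scan, GA at birth,
#' global covariate(metric)]`, where the global covariate is
#' [compute_global_covariate()]. All regressors enter jointly in a single
#' projection, so the corrected values are exactly orthogonal to each of them.
#'
#' @param table A [cohort_metrics()] table with at least 5 subjects.
#' @return A `cohort_metrics` table of residuals (means ~ 0 per column).
#' @export
residualize_metrics <- function(table) {
  validate_cohort_metrics(table, check_ranges = FALSE)
  n <- nrow(table$subjects)
  if (n < 5L) {
    stop("residualization needs >= 5 subjects (4 regressors incl. intercept)",
         call. = FALSE)
  }
  vals <- table$values
  out <- vals
  for (m in table$metrics) {
    gcv <- compute_global_covariate(table, m)
    X <- cbind(table$subjects$pma_scan_weeks, table$subjects$ga_birth_weeks,
               gcv)
    out[, , m] <- .ols_residuals(
      vals[, , m], X,
      c("pma_scan_weeks", "ga_birth_weeks", "global_covariate"))
  }
  res <- table
  res$values <- out
  res
}

#' Min-max scale metric values to [0, 1]
#'
#' Per metric and per group, pools the values across all regions and subjects
#' and maps `[min, max]` linearly onto `[0, 1]`. Scaling is per metric because
#' the metrics carry incommensurable units (diffusivities in mm^2/s vs
#' unitless indices); pooling across metrics would let the larger-variance
#' metrics dominate the fingerprints.
#'
#' @param table A `cohort_metrics` table (typically residualized).
#' @return The scaled table.
#' @export
minmax_scale <- function(table) {
  validate_cohort_metrics(table, check_ranges = FALSE)
  out <- table$values
  for (m in table$metrics) {
    v <- out[, , m]
    rng <- range(v)
    if (rng[2] <= rng[1]) {
      stop("metric ", m, " is constant within the group; cannot scale",
           call. = FALSE)
    }
    out[, , m] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  res <- table
  res$values <- out
  res
}

#' Build the group microstructural connectivity matrix
#'
#' Each ROI's microstructural fingerprint is the concatenation, across all
#' subjects of the group (subject-major: subject 1's six metrics, then
#' subject 2's, ...), of its six scaled diffusion metrics; MC between two
#' ROIs is the Pearson correlation of their fingerprints. The diagonal is set
#' to exactly 1.
#'
#' @param table A scaled `cohort_metrics` table (see [minmax_scale()]).
#' @param atlas Optional `roi_atlas` supplying ROI names.
#' @return A signed [conn_matrix()] with modality `"MC"`.
#' @export
build_mc <- function(table, atlas = NULL) {
  validate_cohort_metrics(table, check_ranges = FALSE)
  v <- table$values
  d <- dim(v)                              # S x R x M
  # fingerprints: (M*S) x R with subject-major element order
  fp <- matrix(aperm(v, c(3L, 1L, 2L)), nrow = d[3] * d[1], ncol = d[2])
  sds <- apply(fp, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    nm <- if (!is.null(atlas)) atlas$name[bad] else as.character(bad)
    stop("zero-variance fingerprint for ROI ", nm, call. = FALSE)
  }
  mc <- stats::cor(fp)
  diag(mc) <- 1
  conn_matrix(mc, modality = "MC", group = table$group, signed = TRUE,
              roi_names = if (!is.null(atlas)) atlas$name else NULL)
}

#' Absolute microstructural connectivity
#'
#' Elementwise absolute value of a signed MC matrix (diagonal unchanged);
#' downstream group analyses work on `|MC|`.
#'
#' @param mc A signed MC [conn_matrix()].
#' @return An unsigned `conn_matrix`.
#' @export
absolute_mc <- function(mc) {
  stopifnot(inherits(mc, "conn_matrix"))
  out <- abs(as_plain_matrix(mc))
  conn_matrix(out, modality = attr(mc, "modality"), group = attr(mc, "group"),
              signed = FALSE, roi_names = rownames(mc))
}
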