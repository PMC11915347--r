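# Longitudinal change matrices between the two preterm sessions.
#
# dMC is a plain difference of absolute MC (the metrics feeding MC were
# already age-corrected within each group). dFC additionally shrinks each
# edge's session difference by the overlap of the two sessions'
# connection-wise confidence intervals, so that differences swamped by
# across-subject variability are attenuated.

#' Developmental change in microstructural connectivity
#'
#' `dMC[i,j] = |MC_ses2[i,j]| - |MC_ses1[i,j]|`; positive values mean
#' strengthening between sessions. Diagonal is 0.
#'
#' @param mc_ses1,mc_ses2 Signed group MC matrices on the same atlas.
#' @return A [conn_matrix()] with modality `"dMC"`.
#' @export
delta_mc <- function(mc_ses1, mc_ses2) {
  m1 <- as_plain_matrix(mc_ses1)
  m2 <- as_plain_matrix(mc_ses2)
  if (!identical(dim(m1), dim(m2))) {
    stop("MC matrices have mismatched dimensions", call. = FALSE)
  }
  d <- abs(m2) - abs(m1)
  diag(d) <- 0
  conn_matrix(d, modality = "dMC", group = "PT:ses2-ses1", signed = TRUE,
              roi_names = rownames(m1))
}

#' Connection-wise confidence intervals of group FC
#'
#' Per edge, the interval `center +/- half_width` with `center` the mean of
#' subject-level FC across the group and
#' `half_width = z_mult * SD / sqrt(n)` — by default the 95% confidence
#' interval of the group mean (`z_mult = 1.96`), built from the SD of the
#' connection's strength across subjects. Set `use_sem = FALSE` to use
#' `z_mult * SD` without the `sqrt(n)` shrinkage.
#'
#' @param fc_stack A `subjects x R x R` array of subject FC matrices.
#' @param z_mult Multiplier on the spread (default 1.96).
#' @param use_sem Divide the SD by `sqrt(n)` (default `TRUE`).
#' @return List with matrices `center` and `half_width` and the subject
#'   count `n`.
#' @export
edge_ci <- function(fc_stack, z_mult = 1.96, use_sem = TRUE) {
  stopifnot(is.array(fc_stack), length(dim(fc_stack)) == 3L)
  n <- dim(fc_stack)[1]
  if (n < 3L) stop("edge CIs need >= 3 subjects", call. = FALSE)
  center <- apply(fc_stack, c(2L, 3L), mean)
  sdm <- apply(fc_stack, c(2L, 3L), stats::sd)
  hw <- z_mult * sdm / if (use_sem) sqrt(n) else 1
  list(center = center, half_width = hw, n = n)
}

#' Confidence-interval overlap weight
#'
#' The overlap of two intervals is measured by Jaccard similarity
#' (intersection length / union length); the weight is `1 - overlap`, so
#' identical intervals give weight 0 and disjoint intervals weight 1. Two
#' degenerate equal intervals count as fully overlapping. The alternative
#' `"min"` measure divides the intersection by the shorter interval's length.
#'
#' @param center_a,half_a,center_b,half_b Interval centers and half-widths
#'   (numeric, vectorized).
#' @param method `"jaccard"` (default) or `"min"`.
#' @return Weights in `[0, 1]`, same shape as the inputs.
#' @export
ci_overlap_weight <- function(center_a, half_a, center_b, half_b,
                              method = c("jaccard", "min")) {
  method <- match.arg(method)
  lo_a <- center_a - half_a; hi_a <- center_a + half_a
  lo_b <- center_b - half_b; hi_b <- center_b + half_b
  inter <- pmax(0, pmin(hi_a, hi_b) - pmax(lo_a, lo_b))
  denom <- switch(method,
                  jaccard = pmax(hi_a, hi_b) - pmin(lo_a, lo_b),
                  min = pmin(hi_a - lo_a, hi_b - lo_b))
  overlap <- ifelse(denom > 0, inter / denom,
                    # both intervals degenerate: overlap iff equal
                    as.numeric(center_a == center_b))
  1 - overlap
}

#' Developmental change in functional connectivity
#'
#' Per edge, the signed session difference of group-mean FC, shrunk by the
#' confidence-interval overlap weight:
#' `dFC = sign(d) * |d| * (1 - overlap)`, `d = mean_ses2 - mean_ses1`.
#' High CI overlap (a difference small relative to across-subject spread)
#' drives the change toward 0; disjoint CIs leave the raw difference.
#'
#' @param fc_stack_ses1,fc_stack_ses2 `subjects x R x R` arrays of subject FC
#'   matrices for the two sessions (>= 3 subjects each).
#' @param z_mult,use_sem,method Passed to [edge_ci()] and
#'   [ci_overlap_weight()].
#' @return A [conn_matrix()] with modality `"dFC"`, diagonal 0.
#' @export
delta_fc <- function(fc_stack_ses1, fc_stack_ses2, z_mult = 1.96,
                     use_sem = TRUE, method = c("jaccard", "min")) {
  method <- match.arg(method)
  if (!identical(dim(fc_stack_ses1)[2:3], dim(fc_stack_ses2)[2:3])) {
    stop("FC stacks have mismatched ROI dimensions", call. = FALSE)
  }
  ci1 <- edge_ci(fc_stack_ses1, z_mult = z_mult, use_sem = use_sem)
  ci2 <- edge_ci(fc_stack_ses2, z_mult = z_mult, use_sem = use_sem)
  d <- ci2$center - ci1$center
  w <- ci_overlap_weight(ci1$center, ci1$half_width,
                         ci2$center, ci2$half_width, method = method)
  out <- d * w
  diag(out) <- 0
  out <- (out + t(out)) / 2
  conn_matrix(out, modality = "dFC", group = "PT:ses2-ses1", signed = TRUE,
              roi_names = dimnames(fc_stack_ses1)[[2]])
}
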