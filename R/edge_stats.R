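# Edge-level statistical machinery: distribution tests, Huber robust
# regression with permutation-tested slopes, slope Z-comparisons, BH-FDR and
# top-fraction thresholding.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the pipeline's
#' preconditions made explicit (3 <= n <= 5000, non-constant input).
#'
#' @param values Numeric vector.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (max(values) == min(values)) {
    stop("Shapiro-Wilk is undefined for constant input", call. = FALSE)
  }
  st <- stats::shapiro.test(values)
  list(statistic = unname(st$statistic), p_value = st$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences `a - b`. Zero differences are
#' dropped (Wilcoxon's original treatment). The reported statistic `W` uses
#' the smaller-rank-sum convention, `W = min(T+, T-)`, which is documented
#' here because printed W values depend on it. The two-sided p-value comes
#' from [stats::wilcox.test()] (exact when feasible, otherwise the normal
#' approximation with continuity correction).
#'
#' @param vec_a,vec_b Equal-length numeric vectors (n >= 5).
#' @return List with `statistic` (W), `p_value`, `n_pairs` (non-zero
#'   differences used) and `direction` (sign of the median difference).
#' @export
paired_wilcoxon <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(vec_a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- vec_a - vec_b
  dz <- d[d != 0]
  if (!length(dz)) {
    stop("all paired differences are zero; signed-rank test is degenerate",
         call. = FALSE)
  }
  r <- rank(abs(dz))
  t_pos <- sum(r[dz > 0])
  t_neg <- sum(r[dz < 0])
  w <- min(t_pos, t_neg)
  p <- suppressWarnings(stats::wilcox.test(dz, mu = 0)$p.value)
  list(statistic = w, p_value = p, n_pairs = length(dz),
       direction = sign(stats::median(d)))
}

# One IRLS pass machinery for simple (intercept + slope) Huber regression.
# Closed-form weighted least squares per iteration keeps the permutation loop
# cheap. Scale is re-estimated each iteration as the MAD of the residuals.
.huber_irls <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 100L) {
  n <- length(x)
  xb0 <- mean(x); yb0 <- mean(y)
  sxx0 <- sum((x - xb0)^2)
  b <- sum((x - xb0) * (y - yb0)) / sxx0
  a <- yb0 - b * xb0
  w <- rep(1, n)
  converged <- FALSE
  scale <- NA_real_
  for (it in seq_len(max_iter)) {
    r <- y - a - b * x
    s <- stats::mad(r)
    if (s == 0) s <- mean(abs(r)) * sqrt(pi / 2)
    if (s == 0) { # perfect fit
      converged <- TRUE
      scale <- 0
      w <- rep(1, n)
      break
    }
    absr <- abs(r)
    w <- ifelse(absr <= k * s, 1, k * s / absr)
    sw <- sum(w)
    xb <- sum(w * x) / sw
    yb <- sum(w * y) / sw
    xc <- x - xb
    b_new <- sum(w * xc * (y - yb)) / sum(w * xc * xc)
    a_new <- yb - b_new * xb
    if (max(abs(b_new - b), abs(a_new - a)) < tol) {
      a <- a_new; b <- b_new
      converged <- TRUE
      scale <- s
      break
    }
    a <- a_new; b <- b_new
    scale <- s
  }
  list(intercept = a, slope = b, weights = w, scale = scale,
       converged = converged, iterations = it)
}

#' Huber robust linear regression (edge vectors)
#'
#' Fits `y ~ x` by iteratively reweighted least squares with Huber weighting
#' (tuning constant `k = 1.345`, 95% Gaussian efficiency), residual scale
#' re-estimated each iteration by the MAD. Convergence is declared when the
#' coefficient change drops below `tol` (default 1e-8); non-convergence
#' within `max_iter` iterations is an error. The slope standard error is the
#' asymptotic Huber sandwich estimate.
#'
#' @param x,y Equal-length numeric vectors, `n >= 10`, `x` non-constant.
#' @param k Huber tuning constant.
#' @param tol Coefficient-change convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `huber_fit`: `slope`, `intercept`, `slope_se`,
#'   `n_edges`, `iterations`, plus `permutation_p`/`n_permutations`/`seed`
#'   slots filled by [permute_slope_p()].
#' @export
huber_fit <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 100L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("huber_fit needs >= 10 observations", call. = FALSE)
  if (max(x) == min(x)) stop("predictor x is constant", call. = FALSE)
  fit <- .huber_irls(x, y, k = k, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    stop("Huber IRLS did not converge in ", fit$iterations, " iterations",
         call. = FALSE)
  }
  r <- y - fit$intercept - fit$slope * x
  s <- fit$scale
  if (is.na(s) || s == 0) {
    se <- 0
  } else {
    u <- r / s
    psi <- pmax(pmin(u, k), -k)
    dpsi <- as.numeric(abs(u) <= k)
    sxx <- sum((x - mean(x))^2)
    se <- sqrt(s^2 * sum(psi^2) / (n - 2) / mean(dpsi)^2 / sxx)
  }
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 slope_se = se, n_edges = n, iterations = fit$iterations,
                 k = k, permutation_p = NA_real_,
                 n_permutations = NA_integer_, seed = NA_integer_),
            class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat(sprintf("Huber fit (k = %.3f, n = %d): slope %.4f (SE %.4f), intercept %.4f\n",
              x$k, x$n_edges, x$slope, x$slope_se, x$intercept))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  }
  invisible(x)
}

#' Permutation p-value for a Huber regression slope
#'
#' Shuffles `y` relative to `x` `n_perm` times, refits the Huber slope each
#' time, and reports the two-sided permutation p-value with the add-one
#' estimator `p = (1 + #{|slope_perm| >= |slope_obs|}) / (1 + n_perm)` (never
#' exactly zero; converges to the plain proportion of more-extreme
#' permutations as `n_perm` grows).
#'
#' @param x,y Edge vectors (see [huber_fit()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param fit An existing [huber_fit()] of `(x, y)` to reuse.
#' @return The `huber_fit` with `permutation_p`, `n_permutations`, `seed`
#'   filled in.
#' @export
permute_slope_p <- function(x, y, n_perm = 1000L, seed = NULL, fit = NULL) {
  if (is.null(fit)) fit <- huber_fit(x, y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  obs <- abs(fit$slope)
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      bp <- .huber_irls(x, yp, k = fit$k)$slope
      if (abs(bp) >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  fit$permutation_p <- (1 + count) / (1 + n_perm)
  fit$n_permutations <- as.integer(n_perm)
  fit$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  fit
}

#' Compare two regression slopes with a Z-score
#'
#' `Z = (slope_1 - slope_2) / sqrt(se_1^2 + se_2^2)`, two-sided normal
#' p-value.
#'
#' @param fit_1,fit_2 [huber_fit()] results (finite SEs).
#' @return List with `z` and `p_value`.
#' @export
compare_slopes_z <- function(fit_1, fit_2) {
  se <- sqrt(fit_1$slope_se^2 + fit_2$slope_se^2)
  if (!is.finite(se) || se == 0) {
    stop("combined slope standard error is zero or non-finite", call. = FALSE)
  }
  z <- (fit_1$slope - fit_2$slope) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation on the `[0, 1]` range.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold connectivity matrices at their strongest fraction
#'
#' Keeps the strongest `fraction` of edges, either with a threshold
#' `adapted` to each matrix (its own `ceiling(fraction * n_edges)`-th largest
#' upper-triangle value) or with a single `common` threshold computed the
#' same way from the pooled upper-triangle values of all supplied matrices.
#' Edges with values tied at the threshold are all kept (`>=` comparison),
#' so the kept count can slightly exceed `fraction * n_edges` under ties.
#'
#' @param matrices A single matrix / [conn_matrix()] or a (named) list.
#' @param fraction Fraction of edges to keep, in (0, 1); default 0.25.
#' @param mode `"adapted"` or `"common"`.
#' @return List with `thresholds` (named numeric) and `masks` (named list of
#'   logical edge vectors in [edge_pairs()] order).
#' @export
threshold_top_fraction <- function(matrices, fraction = 0.25,
                                   mode = c("adapted", "common")) {
  mode <- match.arg(mode)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("matrix", seq_along(matrices))
  }
  vecs <- lapply(matrices, function(m) upper_triangle(as_plain_matrix(m)))
  kth_largest <- function(v) {
    sort(v, decreasing = TRUE)[ceiling(fraction * length(v))]
  }
  if (mode == "common") {
    thr <- kth_largest(unlist(vecs, use.names = FALSE))
    thresholds <- stats::setNames(rep(thr, length(vecs)), names(vecs))
  } else {
    thresholds <- vapply(vecs, kth_largest, numeric(1))
  }
  masks <- Map(function(v, t) v >= t, vecs, thresholds)
  list(thresholds = thresholds, masks = masks, mode = mode,
       fraction = fraction)
}

#' Robust MC-FC regressions over connection subsets
#'
#' For each requested connection subset (whole-brain, cortico-subcortical,
#' thalamo-cortical, intra-/inter-hemispheric cortico-cortical, SM, VIS),
#' fits the robust regression of the response edge values on the predictor
#' edge values (by convention MC is the predictor and FC the response), with
#' a permutation-tested slope, and Benjamini-Hochberg-adjusts the permutation
#' p-values across the reported family. Subsets with fewer than `min_edges`
#' edges are recorded as skipped rather than erroring.
#'
#' @param mc Predictor matrix (e.g. group MC).
#' @param fc Response matrix (e.g. group FC), same atlas order.
#' @param labeling Output of [label_edges()].
#' @param subsets Character vector of subset names (default: all of
#'   [edge_subset_masks()]).
#' @param n_perm Permutations per subset (default 1000).
#' @param seed Optional master seed; subset fits use derived sub-seeds.
#' @param min_edges Minimum edges per subset (default 10).
#' @return Data frame with columns `subset`, `n_edges`, `slope`, `intercept`,
#'   `slope_se`, `perm_p`, `perm_p_bh`, `n_perm`, `seed`.
#' @export
subset_regression_report <- function(mc, fc, labeling, subsets = NULL,
                                     n_perm = 1000L, seed = NULL,
                                     min_edges = 10L) {
  xm <- as_plain_matrix(mc); ym <- as_plain_matrix(fc)
  if (!identical(dim(xm), dim(ym))) {
    stop("predictor and response matrices have mismatched dimensions",
         call. = FALSE)
  }
  n_edges_total <- nrow(xm) * (nrow(xm) - 1L) / 2L
  if (nrow(labeling) != n_edges_total) {
    stop("edge labeling does not match the matrix size", call. = FALSE)
  }
  x <- upper_triangle(xm)
  y <- upper_triangle(ym)
  masks <- edge_subset_masks(labeling)
  if (!is.null(subsets)) {
    bad <- setdiff(subsets, names(masks))
    if (length(bad)) stop("unknown subset(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    masks <- masks[subsets]
  }
  rows <- lapply(seq_along(masks), function(i) {
    mask <- masks[[i]]
    nm <- names(masks)[i]
    ne <- sum(mask)
    if (ne < min_edges) {
      return(data.frame(subset = nm, n_edges = ne, slope = NA_real_,
                        intercept = NA_real_, slope_se = NA_real_,
                        perm_p = NA_real_, perm_p_bh = NA_real_,
                        n_perm = NA_integer_, seed = NA_integer_,
                        skipped = TRUE))
    }
    sub_seed <- if (is.null(seed)) NULL else {
      as.integer(derive_seed(seed, "subset_regression", i) %% 2147483647)
    }
    fit <- permute_slope_p(x[mask], y[mask], n_perm = n_perm, seed = sub_seed)
    data.frame(subset = nm, n_edges = ne, slope = fit$slope,
               intercept = fit$intercept, slope_se = fit$slope_se,
               perm_p = fit$permutation_p, perm_p_bh = NA_real_,
               n_perm = fit$n_permutations,
               seed = if (is.null(sub_seed)) NA_integer_ else sub_seed,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$perm_p_bh[!out$skipped] <- bh_fdr(out$perm_p[!out$skipped])
  out
}
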