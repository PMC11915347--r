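# Network extraction and overlap: cosine-theorem distances, Ward hierarchical
# clustering, mutual information between clusterings across all cluster-size
# pairs, permutation nulls and significant-pair summaries.

#' Cosine-theorem distance from a correlation matrix
#'
#' `d[i, j] = sqrt(2 * (1 - rho[i, j]))` — the Euclidean distance between
#' standardized profiles with correlation `rho`. For MC the absolute
#' correlation is used (`use_abs = TRUE`); FC keeps the signed correlation.
#'
#' @param m Correlation-like matrix with values in `[-1, 1]` (a tolerance of
#'   1e-8 is allowed and clipped; larger excursions are an error).
#' @param use_abs Use `|r|` instead of `r`.
#' @return A symmetric distance matrix with zero diagonal, values in
#'   `[0, 2]`.
#' @export
corr_to_distance <- function(m, use_abs = FALSE) {
  m <- as_plain_matrix(m)
  if (any(abs(m) > 1 + 1e-8)) {
    stop("correlation values outside [-1, 1]", call. = FALSE)
  }
  rho <- if (use_abs) abs(m) else m
  rho <- pmin(pmax(rho, -1), 1)
  d <- sqrt(pmax(2 * (1 - rho), 0))
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Ward dendrogram of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion on an (assumed Euclidean)
#' distance matrix — `stats::hclust(method = "ward.D2")`, which applies the
#' Lance-Williams update on squared distances. The cosine-theorem distance of
#' [corr_to_distance()] is Euclidean for standardized profiles, so Ward's
#' variance interpretation holds. Output is deterministic for a given input.
#'
#' @param d Square symmetric distance matrix (finite entries) or a `dist`.
#' @return An `hclust` object (75-leaf dendrograms have 74 merges).
#' @export
ward_dendrogram <- function(d) {
  if (is.matrix(d)) {
    if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro An `hclust` object.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Integer label vector (1..k, renumbered in leaf order).
#' @export
cut_dendrogram <- function(dendro, k) {
  n_leaves <- length(dendro$order)
  if (k < 1L || k > n_leaves) {
    stop("k must lie in 1..", n_leaves, call. = FALSE)
  }
  unname(stats::cutree(dendro, k = k))
}

#' Mutual information between two clusterings (nats)
#'
#' Raw (unadjusted) mutual information of the contingency table of two label
#' vectors, in natural log units: `MI = sum p_ij log(p_ij / (p_i q_j))`.
#' Always >= 0 and bounded by `min(H(a), H(b))`.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(labels_a, labels_b) {
  n <- length(labels_a)
  if (n == 0L) stop("empty labelings", call. = FALSE)
  if (length(labels_b) != n) {
    stop("labelings must have equal length", call. = FALSE)
  }
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  .mi_nats(a, b, max(a), max(b))
}

# fast core: a, b already integer in 1..ka / 1..kb
.mi_nats <- function(a, b, ka, kb) {
  n <- length(a)
  code <- (a - 1L) * kb + b
  cnt <- rle(sort.int(code, method = "quick"))
  pj <- cnt$lengths / n
  ai <- (cnt$values - 1L) %/% kb + 1L
  bj <- (cnt$values - 1L) %% kb + 1L
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  sum(pj * (log(pj) - log(pa[ai]) - log(pb[bj])))
}

.entropy_int <- function(x, k) {
  p <- tabulate(x, k)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

# Null MI sample for one (a, b) pair under n_perm shuffles of b, batched via
# MI = H(a) + H(b) - H(a,b). All shuffles are generated in one two-key radix
# sort (order of uniform keys within blocks) and the joint entropies of all
# shuffles are read off one sorted code vector; H(b) is shuffle-invariant
# because shuffling preserves cluster sizes.
.gen_perms <- function(n, n_perm, seed) {
  block <- rep.int(seq_len(n_perm), rep.int(n, n_perm))
  perm <- with_seed(seed, {
    order(block, stats::runif(n * n_perm)) - (block - 1L) * n
  })
  list(perm = perm, block = block)
}

.mi_null_from_perms <- function(a, b, ka, kb, perms) {
  n <- length(a)
  len <- length(perms$perm)
  ncells <- ka * kb
  code <- (a - 1L) * kb + b[perms$perm] + (perms$block - 1L) * ncells
  v <- sort.int(code, method = "radix")
  ends <- c(which(v[-1L] != v[-len]), len)
  p <- diff(c(0L, ends)) / n
  cs <- cumsum(p * log(p))
  gpe <- (v[ends] - 1L) %/% ncells
  ge <- c(which(gpe[-1L] != gpe[-length(gpe)]), length(gpe))
  .entropy_int(a, ka) + .entropy_int(b, kb) + diff(c(0, cs[ge]))
}

.mi_null_sample <- function(a, b, ka, kb, n_perm, seed) {
  .mi_null_from_perms(a, b, ka, kb, .gen_perms(length(a), n_perm, seed))
}

#' Entropy of a clustering (nats)
#'
#' @param labels Label vector.
#' @return Shannon entropy in nats.
#' @export
cluster_entropy <- function(labels) {
  p <- tabulate(as.integer(factor(labels)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Mutual information across all cluster-size pairs
#'
#' Cuts both dendrograms at every `k` in `k_range` and computes the mutual
#' information for every `(k_a, k_b)` pair.
#'
#' @param d_a,d_b `hclust` dendrograms over the same leaf set.
#' @param k_range Cluster sizes (default `2:75`).
#' @return Numeric matrix `length(k_range) x length(k_range)`, dimnames the
#'   k values; rows index cuts of `d_a`.
#' @export
mi_across_scales <- function(d_a, d_b, k_range = 2:75) {
  if (length(d_a$order) != length(d_b$order)) {
    stop("dendrograms have different leaf sets", call. = FALSE)
  }
  cuts_a <- lapply(k_range, function(k) cut_dendrogram(d_a, k))
  cuts_b <- lapply(k_range, function(k) cut_dendrogram(d_b, k))
  mi <- matrix(NA_real_, length(k_range), length(k_range),
               dimnames = list(k_range, k_range))
  for (ia in seq_along(k_range)) {
    a <- cuts_a[[ia]]
    ka <- max(a)
    for (ib in seq_along(k_range)) {
      b <- cuts_b[[ib]]
      mi[ia, ib] <- .mi_nats(a, b, ka, max(b))
    }
  }
  mi
}

#' Permutation null for the MI of two labelings
#'
#' Shuffles one labeling's assignment vector `n_perm` times (cluster sizes
#' preserved by construction) and recomputes the MI, yielding a null sample
#' and its 95th percentile (nearest-rank on the sorted null, unambiguous at
#' small `n_perm`).
#'
#' @param labels_a,labels_b Label vectors.
#' @param n_perm Number of shuffles (default 100).
#' @param seed Optional seed.
#' @param prob Percentile reported (default 0.95).
#' @return List with `null` (numeric vector), `p95`, and `observed`.
#' @export
mi_permutation_null <- function(labels_a, labels_b, n_perm = 100L,
                                seed = NULL, prob = 0.95) {
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  ka <- max(a); kb <- max(b)
  obs <- .mi_nats(a, b, ka, kb)
  null <- .mi_null_sample(a, b, ka, kb, n_perm, seed)
  p95 <- sort(null)[ceiling(prob * n_perm)]
  list(null = null, p95 = p95, observed = obs)
}

#' Compare two dendrograms across all cluster-size pairs with nulls
#'
#' For every `(k_a, k_b)` pair, computes the observed MI and a 100-shuffle
#' permutation null; cells whose observed MI exceeds the null's 95th
#' percentile are flagged significant, and the significant cells are
#' summarized by their mean and SD.
#'
#' @param d_a,d_b `hclust` dendrograms over the same leaves.
#' @param k_range Cluster sizes (default `2:75`).
#' @param n_perm Shuffles per cell (default 100).
#' @param seed Optional master seed (per-cell sub-seeds are derived).
#' @param labels Optional `c(name_a, name_b)` recorded on the result.
#' @return A list of class `mi_comparison`: matrices `mi`, `null_p95`,
#'   logical `significant`, and the [summarize_mi()] fields.
#' @export
mi_comparison <- function(d_a, d_b, k_range = 2:75, n_perm = 100L,
                          seed = NULL, labels = c("A", "B")) {
  if (length(d_a$order) != length(d_b$order)) {
    stop("dendrograms have different leaf sets", call. = FALSE)
  }
  cuts_a <- lapply(k_range, function(k) cut_dendrogram(d_a, k))
  cuts_b <- lapply(k_range, function(k) cut_dendrogram(d_b, k))
  nk <- length(k_range)
  mi <- matrix(NA_real_, nk, nk, dimnames = list(k_range, k_range))
  p95 <- mi
  # one set of shuffle draws per comparison (derived from the seed), applied
  # to every cluster-size pair: each cell still gets an n_perm-value null of
  # its own cuts under those shuffles
  cmp_seed <- if (is.null(seed)) NULL else {
    as.integer(derive_seed(seed, "mi_null") %% 2147483647)
  }
  perms <- .gen_perms(length(d_a$order), n_perm, cmp_seed)
  for (ia in seq_len(nk)) {
    a <- cuts_a[[ia]]
    ka <- max(a)
    for (ib in seq_len(nk)) {
      b <- cuts_b[[ib]]
      kb <- max(b)
      mi[ia, ib] <- .mi_nats(a, b, ka, kb)
      nullv <- .mi_null_from_perms(a, b, ka, kb, perms)
      p95[ia, ib] <- sort(nullv)[ceiling(0.95 * n_perm)]
    }
  }
  sig <- mi > p95
  res <- structure(list(mi = mi, null_p95 = p95, significant = sig,
                        k_range = k_range, n_perm = as.integer(n_perm),
                        seed = seed, labels = labels),
                   class = "mi_comparison")
  s <- summarize_mi(res)
  res$mean_significant <- s$mean_significant
  res$sd_significant <- s$sd_significant
  res$n_significant <- s$n_significant
  res
}

#' Summarize an MI comparison over its significant cells
#'
#' Mean and SD of the observed MI over cells exceeding their null's 95th
#' percentile. With no significant cell the mean/SD are `NA` ("no significant
#' overlap"), not an error.
#'
#' @param comparison An `mi_comparison`.
#' @return List with `mean_significant`, `sd_significant`, `n_significant`.
#' @export
summarize_mi <- function(comparison) {
  stopifnot(inherits(comparison, "mi_comparison"))
  vals <- comparison$mi[comparison$significant]
  n_sig <- length(vals)
  list(
    mean_significant = if (n_sig) mean(vals) else NA_real_,
    sd_significant = if (n_sig > 1L) stats::sd(vals) else
      if (n_sig == 1L) 0 else NA_real_,
    n_significant = n_sig
  )
}

#' @export
print.mi_comparison <- function(x, ...) {
  cat(sprintf("MI comparison %s vs %s: k in %d..%d, %d permutations\n",
              x$labels[1], x$labels[2], min(x$k_range), max(x$k_range),
              x$n_perm))
  cat(sprintf("  significant cells: %d / %d; mean significant MI %.4f (SD %.4f)\n",
              x$n_significant, length(x$mi),
              x$mean_significant, x$sd_significant))
  invisible(x)
}
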