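# Edge indexing and edge-subset labeling.
#
# All vectorized edge quantities in the package use one fixed convention:
# the row-major upper triangle, i < j, i.e. (1,2),(1,3),...,(1,R),(2,3),...
# For R = 75 regions that is 2775 edges.

#' Enumerate edges in canonical order
#'
#' @param n_rois Number of regions.
#' @return A data frame with columns `i`, `j` (1-based ROI ids, `i < j`) and
#'   `linear_pos` (position in the row-major upper-triangle ordering).
#' @examples
#' head(edge_pairs(4))
#' @export
edge_pairs <- function(n_rois) {
  stopifnot(n_rois >= 2)
  i <- rep.int(seq_len(n_rois - 1L), times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(k) (k + 1L):n_rois),
              use.names = FALSE)
  data.frame(i = i, j = j, linear_pos = seq_along(i))
}

# linear index matrix into an R x R matrix for the canonical edge order
.edge_flat_idx <- function(n_rois) {
  ep <- edge_pairs(n_rois)
  cbind(ep$i, ep$j)
}

#' Extract the upper triangle of a symmetric connectivity matrix
#'
#' @param m A square numeric matrix, symmetric to within `tol`.
#' @param tol Maximum tolerated `|m - t(m)|`.
#' @return Numeric vector of length `R(R-1)/2` in [edge_pairs()] order.
#' @seealso [edges_to_matrix()] for the inverse.
#' @export
upper_triangle <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  dev <- abs(m - t(m))
  if (any(dev > tol, na.rm = TRUE)) {
    w <- which(dev == max(dev), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is not symmetric: max deviation %.3g at entry (%d, %d)",
      max(dev), min(w), max(w)), call. = FALSE)
  }
  m[.edge_flat_idx(nrow(m))]
}

#' Rebuild a symmetric matrix from an edge-value vector
#'
#' @param v Edge values in canonical order.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return A symmetric `R x R` matrix.
#' @export
edges_to_matrix <- function(v, diag_value = 0) {
  n2 <- length(v)
  n <- (1 + sqrt(1 + 8 * n2)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("length ", n2, " is not a triangular number", call. = FALSE)
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  idx <- .edge_flat_idx(n)
  m[idx] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Label every edge with its connection subtype
#'
#' Assigns each of the `R(R-1)/2` edges exactly one of five mutually
#' exclusive categories — `cortico-subcortical`, `subcortico-subcortical`,
#' and for cortico-cortical edges `cc-intraH`, `cc-interH-homo` (links
#' homotopic partners) or `cc-interH-non-homo` — plus boolean flags for
#' thalamo-cortical edges and edges touching the primary sensorimotor (SM) or
#' visual (VIS) systems.
#'
#' @param atlas An `roi_atlas` (see [default_atlas()]).
#' @return A data frame with one row per edge: `i`, `j`, `linear_pos`,
#'   `category`, `thalamo_cortical`, `involves_SM`, `involves_VIS`.
#' @examples
#' lab <- label_edges(default_atlas())
#' table(lab$category)
#' @export
label_edges <- function(atlas) {
  validate_atlas(atlas)
  ep <- edge_pairs(nrow(atlas))
  cort <- atlas$is_cortical
  hp <- atlas$homotopic_partner
  hemi <- atlas$hemisphere
  tags <- strsplit(atlas$system_tags, ";", fixed = TRUE)
  has_tag <- function(tag) vapply(tags, function(t) tag %in% t, logical(1))
  is_thal <- has_tag("thalamus")
  is_sm <- has_tag("SM")
  is_vis <- has_tag("VIS")

  ci <- cort[ep$i]; cj <- cort[ep$j]
  category <- character(nrow(ep))
  category[!ci & !cj] <- "subcortico-subcortical"
  category[xor(ci, cj)] <- "cortico-subcortical"
  cc <- ci & cj
  same_h <- hemi[ep$i] == hemi[ep$j]
  homo <- !is.na(hp[ep$i]) & hp[ep$i] == ep$j
  category[cc & same_h] <- "cc-intraH"
  category[cc & !same_h & homo] <- "cc-interH-homo"
  category[cc & !same_h & !homo] <- "cc-interH-non-homo"

  thalcort <- (is_thal[ep$i] & cj) | (is_thal[ep$j] & ci)
  out <- data.frame(
    i = ep$i, j = ep$j, linear_pos = ep$linear_pos,
    category = category,
    thalamo_cortical = thalcort,
    involves_SM = is_sm[ep$i] | is_sm[ep$j],
    involves_VIS = is_vis[ep$i] | is_vis[ep$j],
    stringsAsFactors = FALSE
  )
  stopifnot(all(nzchar(out$category)))
  out
}

#' Logical edge masks for the standard connection subsets
#'
#' The reported subset family: whole-brain (all edges), cortico-subcortical,
#' thalamo-cortical, intra-hemispheric cortico-cortical, inter-hemispheric
#' homotopic and non-homotopic cortico-cortical, and the SM / VIS system
#' subsets (restricted to edges with at least one cortical end).
#' Subcortico-subcortical edges are kept in `whole_brain` and excluded from
#' the stratified subsets.
#'
#' @param labeling Output of [label_edges()].
#' @return Named list of logical vectors over edges.
#' @export
edge_subset_masks <- function(labeling) {
  strat <- labeling$category != "subcortico-subcortical"
  list(
    whole_brain = rep(TRUE, nrow(labeling)),
    cortico_subcortical = labeling$category == "cortico-subcortical",
    thalamo_cortical = labeling$thalamo_cortical,
    cc_intraH = labeling$category == "cc-intraH",
    cc_interH_homo = labeling$category == "cc-interH-homo",
    cc_interH_non_homo = labeling$category == "cc-interH-non-homo",
    SM = labeling$involves_SM & strat,
    VIS = labeling$involves_VIS & strat
  )
}
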