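# Light container for connectivity matrices: a plain numeric matrix with
# modality/group metadata attributes, ROI names as dimnames.

#' Construct a connectivity matrix object
#'
#' @param values Square symmetric numeric matrix in atlas ROI order.
#' @param modality One of `"MC"`, `"FC"`, `"dMC"`, `"dFC"`.
#' @param group Group label (e.g. `"PT:ses1"`), or `NA`.
#' @param signed Logical; whether entries may be negative.
#' @param roi_names Optional character vector of ROI names.
#' @return A matrix of class `conn_matrix`.
#' @export
conn_matrix <- function(values, modality = c("MC", "FC", "dMC", "dFC"),
                        group = NA_character_, signed = TRUE,
                        roi_names = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!is.null(roi_names)) dimnames(values) <- list(roi_names, roi_names)
  structure(values, modality = modality, group = group, signed = signed,
            class = c("conn_matrix", class(values)))
}

#' @export
print.conn_matrix <- function(x, ...) {
  v <- upper_triangle(unclass(x))
  cat(sprintf("%s connectivity matrix [%s]: %d ROIs, %d edges, range [%.3f, %.3f]\n",
              attr(x, "modality"), attr(x, "group") %||% "?", nrow(x),
              length(v), min(v), max(v)))
  invisible(x)
}

# strip conn_matrix attributes, keep dimnames
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "modality") <- NULL
  attr(m, "group") <- NULL
  attr(m, "signed") <- NULL
  m
}
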