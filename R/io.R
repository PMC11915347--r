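# Plain-text readers and writers for the pipeline's interchange formats:
# connectivity matrices (TSV with ROI-name headers), ROI time series (TSV +
# JSON sidecar), dendrogram merge tables (CSV) and circos-ready edge lists.

#' Read / write a connectivity matrix as TSV
#'
#' TSV with ROI names as header row and first column, full double precision.
#' Modality/group metadata travel in a JSON sidecar (`<path>.json`).
#'
#' @param m A [conn_matrix()] (write) / file path (read).
#' @param path File path.
#' @return `read_matrix_tsv()` returns a `conn_matrix`.
#' @export
write_matrix_tsv <- function(m, path) {
  mat <- as_plain_matrix(m)
  df <- data.frame(roi = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                   mat, check.names = FALSE)
  colnames(df) <- c("roi", rownames(mat) %||% as.character(seq_len(nrow(mat))))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(modality = attr(m, "modality") %||% "MC",
               group = attr(m, "group"),
               signed = attr(m, "signed") %||% TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  rois <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(rois, colnames(df)[-1])
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  conn_matrix(mat, modality = meta$modality %||% "MC",
              group = meta$group %||% NA_character_,
              signed = meta$signed %||% TRUE)
}

#' Write / read a group's ROI time series
#'
#' One TSV per subject (rows = named ROIs, columns = time points) plus a JSON
#' sidecar per subject holding `subject_id`, `group` and `sampling_interval`.
#' Files are named `<prefix>_<subject_id>.tsv`.
#'
#' @param ts A [timeseries_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the group label, slashes/colons
#'   replaced).
#' @param atlas Optional atlas for ROI row names.
#' @return `read_timeseries_set()` returns a `timeseries_set`.
#' @export
write_timeseries_set <- function(ts, dir, prefix = NULL,
                                 atlas = NULL) {
  stopifnot(inherits(ts, "timeseries_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% gsub("[^A-Za-z0-9]+", "_", ts$group)
  for (s in seq_along(ts$series)) {
    m <- ts$series[[s]]
    rn <- if (!is.null(atlas)) atlas$name else
      rownames(m) %||% paste0("roi", seq_len(nrow(m)))
    df <- data.frame(roi = rn, m, check.names = FALSE)
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, ts$subject_ids[s]))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subject_id = ts$subject_ids[s], group = ts$group,
           sampling_interval = ts$sampling_interval),
      paste0(f, ".json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_timeseries_set
#' @param files Character vector of subject TSV paths (each with its
#'   `.json` sidecar).
#' @export
read_timeseries_set <- function(files) {
  if (!length(files)) stop("no time-series files supplied", call. = FALSE)
  series <- list(); ids <- character(); group <- NA; si <- NA
  for (f in files) {
    if (!file.exists(f)) stop("time-series file not found: ", f, call. = FALSE)
    df <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    meta <- jsonlite::read_json(paste0(f, ".json"))
    series[[length(series) + 1L]] <- m
    ids <- c(ids, meta$subject_id)
    group <- meta$group
    si <- meta$sampling_interval
  }
  timeseries_set(series, ids, group, si)
}

#' Serialize a dendrogram as a merge table
#'
#' CSV with columns `step,left,right,height` using `hclust` merge coding
#' (negative = leaf index, positive = earlier merge step). Round-trips
#' exactly; the leaf ordering for plotting is reconstructed on read.
#'
#' @param dendro An `hclust` object.
#' @param path CSV path.
#' @return `read_dendrogram_csv()` returns an `hclust`.
#' @export
write_dendrogram_csv <- function(dendro, path) {
  df <- data.frame(step = seq_len(nrow(dendro$merge)),
                   left = dendro$merge[, 1], right = dendro$merge[, 2],
                   height = format(dendro$height, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# leaf order by in-order traversal of the merge tree
.merge_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @rdname write_dendrogram_csv
#' @export
read_dendrogram_csv <- function(path) {
  if (!file.exists(path)) stop("dendrogram file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  merge <- cbind(df$left, df$right)
  hc <- list(merge = merge, height = as.numeric(df$height),
             order = .merge_order(merge),
             labels = NULL, method = "ward.D2",
             call = NULL, dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

#' Export a thresholded edge list for circos-style plots
#'
#' Writes the kept edges of a connectivity matrix as a CSV with columns
#' `roi_i,roi_j,lobe_i,lobe_j,value,sign` (one row per kept edge, canonical
#' edge order; header only if the mask is empty).
#'
#' @param m Connectivity matrix ([conn_matrix()] or plain).
#' @param atlas `roi_atlas` aligned with the matrix.
#' @param mask Logical edge vector (e.g. from [threshold_top_fraction()]).
#' @param path CSV path.
#' @return The path, invisibly; the edge-list data frame as attribute
#'   `"edges"`.
#' @export
export_circos_edges <- function(m, atlas, mask, path) {
  v <- upper_triangle(as_plain_matrix(m))
  if (length(mask) != length(v)) {
    stop("edge mask length does not match the matrix", call. = FALSE)
  }
  ep <- edge_pairs(nrow(atlas))
  keep <- which(mask)
  df <- data.frame(
    roi_i = atlas$name[ep$i[keep]], roi_j = atlas$name[ep$j[keep]],
    lobe_i = atlas$lobe[ep$i[keep]], lobe_j = atlas$lobe[ep$j[keep]],
    value = v[keep], sign = ifelse(v[keep] >= 0, 1L, -1L),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  out <- invisible(path)
  attr(out, "edges") <- df
  out
}
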