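# ROI atlas: 75 grey-matter regions (62 cortical DKT-style labels, 13
# subcortical parcels), with hemisphere, lobe, homotopy and functional-system
# tags. This table anchors the ROI ordering used by every connectivity matrix.

# The 31 DKT cortical labels per hemisphere, with lobe assignment.
.dkt_cortical <- data.frame(
  base = c(
    "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
    "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
    "lateraloccipital", "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "parahippocampal", "paracentral", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "transversetemporal", "insula"
  ),
  lobe = c(
    "cingulate", "frontal", "occipital", "temporal",
    "temporal", "parietal", "temporal", "cingulate",
    "occipital", "frontal", "occipital", "frontal",
    "temporal", "temporal", "frontal", "frontal",
    "frontal", "frontal", "occipital", "parietal",
    "cingulate", "frontal", "parietal", "cingulate",
    "frontal", "frontal", "parietal",
    "temporal", "parietal", "temporal", "insular"
  ),
  stringsAsFactors = FALSE
)

# primary sensorimotor and visual system tags available in this parcellation
.sm_labels  <- c("precentral", "postcentral", "paracentral")
.vis_labels <- c("pericalcarine", "lateraloccipital", "cuneus")

.subcortical_bases <- c("thalamus", "caudate", "lenticular", "amygdala",
                        "hippocampus", "cerebellum")

#' Default 75-region grey-matter atlas
#'
#' Builds the package's default ROI atlas: 62 cortical regions (the 31-label
#' DKT cortical scheme in each hemisphere), 12 bilateral subcortical parcels
#' (thalamus, caudate, lenticular and amygdala nuclei, hippocampus,
#' cerebellum) and the medial brainstem. Cortical regions carry one of six
#' lobes; subcortical regions the pseudo-lobe `"subcortical"`. Homotopic
#' partners link the left and right instance of the same label; the brainstem,
#' being medial, has none. Primary sensorimotor (`SM`: precentral,
#' postcentral, paracentral) and visual (`VIS`: pericalcarine,
#' lateral occipital, cuneus) labels and the thalami are tagged so that
#' edge subsets (thalamo-cortical, SM, VIS) can be selected downstream.
#'
#' @return A data frame of class `roi_atlas` with one row per ROI and columns
#'   `roi_id` (1-based index, also the matrix row/column order), `name`,
#'   `hemisphere` (`"L"`, `"R"` or `"medial"`), `lobe`, `is_cortical`,
#'   `homotopic_partner` (`roi_id` of the mirror region or `NA`) and
#'   `system_tags` (semicolon-separated subset of `SM;VIS;thalamus`).
#' @examples
#' atlas <- default_atlas()
#' table(atlas$lobe)
#' @export
default_atlas <- function() {
  cort <- .dkt_cortical
  rois <- data.frame(
    name = c(paste0(cort$base, "-L"), paste0(cort$base, "-R"),
             "brainstem",
             paste0(rep(.subcortical_bases, each = 2), c("-L", "-R"))),
    hemisphere = c(rep("L", 31), rep("R", 31), "medial",
                   rep(c("L", "R"), times = 6)),
    lobe = c(cort$lobe, cort$lobe, rep("subcortical", 13)),
    is_cortical = c(rep(TRUE, 62), rep(FALSE, 13)),
    stringsAsFactors = FALSE
  )
  rois$roi_id <- seq_len(nrow(rois))
  base <- sub("-[LR]$", "", rois$name)
  rois$homotopic_partner <- NA_integer_
  for (i in seq_len(nrow(rois))) {
    if (rois$hemisphere[i] %in% c("L", "R")) {
      j <- which(base == base[i] & rois$hemisphere != rois$hemisphere[i] &
                   rois$hemisphere != "medial")
      if (length(j) == 1L) rois$homotopic_partner[i] <- rois$roi_id[j]
    }
  }
  tags <- character(nrow(rois))
  tags[base %in% .sm_labels]  <- "SM"
  tags[base %in% .vis_labels] <- "VIS"
  tags[base == "thalamus"]    <- "thalamus"
  rois$system_tags <- tags
  rois <- rois[, c("roi_id", "name", "hemisphere", "lobe", "is_cortical",
                   "homotopic_partner", "system_tags")]
  class(rois) <- c("roi_atlas", "data.frame")
  validate_atlas(rois)
}

#' Validate an ROI atlas
#'
#' Checks the structural invariants the pipeline relies on: unique contiguous
#' `roi_id`, legal hemisphere/lobe values, a symmetric homotopy map that only
#' links L/R regions sharing a base name, and no partner for medial regions.
#'
#' @param atlas A data frame with the columns of [default_atlas()].
#' @return The atlas, invisibly classed as `roi_atlas`, or an error.
#' @export
validate_atlas <- function(atlas) {
  req <- c("roi_id", "name", "hemisphere", "lobe", "is_cortical",
           "homotopic_partner", "system_tags")
  miss <- setdiff(req, names(atlas))
  if (length(miss)) {
    stop("invalid atlas: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(atlas)
  if (!identical(as.integer(atlas$roi_id), seq_len(n))) {
    stop("invalid atlas: roi_id must be 1..", n, " in order", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("L", "R", "medial"))) {
    stop("invalid atlas: hemisphere must be L, R or medial", call. = FALSE)
  }
  ok_lobes <- c("frontal", "parietal", "temporal", "occipital", "cingulate",
                "insular", "subcortical")
  if (!all(atlas$lobe %in% ok_lobes)) {
    stop("invalid atlas: unknown lobe value", call. = FALSE)
  }
  hp <- atlas$homotopic_partner
  for (i in seq_len(n)) {
    if (!is.na(hp[i])) {
      j <- hp[i]
      if (j < 1 || j > n || is.na(hp[j]) || hp[j] != i) {
        stop("invalid atlas: homotopic_partner map is not symmetric at roi ",
             atlas$name[i], call. = FALSE)
      }
      if (atlas$hemisphere[i] == "medial" || atlas$hemisphere[j] == "medial") {
        stop("invalid atlas: medial region cannot have a homotopic partner",
             call. = FALSE)
      }
      if (atlas$hemisphere[i] == atlas$hemisphere[j]) {
        stop("invalid atlas: homotopic partners must lie in opposite hemispheres",
             call. = FALSE)
      }
      if (sub("-[LR]$", "", atlas$name[i]) != sub("-[LR]$", "", atlas$name[j])) {
        stop("invalid atlas: homotopic partners must share a base name",
             call. = FALSE)
      }
    }
  }
  if (!inherits(atlas, "roi_atlas")) class(atlas) <- c("roi_atlas", "data.frame")
  invisible(atlas)
}

#' Read / write an atlas CSV
#'
#' The on-disk format is a plain CSV with columns
#' `roi_id,name,hemisphere,lobe,is_cortical,homotopic_partner,system_tags`
#' (semicolon-separated tags, empty string for none). A copy of the default
#' atlas ships with the package under `extdata/atlas_dkt75.csv`.
#'
#' @param path File path.
#' @return `read_atlas()` returns a validated `roi_atlas`.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$homotopic_partner <- suppressWarnings(as.integer(df$homotopic_partner))
  df$is_cortical <- as.logical(df$is_cortical)
  df$system_tags[is.na(df$system_tags)] <- ""
  validate_atlas(df)
  class(df) <- c("roi_atlas", "data.frame")
  df
}

#' @rdname read_atlas
#' @param atlas An `roi_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("ROI atlas: %d regions (%d cortical, %d subcortical)\n",
              nrow(x), sum(x$is_cortical), sum(!x$is_cortical)))
  NextMethod()
}
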