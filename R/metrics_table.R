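# Cohort metric tables: subjects x ROIs x 6 diffusion metrics per group,
# with per-subject PMA-at-scan and GA-at-birth covariates.

#' Construct a cohort metric table
#'
#' @param group Group label, one of `"PT:ses1"`, `"PT:ses2"`, `"FT"` (other
#'   labels are allowed but the standard pipeline uses these three).
#' @param subjects Data frame with columns `subject_id`, `pma_scan_weeks`,
#'   `ga_birth_weeks`.
#' @param values Numeric array `subjects x ROIs x metrics`; third dimension
#'   named with the six diffusion metrics FA, AD, RD, MD, NDI, ODI.
#' @param check_ranges If `TRUE`, warn when raw metric values leave their
#'   nominal physical ranges (FA/NDI/ODI in `[0,1]`, diffusivities positive).
#' @return A list of class `cohort_metrics`.
#' @export
cohort_metrics <- function(group, subjects, values, check_ranges = FALSE) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "pma_scan_weeks", "ga_birth_weeks") %in%
                  names(subjects)),
            is.array(values), length(dim(values)) == 3L,
            dim(values)[1] == nrow(subjects))
  if (is.null(dimnames(values)[[3]])) {
    stopifnot(dim(values)[3] == 6L)
    dimnames(values)[[3]] <- .metric_names
  }
  obj <- structure(list(group = group, subjects = subjects, values = values,
                        metrics = dimnames(values)[[3]]),
                   class = "cohort_metrics")
  validate_cohort_metrics(obj, check_ranges = check_ranges)
  obj
}

#' @rdname cohort_metrics
#' @param table A `cohort_metrics` object.
#' @export
validate_cohort_metrics <- function(table, check_ranges = TRUE) {
  stopifnot(inherits(table, "cohort_metrics"))
  if (anyNA(table$values) || any(!is.finite(table$values))) {
    stop("metric table contains missing or non-finite values", call. = FALSE)
  }
  if (nrow(table$subjects) < 3L) {
    stop("metric table needs >= 3 subjects", call. = FALSE)
  }
  if (check_ranges) {
    v <- table$values
    m <- table$metrics
    unitless <- intersect(c("FA", "NDI", "ODI"), m)
    for (mm in unitless) {
      if (any(v[, , mm] < 0 | v[, , mm] > 1)) {
        warning(mm, " values outside [0, 1]", call. = FALSE)
      }
    }
    diffs <- intersect(c("AD", "RD", "MD"), m)
    for (mm in diffs) {
      if (any(v[, , mm] <= 0)) {
        warning(mm, " values not strictly positive", call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' @export
print.cohort_metrics <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("cohort metric table [%s]: %d subjects x %d ROIs x %d metrics\n",
              x$group, d[1], d[2], d[3]))
  invisible(x)
}

#' Read / write cohort metric tables as long-format CSV
#'
#' Columns: `group,subject_id,pma_scan_weeks,ga_birth_weeks,roi_name,metric,value`.
#' One file may hold several groups; `read_metric_tables()` returns a named
#' list of `cohort_metrics`, ROI order taken from the atlas.
#'
#' @param tables Named list of `cohort_metrics` (or a single one).
#' @param path CSV path.
#' @param atlas `roi_atlas` giving ROI names and order.
#' @return `read_metric_tables()`: named list of `cohort_metrics`.
#' @export
write_metric_tables <- function(tables, path, atlas = default_atlas()) {
  if (inherits(tables, "cohort_metrics")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    d <- dim(tb$values)
    grid <- expand.grid(s = seq_len(d[1]), r = seq_len(d[2]),
                        m = seq_len(d[3]))
    data.frame(
      group = tb$group,
      subject_id = tb$subjects$subject_id[grid$s],
      pma_scan_weeks = tb$subjects$pma_scan_weeks[grid$s],
      ga_birth_weeks = tb$subjects$ga_birth_weeks[grid$s],
      roi_name = atlas$name[grid$r],
      metric = tb$metrics[grid$m],
      value = tb$values[cbind(grid$s, grid$r, grid$m)],
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_tables
#' @export
read_metric_tables <- function(path, atlas = default_atlas()) {
  if (!file.exists(path)) stop("metric table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(df$group)) {
    dg <- df[df$group == g, ]
    subs <- unique(dg[, c("subject_id", "pma_scan_weeks", "ga_birth_weeks")])
    rownames(subs) <- NULL
    mets <- intersect(.metric_names, unique(dg$metric))
    v <- array(NA_real_,
               dim = c(nrow(subs), nrow(atlas), length(mets)),
               dimnames = list(subs$subject_id, atlas$name, mets))
    v[cbind(match(dg$subject_id, subs$subject_id),
            match(dg$roi_name, atlas$name),
            match(dg$metric, mets))] <- dg$value
    out[[g]] <- cohort_metrics(group = g, subjects = subs, values = v)
  }
  out
}
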