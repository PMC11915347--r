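# Full-pipeline orchestration: cohort -> MC/FC -> group comparisons -> MC-FC
# coupling -> longitudinal delta matrices and the three co-evolution
# hypotheses -> thresholded edge lists -> networks and MI overlap summaries.
# Deterministic given (config, seed): every stage draws from a named
# substream derived from the master seed.

#' Assemble a pipeline run configuration
#'
#' Collects the synthetic-cohort configuration (or pre-built inputs) and every
#' numeric analysis option, each with its standard default: 0.1 Hz low-pass
#' cutoff, 50-sample trim, 95% CI multiplier 1.96 with SEM scaling and
#' Jaccard overlap for dFC, 25% edge threshold, 1000 slope permutations, 100
#' MI shuffles, cluster sizes 2..75, absolute values for MC (signed FC), no
#' Fisher z before FC averaging.
#'
#' @param synthetic A [synthetic_config()] describing the cohort to simulate,
#'   or `NULL` when `cohort` is supplied.
#' @param cohort Optionally a pre-generated [generate_cohort()] result.
#' @param atlas The `roi_atlas` (default [default_atlas()]).
#' @param seed Master seed for the run.
#' @param out_dir Output directory, or `NULL` to keep results in memory only.
#' @param cutoff_hz,trim FC preprocessing options.
#' @param z_mult,use_sem,overlap_method dFC confidence-interval options.
#' @param fraction Top-edge threshold fraction.
#' @param n_perm_slope,n_perm_mi Permutation counts.
#' @param k_range Cluster sizes for the MI scans.
#' @param mc_use_abs,fc_use_abs Use absolute values when converting each
#'   modality to distances.
#' @param fisher_z Average subject FC on the arctanh scale.
#' @param residualize Apply metric confound residualization (default `TRUE`;
#'   disabling is for sensitivity analyses only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), cohort = NULL,
                       atlas = default_atlas(), seed = 1L, out_dir = NULL,
                       cutoff_hz = 0.1, trim = 50L, z_mult = 1.96,
                       use_sem = TRUE, overlap_method = "jaccard",
                       fraction = 0.25, n_perm_slope = 1000L,
                       n_perm_mi = 100L, k_range = 2:75,
                       mc_use_abs = TRUE, fc_use_abs = FALSE,
                       fisher_z = FALSE, residualize = TRUE) {
  structure(list(
    synthetic = synthetic, cohort = cohort, atlas = atlas,
    seed = as.integer(seed), out_dir = out_dir,
    options = list(cutoff_hz = cutoff_hz, trim = as.integer(trim),
                   z_mult = z_mult, use_sem = use_sem,
                   overlap_method = overlap_method, fraction = fraction,
                   n_perm_slope = as.integer(n_perm_slope),
                   n_perm_mi = as.integer(n_perm_mi),
                   k_range = as.integer(k_range),
                   mc_use_abs = mc_use_abs, fc_use_abs = fc_use_abs,
                   fisher_z = fisher_z, residualize = residualize)
  ), class = "run_config")
}

.stage_seed <- function(master, stage) {
  as.integer(derive_seed(master, stage) %% 2147483647)
}

.clip_unit <- function(m) {
  v <- as_plain_matrix(m)
  pmin(pmax(v, -1), 1)
}

#' Run the full co-development analysis
#'
#' Executes every stage on a synthetic (or supplied) cohort: group MC and FC
#' matrices; between-group edge-distribution comparisons (Shapiro-Wilk on
#' each group, paired Wilcoxon, robust between-group regressions); MC-FC
#' robust regressions per connection subset and group; dMC/dFC; the six
#' co-evolution regressions (both directions of dFC~dMC, plus dFC against
#' session-1 MC, session-2 FC against dMC, dMC against session-1 FC, and
#' session-2 MC against dFC) with permutation p-values, BH correction and
#' pairwise slope Z-comparisons; 25%-thresholded edge lists (common and
#' adapted thresholds); and Ward dendrograms with MI-overlap comparisons
#' within modality (between groups), between modalities (within group) and
#' for the longitudinal matrices.
#'
#' When `config$out_dir` is set, matrices (TSV), tables (CSV), edge lists,
#' dendrograms, a machine-readable `summary.json` and a `run_log.txt` with
#' all resolved options and stage seeds are written there.
#'
#' @param config A [run_config()].
#' @return A list of class `neoconn_results` with elements `mc`, `fc`,
#'   `fc_stacks`, `group_comparisons`, `mcfc_subsets`, `delta`,
#'   `coevolution`, `thresholds`, `networks`, `mi`, `summary`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  opt <- config$options
  atlas <- config$atlas
  seed <- config$seed
  groups <- c("PT:ses1", "PT:ses2", "FT")

  cohort <- config$cohort %||%
    generate_cohort(config$synthetic, seed = .stage_seed(seed, "cohort"))

  # --- MC -------------------------------------------------------------------
  mc <- list(); mc_abs <- list()
  for (g in groups) {
    tb <- cohort$metrics[[g]]
    if (opt$residualize) tb <- residualize_metrics(tb)
    tb <- minmax_scale(tb)
    mc[[g]] <- build_mc(tb, atlas = atlas)
    mc_abs[[g]] <- absolute_mc(mc[[g]])
  }

  # --- FC -------------------------------------------------------------------
  fc_stacks <- list(); fc <- list()
  for (g in groups) {
    pre <- preprocess_timeseries(cohort$timeseries[[g]],
                                 cutoff_hz = opt$cutoff_hz, trim = opt$trim)
    fc_stacks[[g]] <- subject_fc_stack(pre, roi_names = atlas$name)
    fc[[g]] <- group_fc(fc_stacks[[g]], group = g, fisher_z = opt$fisher_z)
  }

  labeling <- label_edges(atlas)

  # --- between-group edge-distribution comparisons --------------------------
  pairs <- list(c("PT:ses2", "FT"), c("PT:ses1", "PT:ses2"))
  group_comparisons <- list()
  for (modality in c("MC", "FC")) {
    mats <- if (modality == "MC") mc_abs else fc
    for (pr in pairs) {
      va <- upper_triangle(as_plain_matrix(mats[[pr[1]]]))
      vb <- upper_triangle(as_plain_matrix(mats[[pr[2]]]))
      key <- sprintf("%s_%s_vs_%s", modality, pr[1], pr[2])
      sw <- list(a = shapiro_normality(va), b = shapiro_normality(vb))
      wt <- paired_wilcoxon(va, vb)
      reg <- huber_fit(va, vb)
      group_comparisons[[key]] <- list(
        modality = modality, groups = pr,
        shapiro_p = c(sw$a$p_value, sw$b$p_value),
        wilcoxon_w = wt$statistic, wilcoxon_p = wt$p_value,
        direction = wt$direction,
        slope = reg$slope, intercept = reg$intercept, slope_se = reg$slope_se)
    }
  }

  # --- MC-FC coupling per subset and group ----------------------------------
  mcfc_subsets <- list()
  for (g in groups) {
    mcfc_subsets[[g]] <- subset_regression_report(
      mc_abs[[g]], fc[[g]], labeling,
      n_perm = opt$n_perm_slope,
      seed = .stage_seed(seed, paste0("mcfc_", g)))
  }

  # --- longitudinal change --------------------------------------------------
  dmc <- delta_mc(mc[["PT:ses1"]], mc[["PT:ses2"]])
  dfc <- delta_fc(fc_stacks[["PT:ses1"]], fc_stacks[["PT:ses2"]],
                  z_mult = opt$z_mult, use_sem = opt$use_sem,
                  method = opt$overlap_method)

  coev <- coevolution_regressions(
    dmc = dmc, dfc = dfc,
    mc_ses1 = mc_abs[["PT:ses1"]], mc_ses2 = mc_abs[["PT:ses2"]],
    fc_ses1 = fc[["PT:ses1"]], fc_ses2 = fc[["PT:ses2"]],
    n_perm = opt$n_perm_slope, seed = .stage_seed(seed, "coevolution"))

  # --- thresholded edge lists -----------------------------------------------
  thresholds <- list(
    MC_common = threshold_top_fraction(mc_abs, fraction = opt$fraction,
                                       mode = "common"),
    MC_adapted = threshold_top_fraction(mc_abs, fraction = opt$fraction,
                                        mode = "adapted"),
    FC_common = threshold_top_fraction(fc, fraction = opt$fraction,
                                       mode = "common"),
    FC_adapted = threshold_top_fraction(fc, fraction = opt$fraction,
                                        mode = "adapted"))

  # --- networks and MI overlap ----------------------------------------------
  dendro <- list()
  for (g in groups) {
    dendro[[paste0("MC_", g)]] <- ward_dendrogram(
      corr_to_distance(mc[[g]], use_abs = opt$mc_use_abs))
    dendro[[paste0("FC_", g)]] <- ward_dendrogram(
      corr_to_distance(fc[[g]], use_abs = opt$fc_use_abs))
  }
  dendro[["dMC"]] <- ward_dendrogram(corr_to_distance(.clip_unit(dmc)))
  dendro[["dFC"]] <- ward_dendrogram(corr_to_distance(.clip_unit(dfc)))

  mi_pairs <- list(
    c("MC_PT:ses1", "MC_PT:ses2"), c("MC_FT", "MC_PT:ses2"),
    c("FC_PT:ses1", "FC_PT:ses2"), c("FC_FT", "FC_PT:ses2"),
    c("MC_PT:ses1", "FC_PT:ses1"), c("MC_PT:ses2", "FC_PT:ses2"),
    c("MC_FT", "FC_FT"),
    c("dMC", "dFC"),
    c("dMC", "FC_PT:ses1"), c("dMC", "FC_PT:ses2"),
    c("dFC", "MC_PT:ses1"), c("dFC", "MC_PT:ses2"))
  mi <- list()
  for (i in seq_along(mi_pairs)) {
    pr <- mi_pairs[[i]]
    key <- paste(pr, collapse = "__vs__")
    mi[[key]] <- mi_comparison(
      dendro[[pr[1]]], dendro[[pr[2]]], k_range = opt$k_range,
      n_perm = opt$n_perm_mi,
      seed = .stage_seed(seed, paste0("mi_", i)), labels = pr)
  }

  summary <- list(
    seed = seed,
    options = opt[setdiff(names(opt), "k_range")],
    k_range = range(opt$k_range),
    n_subjects = cohort$config$n_subjects,
    n_rois = cohort$config$n_rois,
    group_comparisons = group_comparisons,
    mcfc_subsets = lapply(mcfc_subsets, function(df) {
      df[, c("subset", "n_edges", "slope", "slope_se", "perm_p", "perm_p_bh")]
    }),
    coevolution = coev$table[, c("name", "hypothesis", "slope", "slope_se",
                                 "perm_p", "perm_p_bh")],
    thresholds = lapply(thresholds, function(t) as.list(t$thresholds)),
    mi = lapply(mi, function(cmp) {
      list(mean_significant = cmp$mean_significant,
           sd_significant = cmp$sd_significant,
           n_significant = cmp$n_significant)
    })
  )

  res <- structure(list(
    atlas = atlas, cohort = cohort, mc = mc, mc_abs = mc_abs, fc = fc,
    fc_stacks = fc_stacks, labeling = labeling,
    group_comparisons = group_comparisons, mcfc_subsets = mcfc_subsets,
    delta = list(dMC = dmc, dFC = dfc), coevolution = coev,
    thresholds = thresholds, networks = dendro, mi = mi,
    summary = summary, config = config
  ), class = "neoconn_results")

  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

#' The six co-evolution ("hypothesis") regressions
#'
#' Tests the three directionality hypotheses about MC-FC co-development with
#' Huber regressions on upper-triangle edge vectors: (1) co-evolution —
#' `dFC ~ dMC` and `dMC ~ dFC`; (2) MC drives FC — `dFC ~ MC(ses1)` and
#' `FC(ses2) ~ dMC`; (3) FC drives MC — `dMC ~ FC(ses1)` and
#' `MC(ses2) ~ dFC`. Permutation p-values are BH-adjusted across the family
#' of six, and all slope pairs are compared by Z-score.
#'
#' @param dmc,dfc Longitudinal change matrices.
#' @param mc_ses1,mc_ses2 Absolute group MC at the two sessions.
#' @param fc_ses1,fc_ses2 Group FC at the two sessions.
#' @param n_perm Permutations per regression.
#' @param seed Optional master seed.
#' @return List with `table` (one row per regression), `fits` and
#'   `slope_comparisons` (pairwise Z table).
#' @export
coevolution_regressions <- function(dmc, dfc, mc_ses1, mc_ses2,
                                    fc_ses1, fc_ses2, n_perm = 1000L,
                                    seed = NULL) {
  v <- function(m) upper_triangle(as_plain_matrix(m))
  specs <- list(
    list(name = "dFC~dMC", hypothesis = "co-evolution",
         x = v(dmc), y = v(dfc)),
    list(name = "dMC~dFC", hypothesis = "co-evolution",
         x = v(dfc), y = v(dmc)),
    list(name = "dFC~MC_ses1", hypothesis = "MC-drives-FC",
         x = v(mc_ses1), y = v(dfc)),
    list(name = "FC_ses2~dMC", hypothesis = "MC-drives-FC",
         x = v(dmc), y = v(fc_ses2)),
    list(name = "dMC~FC_ses1", hypothesis = "FC-drives-MC",
         x = v(fc_ses1), y = v(dmc)),
    list(name = "MC_ses2~dFC", hypothesis = "FC-drives-MC",
         x = v(dfc), y = v(mc_ses2)))
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    sub_seed <- if (is.null(seed)) NULL else {
      as.integer(derive_seed(seed, "coev", i) %% 2147483647)
    }
    fits[[i]] <- permute_slope_p(s$x, s$y, n_perm = n_perm, seed = sub_seed)
  }
  tab <- do.call(rbind, lapply(seq_along(specs), function(i) {
    data.frame(name = specs[[i]]$name, hypothesis = specs[[i]]$hypothesis,
               slope = fits[[i]]$slope, intercept = fits[[i]]$intercept,
               slope_se = fits[[i]]$slope_se,
               perm_p = fits[[i]]$permutation_p,
               n_perm = fits[[i]]$n_permutations,
               stringsAsFactors = FALSE)
  }))
  tab$perm_p_bh <- bh_fdr(tab$perm_p)
  cmp <- utils::combn(seq_along(fits), 2)
  zt <- do.call(rbind, lapply(seq_len(ncol(cmp)), function(j) {
    i1 <- cmp[1, j]; i2 <- cmp[2, j]
    z <- compare_slopes_z(fits[[i1]], fits[[i2]])
    data.frame(fit_1 = specs[[i1]]$name, fit_2 = specs[[i2]]$name,
               z = z$z, p_value = z$p_value, stringsAsFactors = FALSE)
  }))
  names(fits) <- tab$name
  list(table = tab, fits = fits, slope_comparisons = zt)
}

#' Write a results bundle to disk
#'
#' Emits TSV matrices, CSV tables, circos edge lists, dendrogram merge
#' tables, `summary.json` (deterministic: no timestamps) and `run_log.txt`
#' (resolved options, seeds and a timestamp).
#'
#' @param res A `neoconn_results`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)
  for (g in names(res$mc)) {
    write_matrix_tsv(res$mc[[g]], file.path(dir, sprintf("MC_%s.tsv", safe(g))))
    write_matrix_tsv(res$fc[[g]], file.path(dir, sprintf("FC_%s.tsv", safe(g))))
  }
  write_matrix_tsv(res$delta$dMC, file.path(dir, "dMC.tsv"))
  write_matrix_tsv(res$delta$dFC, file.path(dir, "dFC.tsv"))
  for (g in names(res$mcfc_subsets)) {
    utils::write.csv(res$mcfc_subsets[[g]],
                     file.path(dir, sprintf("mcfc_subsets_%s.csv", safe(g))),
                     row.names = FALSE)
  }
  utils::write.csv(res$coevolution$table,
                   file.path(dir, "coevolution_regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$coevolution$slope_comparisons,
                   file.path(dir, "coevolution_slope_z.csv"),
                   row.names = FALSE)
  for (nm in names(res$thresholds)) {
    thr <- res$thresholds[[nm]]
    mats <- if (startsWith(nm, "MC")) res$mc_abs else res$fc
    for (g in names(thr$masks)) {
      export_circos_edges(
        mats[[g]], res$atlas, thr$masks[[g]],
        file.path(dir, sprintf("edges_%s_%s.csv", safe(nm), safe(g))))
    }
  }
  for (nm in names(res$networks)) {
    write_dendrogram_csv(res$networks[[nm]],
                         file.path(dir, sprintf("dendrogram_%s.csv", safe(nm))))
  }
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_lines <- c(
    sprintf("neoconn run log - %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("master seed: %d", res$config$seed),
    "resolved options:",
    vapply(names(res$config$options), function(o) {
      sprintf("  %s = %s", o,
              paste(format(res$config$options[[o]]), collapse = ","))
    }, character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.neoconn_results <- function(x, ...) {
  cat("neoconn pipeline results\n")
  cat(sprintf("  groups: %s\n", paste(names(x$mc), collapse = ", ")))
  cat(sprintf("  co-evolution regressions: %d (min BH p = %.4g)\n",
              nrow(x$coevolution$table), min(x$coevolution$table$perm_p_bh)))
  cat(sprintf("  MI comparisons: %d\n", length(x$mi)))
  invisible(x)
}
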