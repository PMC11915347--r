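# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: three infant groups
# (a preterm group scanned twice, PT:ses1 and PT:ses2, and a term-born group
# FT, 45 subjects each by default), regional diffusion-metric tables with
# planted block covariance (one latent factor per block), linear PMA/GA
# confound effects and a per-subject global offset, and ROI BOLD time series
# with planted within-block correlation. Ground truth (block assignments,
# betas, covariate draws) is returned alongside the data.

.metric_names <- c("FA", "AD", "RD", "MD", "NDI", "ODI")
# affine map from the standardized latent scale onto plausible physical units;
# Pearson-based statistics downstream are invariant to it
.metric_center <- c(FA = 0.30, AD = 1.5e-3, RD = 1.1e-3, MD = 1.2e-3,
                    NDI = 0.30, ODI = 0.40)
.metric_unit <- c(FA = 0.04, AD = 5e-5, RD = 5e-5, MD = 5e-5,
                  NDI = 0.04, ODI = 0.04)

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: 45 subjects per group, 75
#' ROIs, preterm PMA-at-scan ranges of 28.3–36.9 weeks (session 1) and
#' 38.4–44.9 weeks (session 2, term-equivalent age, shared by the term-born
#' group), GA-at-birth ranges of 25.6–36.0 weeks (preterm) and 37.4–42.3
#' weeks (term), 300 BOLD samples at a 0.392 s sampling interval, and five
#' equal planted blocks shared between modalities.
#'
#' @param n_subjects Subjects per group (>= 3).
#' @param n_rois Number of regions.
#' @param mc_blocks Integer block assignment per ROI for the metric (MC) side.
#' @param fc_blocks Block assignment for the time-series (FC) side; defaults
#'   to `mc_blocks` (shared network structure).
#' @param mc_loading Within-block latent-factor loading in `[0, 1)`, scalar or
#'   one value per block.
#' @param mc_loading_ses2 Loadings used for PT:ses2 (defaults to `mc_loading`;
#'   set per-block values to plant longitudinal MC change).
#' @param fc_rho Planted within-block time-series correlation in `[0, 1)`,
#'   scalar or per block.
#' @param fc_rho_ses2 PT:ses2 values (defaults to `fc_rho`; per-block values
#'   plant longitudinal FC change).
#' @param beta_pma,beta_ga Linear confound coefficients per metric (latent
#'   units per week), recycled to 6 metrics.
#' @param block_mean_sd SD of fixed per-(block, metric) mean offsets.
#' @param global_scale_sd SD of the per-subject global offset shared by all
#'   ROIs and metrics of a scan.
#' @param noise_sd Residual SD per metric value.
#' @param ts_length Number of BOLD samples T (> 100).
#' @param sampling_interval Sampling interval in seconds.
#' @param pma_range_ses1,pma_range_ses2,pma_range_ft PMA-at-scan ranges
#'   (weeks).
#' @param ga_range_pt,ga_range_ft GA-at-birth ranges (weeks).
#' @param seed Default seed used by [generate_cohort()] when none is passed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 45L,
                             n_rois = 75L,
                             mc_blocks = rep(seq_len(5L), length.out = n_rois),
                             fc_blocks = mc_blocks,
                             mc_loading = 0.8,
                             mc_loading_ses2 = NULL,
                             fc_rho = 0.6,
                             fc_rho_ses2 = NULL,
                             beta_pma = 0.02,
                             beta_ga = 0.01,
                             block_mean_sd = 0.2,
                             global_scale_sd = 0.1,
                             noise_sd = 0.1,
                             ts_length = 300L,
                             sampling_interval = 0.392,
                             pma_range_ses1 = c(28.3, 36.9),
                             pma_range_ses2 = c(38.4, 44.9),
                             pma_range_ft = c(38.4, 44.9),
                             ga_range_pt = c(25.6, 36.0),
                             ga_range_ft = c(37.4, 42.3),
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    mc_blocks = as.integer(mc_blocks), fc_blocks = as.integer(fc_blocks),
    mc_loading = mc_loading, mc_loading_ses2 = mc_loading_ses2,
    fc_rho = fc_rho, fc_rho_ses2 = fc_rho_ses2,
    beta_pma = rep_len(beta_pma, 6L), beta_ga = rep_len(beta_ga, 6L),
    block_mean_sd = block_mean_sd, global_scale_sd = global_scale_sd,
    noise_sd = noise_sd,
    ts_length = as.integer(ts_length), sampling_interval = sampling_interval,
    pma_range_ses1 = pma_range_ses1, pma_range_ses2 = pma_range_ses2,
    pma_range_ft = pma_range_ft,
    ga_range_pt = ga_range_pt, ga_range_ft = ga_range_ft,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param config Object to validate.
#' @export
validate_synthetic_config <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_subjects < 3L) {
    stop("n_subjects must be >= 3 (correlations undefined below that)",
         call. = FALSE)
  }
  if (length(config$mc_blocks) != config$n_rois ||
      length(config$fc_blocks) != config$n_rois) {
    stop("block assignments must have one entry per ROI", call. = FALSE)
  }
  loads <- c(config$mc_loading, config$mc_loading_ses2,
             config$fc_rho, config$fc_rho_ses2)
  if (any(loads < 0 | loads >= 1)) {
    stop("loadings and fc_rho values must lie in [0, 1)", call. = FALSE)
  }
  if (config$noise_sd <= 0 || config$global_scale_sd < 0 ||
      config$block_mean_sd < 0) {
    stop("noise_sd must be > 0 and SDs must be >= 0", call. = FALSE)
  }
  if (config$ts_length <= 100L) stop("ts_length must be > 100", call. = FALSE)
  if (config$sampling_interval <= 0) {
    stop("sampling_interval must be positive", call. = FALSE)
  }
  invisible(config)
}

.per_block <- function(x, n_blocks) {
  if (is.null(x)) return(NULL)
  rep_len(x, n_blocks)
}

#' Generate a synthetic three-group cohort
#'
#' Draws covariates, regional metric tables and ROI time series for the three
#' groups. The metric model for subject `s`, ROI `r`, metric `m` is
#' `x = mu_m(block(r)) + beta_pma_m (PMA_s - 40) + beta_ga_m (GA_s - 35) +
#' g_s + lambda_b f_{s,b} + noise`, with one latent factor `f` per block per
#' subject, then an affine map onto the metric's physical scale. Time series
#' are `sqrt(rho_b) * latent_block + sqrt(1 - rho_b) * noise`, white Gaussian.
#' Preterm subjects keep their identity (same subject ids and GA) across the
#' two sessions; PMA at the two sessions is drawn independently. PMA at scan
#' is forced to be at least 0.1 weeks after GA at birth.
#'
#' Three named RNG substreams (covariates, metrics, timeseries) are derived
#' from the seed so that the draws of one component do not shift another's.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   `(config, seed)` gives bit-identical output.
#' @return A list of class `synthetic_cohort` with elements `metrics` (named
#'   list of `cohort_metrics`, one per group), `timeseries` (named list of
#'   per-group time-series sets, see [timeseries_set()]), `truth` (planted
#'   block assignments, betas, covariates and per-session loadings) and
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  validate_synthetic_config(config)
  n <- config$n_subjects
  R <- config$n_rois
  nb_mc <- max(config$mc_blocks)
  nb_fc <- max(config$fc_blocks)
  groups <- c("PT:ses1", "PT:ses2", "FT")

  # --- covariates -----------------------------------------------------------
  covs <- with_seed(derive_seed(seed, "covariates"), {
    draw_pma <- function(ga, range) {
      lo <- pmax(range[1], ga + 0.1)
      stats::runif(length(ga), lo, range[2])
    }
    ga_pt <- stats::runif(n, config$ga_range_pt[1], config$ga_range_pt[2])
    ga_ft <- stats::runif(n, config$ga_range_ft[1], config$ga_range_ft[2])
    list(
      "PT:ses1" = data.frame(
        subject_id = sprintf("PT%02d", seq_len(n)),
        pma_scan_weeks = draw_pma(ga_pt, config$pma_range_ses1),
        ga_birth_weeks = ga_pt),
      "PT:ses2" = data.frame(
        subject_id = sprintf("PT%02d", seq_len(n)),
        pma_scan_weeks = draw_pma(ga_pt, config$pma_range_ses2),
        ga_birth_weeks = ga_pt),
      "FT" = data.frame(
        subject_id = sprintf("FT%02d", seq_len(n)),
        pma_scan_weeks = draw_pma(ga_ft, config$pma_range_ft),
        ga_birth_weeks = ga_ft)
    )
  })

  load_ses1 <- .per_block(config$mc_loading, nb_mc)
  load_ses2 <- .per_block(config$mc_loading_ses2, nb_mc) %||% load_ses1
  rho_ses1 <- .per_block(config$fc_rho, nb_fc)
  rho_ses2 <- .per_block(config$fc_rho_ses2, nb_fc) %||% rho_ses1
  mc_loadings <- list("PT:ses1" = load_ses1, "PT:ses2" = load_ses2,
                      "FT" = load_ses1)
  fc_rhos <- list("PT:ses1" = rho_ses1, "PT:ses2" = rho_ses2,
                  "FT" = rho_ses1)

  # --- metrics --------------------------------------------------------------
  metrics <- with_seed(derive_seed(seed, "metrics"), {
    mu <- matrix(stats::rnorm(nb_mc * 6L, 0, config$block_mean_sd), nb_mc, 6L,
                 dimnames = list(NULL, .metric_names))
    out <- list()
    for (g in groups) {
      sub <- covs[[g]]
      lam <- mc_loadings[[g]]
      f <- matrix(stats::rnorm(n * nb_mc), n, nb_mc)
      gs <- stats::rnorm(n, 0, config$global_scale_sd)
      vals <- array(NA_real_, dim = c(n, R, 6L),
                    dimnames = list(sub$subject_id, NULL, .metric_names))
      eps <- array(stats::rnorm(n * R * 6L, 0, config$noise_sd),
                   dim = c(n, R, 6L))
      for (m in seq_len(6L)) {
        base <- mu[config$mc_blocks, m]                       # length R
        conf <- config$beta_pma[m] * (sub$pma_scan_weeks - 40) +
          config$beta_ga[m] * (sub$ga_birth_weeks - 35) + gs  # length n
        z <- outer(conf, base, `+`) +
          f[, config$mc_blocks, drop = FALSE] * rep(lam[config$mc_blocks],
                                                    each = n) +
          eps[, , m]
        vals[, , m] <- .metric_center[m] + .metric_unit[m] * z
      }
      out[[g]] <- cohort_metrics(group = g, subjects = sub, values = vals)
    }
    attr(out, "mu") <- mu
    out
  })
  mu <- attr(metrics, "mu")
  attr(metrics, "mu") <- NULL

  # --- time series ----------------------------------------------------------
  timeseries <- with_seed(derive_seed(seed, "timeseries"), {
    len <- config$ts_length
    out <- list()
    for (g in groups) {
      rho <- fc_rhos[[g]]
      series <- vector("list", n)
      for (s in seq_len(n)) {
        lat <- matrix(stats::rnorm(nb_fc * len), nb_fc, len)
        noise <- matrix(stats::rnorm(R * len), R, len)
        rb <- rho[config$fc_blocks]
        y <- sqrt(rb) * lat[config$fc_blocks, , drop = FALSE] +
          sqrt(1 - rb) * noise
        series[[s]] <- y
      }
      out[[g]] <- timeseries_set(series,
                                 subject_ids = covs[[g]]$subject_id,
                                 group = g,
                                 sampling_interval = config$sampling_interval)
    }
    out
  })

  truth <- list(
    mc_blocks = config$mc_blocks, fc_blocks = config$fc_blocks,
    block_means = mu,
    beta_pma = config$beta_pma, beta_ga = config$beta_ga,
    covariates = covs,
    mc_loadings = mc_loadings, fc_rhos = fc_rhos
  )
  structure(list(metrics = metrics, timeseries = timeseries, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d groups x %d subjects, %d ROIs, T = %d (seed %d)\n",
    length(x$metrics), x$config$n_subjects, x$config$n_rois,
    x$config$ts_length, x$seed))
  invisible(x)
}
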