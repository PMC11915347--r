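# Shared fixtures: small cohorts built in code, cached per test run.

atlas75 <- default_atlas()

# small-but-structured cohort used by several unit tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_subjects = 15L, ts_length = 150L)
      cache <<- generate_cohort(cfg, seed = 101)
    }
    cache
  }
})

# build a group MC matrix through the standard chain
mc_from <- function(table, atlas = atlas75, residualize = TRUE) {
  if (residualize) table <- residualize_metrics(table)
  build_mc(minmax_scale(table), atlas = atlas)
}

# mean within-block minus mean between-block |MC| over off-diagonal edges
block_contrast <- function(mc, blocks) {
  m <- abs(unclass(mc))
  same <- outer(blocks, blocks, `==`)
  ut <- upper.tri(m)
  mean(m[ut & same]) - mean(m[ut & !same])
}
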