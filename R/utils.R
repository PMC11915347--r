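# internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a deterministic 31-bit sub-seed from a master seed and a stage name
#'
#' Stage streams are independent of one another so that changing the number of
#' draws consumed by one stage never perturbs another (each stage re-seeds from
#' its own derived seed).
#' @noRd
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.double(master) %% 2147483647) * 48271 + h * 7919 + as.double(index) * 104729) %%
    2147483629
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
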