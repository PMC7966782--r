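# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Saves and restores `.Random.seed` so that package internals never disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic per-item substream seed derivation; prefix-stable so adding
# items to a cohort never perturbs earlier items. Kept below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(index) * 9973) %%
               2147483629) + 1L
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
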