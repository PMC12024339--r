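## Reproducible child streams: one root seed, per-operation streams derived
## from fixed string labels, so generating one table never perturbs another.

MOD31 <- 2147483647 # 2^31 - 1; keeps every derived seed a valid R integer

#' Derive a child seed from a root seed and a stream label
#'
#' Hashes `label` (polynomial rolling hash, modulo 2^31 - 1) and folds it
#' into `seed`. The same (seed, label) pair always yields the same child
#' seed; different labels give effectively independent streams.
#'
#' @param seed integer root seed.
#' @param label character scalar naming the stream (e.g. `"sites"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label),
            length(label) == 1)
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% MOD31
  as.integer((abs(seed) + h) %% MOD31)
}

## Run `expr` under set.seed(child_seed(seed, label)), restoring the caller's
## RNG state afterwards so generation order cannot leak between operations.
with_stream <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(child_seed(seed, label))
  expr
}
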