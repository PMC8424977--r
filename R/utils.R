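# Internal helpers shared across the package.

# Evaluate `expr` with the global RNG temporarily seeded to `seed`,
# restoring the caller's RNG state afterwards. `seed = NULL` evaluates
# `expr` on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible child seed
#'
#' Mixes a master seed with one or more integer indices (e.g. setting
#' number, dataset number, pair number) through a multiplicative
#' congruential step, so that every randomized unit of a larger run has
#' its own deterministic seed below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the unit of work.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[i]) + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
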