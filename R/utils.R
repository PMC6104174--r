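#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the caller's RNG state, so seeded helpers never perturb the
#' surrounding random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream-specific seed from a top-level seed
#'
#' Mixes a top-level seed with one or more stream keys (stage codes,
#' individual indices, ...) into a deterministic 31-bit seed, so that every
#' random draw in the pipeline is reproducible from a single integer.
#'
#' @param seed Top-level integer seed.
#' @param ... Additional integer keys.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- as.numeric(c(seed, ...))
  m <- 2147483647
  x <- 0
  for (k in key) x <- (x * 69069 + (k %% m) + 1) %% m
  as.integer(x)
}

# column variances without forming an apply() loop; unbiased (n - 1) divisor
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows to compute column variances")
  mu <- colMeans(x)
  (colSums(x * x) - n * mu * mu) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
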