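#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm lm.fit coef pf pt sd var median optim quantile
#'   rnorm runif anova aov AIC logLik setNames complete.cases
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

tl_stop <- function(...) stop(sprintf(...), call. = FALSE)

tl_assert <- function(cond, ...) if (!isTRUE(cond)) tl_stop(...)

# polynomial rolling hash of a serialized R object; cheap deterministic
# fingerprint used to stamp outputs so reruns with the same config are
# recognizable (not cryptographic)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # drop serialization header (R version specific bytes)
  raw <- as.integer(raw[-seq_len(14L)])
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}
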