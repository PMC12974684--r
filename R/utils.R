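#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

## Clip a probability-like vector into [eps, 1 - eps].
clip_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

## Floor positive denominators at eps, returning the number of clipped entries
## through an attribute so callers can accumulate diagnostics.
floor_at <- function(x, eps) {
  n_clip <- sum(x < eps)
  out <- pmax(x, eps)
  attr(out, "n_clipped") <- n_clip
  out
}

## Evaluate a right-continuous nondecreasing step function defined by jump
## times `times` (increasing) and cumulative values `cumvals` at points `t`;
## value is 0 before the first jump, and the last cumulative value beyond the
## final jump time.
step_eval <- function(times, cumvals, t) {
  if (length(times) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, times)
  c(0, cumvals)[idx + 1L]
}

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a bounded sub-seed from a master seed and a stream label, so that
## named draw blocks use separate, reproducible substreams.
sub_seed <- function(seed, stream) {
  streams <- c(covariates = 11L, t0 = 23L, t1 = 37L, c0 = 53L, c1 = 71L,
               treatment = 89L, sampling = 107L, target = 131L, folds = 151L,
               search = 173L, bootstrap = 197L)
  off <- streams[[stream]]
  (as.integer(seed) %% 1000003L) * 1009L %% 2000000011L %/% 1L + off
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
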