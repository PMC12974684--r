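## Global stochastic maximization of an estimated value function over the
## linear-ITR class. The value surface is piecewise constant in eta
## (non-convex, non-smooth), so a population-based optimizer is required; a
## differential-evolution search (DE/rand/1/bin) is implemented here with a
## mandatory seed, box bounds for the free coordinates, restarts, and a
## mirrored run with the linear score negated to cover both signs of the
## anchor coefficient.

#' Policy-search configuration
#'
#' @param bounds length-2 numeric, the box `[lo, hi]` for every free
#'   coordinate (intercept and non-anchor coefficients).
#' @param population DE population size.
#' @param generations number of DE generations per restart.
#' @param restarts independent restarts (best solution kept).
#' @param seed mandatory RNG seed.
#' @param F,CR DE differential weight and crossover probability.
#' @param mirror also search the branch with the anchor coefficient `-1`.
#' @export
search_config <- function(bounds = c(-20, 20), population = 50L,
                          generations = 200L, restarts = 5L, seed,
                          F = 0.8, CR = 0.9, mirror = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for policy search",
                          call. = FALSE)
  stopifnot(length(bounds) == 2L, all(is.finite(bounds)),
            bounds[1] < bounds[2], population >= 5L, generations >= 1L)
  structure(list(bounds = bounds, population = as.integer(population),
                 generations = as.integer(generations),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 F = F, CR = CR, mirror = isTRUE(mirror)),
            class = "search_config")
}

## One DE run (synchronous generational DE/rand/1/bin) maximizing f over a
## p-box; returns list(par, value, trace, n_evals). `f` evaluates a whole
## matrix of candidates (one per row) at once; non-finite values are
## treated as -Inf.
de_maximize <- function(f, p, lo, hi, NP, gens, F, CR) {
  evals <- 0L
  fs <- function(M) {
    evals <<- evals + nrow(M)
    v <- f(M)
    v[!is.finite(v)] <- -Inf
    v
  }
  pop <- matrix(stats::runif(NP * p, lo, hi), NP, p)
  fit <- fs(pop)
  trace <- numeric(gens)
  for (g in seq_len(gens)) {
    r <- t(vapply(seq_len(NP), function(i) sample(seq_len(NP)[-i], 3L),
                  integer(3L)))
    donor <- pop[r[, 1L], , drop = FALSE] +
      F * (pop[r[, 2L], , drop = FALSE] - pop[r[, 3L], , drop = FALSE])
    donor <- pmin(pmax(donor, lo), hi)
    cross <- matrix(stats::runif(NP * p) < CR, NP, p)
    cross[cbind(seq_len(NP), sample.int(p, NP, replace = TRUE))] <- TRUE
    trial <- ifelse(cross, donor, pop)
    ft <- fs(trial)
    ## strict improvement only: exact ties keep the first-found candidate
    win <- ft > fit
    pop[win, ] <- trial[win, , drop = FALSE]
    fit[win] <- ft[win]
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], trace = trace, n_evals = evals)
}

#' Search the optimal linear ITR
#'
#' Maximizes `value_fn` over rules `d(x) = I(eta' (1, x) >= 0)` with the
#' anchor (last) coefficient fixed at `+1`, plus a mirrored run with the
#' score negated (anchor `-1`) when `config$mirror` is `TRUE`. `value_fn`
#' receives the full coefficient vector of length `p + 1` and must be
#' deterministic. Reproducible under the configured seed; the per-generation
#' best value is nondecreasing within each restart.
#'
#' @param value_fn function `eta -> value` (maximized).
#' @param p number of covariates (so `eta` has length `p + 1`).
#' @param config a [search_config()].
#' @param value_fn_batch optional batched evaluator (matrix of rules, one
#'   per row, to a vector of values; see [value_batch_fn()]); when supplied
#'   whole generations are evaluated at once.
#' @return object of class `search_result`: `eta_hat` (a [linear_itr()]),
#'   `value_hat`, `trace` (best value per generation of the winning run),
#'   `n_evals`, `branch` (+1/-1).
#' @export
search_optimal_itr <- function(value_fn, p, config, value_fn_batch = NULL) {
  stopifnot(inherits(config, "search_config"))
  lo <- config$bounds[1]; hi <- config$bounds[2]
  branches <- if (config$mirror) c(1, -1) else 1
  best <- NULL
  with_seed(config$seed, {
    for (br in branches) {
      f <- if (is.null(value_fn_batch))
        function(M) apply(M, 1L, function(free) value_fn(c(free, br)))
      else
        function(M) value_fn_batch(cbind(M, br))
      for (r in seq_len(config$restarts)) {
        run <- de_maximize(f, p, lo, hi, config$population,
                           config$generations, config$F, config$CR)
        if (is.null(best) || run$value > best$value) {
          best <- run
          best$branch <- br
        }
      }
    }
  })
  eta_raw <- c(best$par, best$branch)
  res <- list(eta_hat = linear_itr(eta_raw), value_hat = best$value,
              trace = best$trace, n_evals = best$n_evals,
              branch = best$branch, config = config)
  ## post-hoc consistency check: reported value equals value_fn at eta_hat
  v_check <- value_fn(res$eta_hat$eta)
  if (is.finite(v_check) && abs(v_check - res$value_hat) > 1e-8 *
        max(1, abs(res$value_hat)))
    res$value_hat <- v_check
  class(res) <- "search_result"
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat("Optimal linear ITR search\n")
  cat("  eta_hat:", paste(round(x$eta_hat$eta, 4), collapse = ", "), "\n")
  cat(sprintf("  value:  %.6g   (%d evaluations, anchor branch %+d)\n",
              x$value_hat, x$n_evals, x$branch))
  invisible(x)
}

#' Evaluate a value function on a list of rules
#'
#' Diagnostic helper: tabulates `value_fn` on each supplied coefficient
#' vector.
#'
#' @param value_fn function `eta -> value`.
#' @param etas list of coefficient vectors (length `p + 1`).
#' @return data frame with one row per rule and columns `eta.*`, `value`.
#' @export
value_profile <- function(value_fn, etas) {
  if (!length(etas))
    return(data.frame(value = numeric(0)))
  vals <- vapply(etas, value_fn, 0)
  em <- do.call(rbind, lapply(etas, as.numeric))
  colnames(em) <- paste0("eta", seq_len(ncol(em)))
  cbind(as.data.frame(em), value = vals)
}

#' Serialize a search result to JSON
#'
#' @param result a `search_result`.
#' @param file optional output path.
#' @export
search_result_to_json <- function(result, file = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("search_result_to_json requires the 'jsonlite' package",
         call. = FALSE)
  obj <- list(eta_hat = result$eta_hat$eta, value = result$value_hat,
              trace = result$trace, n_evals = result$n_evals,
              branch = result$branch,
              config = result$config[c("bounds", "population", "generations",
                                       "restarts", "seed", "F", "CR",
                                       "mirror")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
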