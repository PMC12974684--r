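## Nonparametric bootstrap for value estimates: source and target rows are
## resampled with replacement *independently* (the two samples are drawn
## independently in the non-nested design), the full pipeline -- nuisance
## fitting, calibration, value evaluation -- is re-run on each replicate,
## and the standard error is the standard deviation of the replicate
## estimates. By default the rule is held fixed at the original eta-hat and
## only the value evaluation is bootstrapped.

#' Bootstrap a value estimate
#'
#' @param src,tgt source and target samples.
#' @param pipeline function `(src_boot, tgt_boot) -> scalar value`; it must
#'   re-run every estimation step (nuisances, calibration, value) on the
#'   resampled data.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed; replicate index sets are drawn up front so the
#'   replicate vector is bit-identical under the same seed.
#' @param level confidence level for the intervals.
#' @param estimate the original-data point estimate around which the normal
#'   interval is centered; defaults to the mean of the replicates.
#' @return object of class `bootstrap_result`: `replicates`, `se`, normal
#'   interval (`ci_low`, `ci_high`), percentile interval (`pct_low`,
#'   `pct_high`), `B`, `level`, `n_failed`.
#' @export
bootstrap_value <- function(src, tgt = NULL, pipeline, B = 200L, seed,
                            level = 0.95, estimate = NULL) {
  B <- as.integer(B)
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  if (missing(seed)) stop("a seed is mandatory for the bootstrap",
                          call. = FALSE)
  n <- src$n
  m <- if (is.null(tgt)) 0L else tgt$m
  idx <- with_seed(sub_seed(seed, "bootstrap"), {
    list(src = matrix(sample.int(n, n * B, replace = TRUE), B, n),
         tgt = if (m) matrix(sample.int(m, m * B, replace = TRUE), B, m))
  })
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ## a resample is a legitimate bootstrap sample even if degenerate (e.g.
    ## single treatment arm); pipelines that cannot handle it fail and the
    ## replicate is dropped
    ii <- idx$src[b, ]
    sb <- structure(list(X = src$X[ii, , drop = FALSE], A = src$A[ii],
                         U = src$U[ii], Delta = src$Delta[ii], n = n,
                         p = src$p), class = "source_sample")
    tb <- if (m) subset_target(tgt, idx$tgt[b, ]) else NULL
    reps[b] <- tryCatch(
      if (is.null(tb)) pipeline(sb) else pipeline(sb, tb),
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(reps))
  if (failed > 0)
    warning(failed, " bootstrap replicate(s) failed and were dropped")
  if (failed > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed", call. = FALSE)
  ok <- reps[!is.na(reps)]
  se <- stats::sd(ok)
  z <- stats::qnorm(1 - (1 - level) / 2)
  center <- if (is.null(estimate)) mean(ok) else estimate
  qs <- stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(B = B, replicates = reps, se = se,
                 ci_low = center - z * se, ci_high = center + z * se,
                 pct_low = qs[1], pct_high = qs[2],
                 level = level, seed = as.integer(seed), n_failed = failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (B = %d): SE = %.4g\n", x$B, x$se))
  cat(sprintf("  %g%% normal CI     [%.4g, %.4g]\n", 100 * x$level,
              x$ci_low, x$ci_high))
  cat(sprintf("  %g%% percentile CI [%.4g, %.4g]\n", 100 * x$level,
              x$pct_low, x$pct_high))
  if (x$n_failed) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Serialize a bootstrap result
#'
#' @param result a `bootstrap_result`.
#' @param file optional path for the JSON report.
#' @param replicates_csv optional path; when given the replicate vector is
#'   written as CSV.
#' @export
bootstrap_to_json <- function(result, file = NULL, replicates_csv = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("bootstrap_to_json requires the 'jsonlite' package", call. = FALSE)
  if (!is.null(replicates_csv))
    utils::write.csv(data.frame(replicate = seq_len(result$B),
                                value = result$replicates),
                     replicates_csv, row.names = FALSE)
  obj <- result[c("B", "se", "ci_low", "ci_high", "pct_low", "pct_high",
                  "level", "seed", "n_failed")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
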