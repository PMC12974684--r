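#' Construct a source sample
#'
#' Bundles the observed data from the selection-biased source study (for
#' example a randomized trial): covariates, binary treatment, right-censored
#' follow-up time and event indicator. All downstream estimators consume this
#' container.
#'
#' @param X numeric matrix (or data frame of numerics), one row per subject,
#'   one column per covariate. Column names are kept and must match the
#'   target sample's.
#' @param A binary treatment vector (0/1), length `nrow(X)`.
#' @param U nonnegative observed time, `min(T, C)`.
#' @param Delta event indicator, `I(T <= C)` (1 = event, 0 = censored).
#' @return An object of class `source_sample` with elements `X`, `A`, `U`,
#'   `Delta`, `n` and `p`.
#' @examples
#' src <- source_sample(X = cbind(x1 = rnorm(10)), A = rep(0:1, 5),
#'                      U = rexp(10), Delta = rbinom(10, 1, 0.8))
#' src$n
#' @export
source_sample <- function(X, A, U, Delta) {
  X <- as_cov_matrix(X)
  n <- nrow(X)
  A <- as.numeric(A); U <- as.numeric(U); Delta <- as.numeric(Delta)
  if (length(A) != n || length(U) != n || length(Delta) != n)
    stop("X, A, U, Delta must have one entry per subject", call. = FALSE)
  if (anyNA(X) || anyNA(A) || anyNA(U) || anyNA(Delta))
    stop("missing values are not allowed in a source sample", call. = FALSE)
  stopifnot_finite(X, "covariates")
  if (!all(A %in% c(0, 1))) stop("A must be 0/1", call. = FALSE)
  if (!all(Delta %in% c(0, 1))) stop("Delta must be 0/1", call. = FALSE)
  if (any(U < 0)) stop("U must be nonnegative", call. = FALSE)
  if (n < 2) stop("need at least 2 source subjects", call. = FALSE)
  if (length(unique(A)) < 2)
    stop("both treatment arms must be present in the source sample",
         call. = FALSE)
  structure(list(X = X, A = A, U = U, Delta = Delta, n = n, p = ncol(X)),
            class = "source_sample")
}

#' Construct a target sample
#'
#' The target sample carries covariates only, together with known design
#' weights `e(x) = 1 / Pr(I_T = 1 | X = x)`; design-weighted, it represents
#' the target population the treatment rule is intended for.
#'
#' @param X numeric covariate matrix, same columns (and order) as the source
#'   sample.
#' @param e positive design weights, length `nrow(X)`. Under simple random
#'   sampling a constant.
#' @return An object of class `target_sample` with elements `X`, `e`, `m`, `p`.
#' @export
target_sample <- function(X, e) {
  X <- as_cov_matrix(X)
  m <- nrow(X)
  e <- as.numeric(e)
  if (length(e) == 1L) e <- rep(e, m)
  if (length(e) != m) stop("e must have one entry per subject", call. = FALSE)
  if (anyNA(X) || anyNA(e))
    stop("missing values are not allowed in a target sample", call. = FALSE)
  stopifnot_finite(X, "covariates")
  if (!all(is.finite(e)) || any(e <= 0))
    stop("design weights must be positive and finite", call. = FALSE)
  structure(list(X = X, e = e, m = m, p = ncol(X)), class = "target_sample")
}

as_cov_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

check_schema_match <- function(src, tgt) {
  if (src$p != tgt$p)
    stop("source and target samples have different covariate dimensions",
         call. = FALSE)
  if (!identical(colnames(src$X), colnames(tgt$X)))
    stop("source and target covariate columns differ (names/order)",
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a linear individualized treatment rule
#'
#' A linear ITR treats subject `x` iff `eta' (1, x') >= 0`. For
#' identifiability the coefficient of a designated continuous "anchor"
#' covariate -- by convention the *last* covariate column -- is fixed to have
#' absolute value one: the supplied coefficient vector is rescaled by the
#' absolute value of its last entry, preserving its sign. The canonical
#' representation has anchor coefficient `+1`; the `-1` branch arises from the
#' mirrored policy-search run.
#'
#' @param eta numeric vector of length `p + 1`: intercept first, then one
#'   coefficient per covariate, anchor covariate last.
#' @return An object of class `linear_itr` whose `eta` has last entry +/-1.
#' @examples
#' linear_itr(c(4, -2, 6, 2))$eta  # (2, -1, 3, 1)
#' @export
linear_itr <- function(eta) {
  eta <- as.numeric(eta)
  if (!all(is.finite(eta))) stop("eta must be finite", call. = FALSE)
  if (length(eta) < 2) stop("eta must have length >= 2", call. = FALSE)
  a <- eta[length(eta)]
  if (a == 0)
    stop("anchor coefficient is 0: rule cannot be normalized", call. = FALSE)
  structure(list(eta = eta / abs(a), p = length(eta) - 1L),
            class = "linear_itr")
}

#' @rdname linear_itr
#' @export
make_linear_itr <- linear_itr

#' Apply a linear ITR to covariate data
#'
#' @param itr a [linear_itr()].
#' @param X covariate matrix with `itr$p` columns (intercept is prepended
#'   internally).
#' @return 0/1 vector of treatment decisions; a linear score of exactly zero
#'   assigns treatment 1 (the ">=" convention).
#' @export
apply_itr <- function(itr, X) {
  stopifnot(inherits(itr, "linear_itr"))
  X <- as_cov_matrix(X)
  if (ncol(X) != itr$p)
    stop(sprintf("ITR expects %d covariates, got %d", itr$p, ncol(X)),
         call. = FALSE)
  score <- drop(itr$eta[1L] + X %*% itr$eta[-1L])
  as.numeric(score >= 0)
}

#' @export
print.linear_itr <- function(x, ...) {
  cat("Linear treatment rule: treat iff eta' (1, x) >= 0\n")
  print(round(x$eta, 4))
  invisible(x)
}

#' Transformation of the survival time defining the value function
#'
#' The value of a rule `d` is `E[y(T(d))]` for a transformation `y`. Two
#' transformations are supported: the survival indicator `y(T) = I(T >= t)`
#' (value = survival probability at `t`) and the restricted mean survival
#' time `y(T) = min(T, L)` (value = RMST over `[0, L]`).
#'
#' @param t,L positive horizon of the transformation.
#' @param h maximal horizon beyond which `y` is constant; defaults to the
#'   transformation's own horizon.
#' @return An object of class `transform_spec`.
#' @export
surv_prob <- function(t, h = t) {
  stopifnot(t > 0, h >= t)
  structure(list(kind = "survival_indicator", horizon = t, h = h),
            class = "transform_spec")
}

#' @rdname surv_prob
#' @export
rmst <- function(L, h = L) {
  stopifnot(L > 0, h >= L)
  structure(list(kind = "rmst", horizon = L, h = h), class = "transform_spec")
}

#' Read source / target samples from CSV
#'
#' Columns are mapped through a schema: a named list with entries
#' `covariates` (character vector, in order, anchor covariate last),
#' `treatment`, `time`, `event` and, for the target file, `design_weight`.
#' A schema can also be stored as YAML/JSON and loaded with [read_schema()].
#' Missing values are rejected, not imputed.
#'
#' @param file path to a CSV file with a header row.
#' @param schema named list as described above.
#' @return a [source_sample()] / [target_sample()].
#' @export
read_source_sample <- function(file, schema) {
  d <- utils::read.csv(file, check.names = FALSE)
  need <- c(schema$covariates, schema$treatment, schema$time, schema$event)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns in source CSV: ", paste(miss, collapse = ", "),
         call. = FALSE)
  source_sample(X = d[, schema$covariates, drop = FALSE],
                A = d[[schema$treatment]],
                U = d[[schema$time]],
                Delta = d[[schema$event]])
}

#' @rdname read_source_sample
#' @export
read_target_sample <- function(file, schema) {
  d <- utils::read.csv(file, check.names = FALSE)
  need <- c(schema$covariates, schema$design_weight)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns in target CSV: ", paste(miss, collapse = ", "),
         call. = FALSE)
  target_sample(X = d[, schema$covariates, drop = FALSE],
                e = d[[schema$design_weight]])
}

#' @rdname read_source_sample
#' @export
read_schema <- function(file) {
  if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML schemas requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON schemas requires the 'jsonlite' package",
           call. = FALSE)
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop("schema file must be .yaml/.yml or .json", call. = FALSE)
}
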