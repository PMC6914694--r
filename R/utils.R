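# Internal helpers shared across the pipeline.

#' Derive a reproducible integer seed from a base seed and labels
#'
#' A small FNV-1a style string hash, reduced modulo 2^31 - 1. Used so that the
#' data of subject k under condition c depends only on (seed, group, condition,
#' k): adding subjects or conditions to a cohort never changes already
#' generated series.
#'
#' @param seed base integer seed.
#' @param ... further labels (coerced to character) mixed into the hash.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
hash_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 * h mod 2^31, kept in double precision safe range
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Check that a matrix is a valid correlation matrix
#' @param m matrix to check.
#' @param tol tolerance on symmetry, unit diagonal and the smallest eigenvalue.
#' @return TRUE invisibly; errors otherwise.
#' @keywords internal
check_correlation_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("expected a square matrix")
  }
  if (max(abs(m - t(m))) > tol) stopf("matrix is not symmetric (tol %g)", tol)
  if (max(abs(diag(m) - 1)) > tol) stopf("matrix diagonal is not 1")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stopf("matrix is not positive semi-definite (min eigenvalue %g)", min(ev))
  }
  invisible(TRUE)
}
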