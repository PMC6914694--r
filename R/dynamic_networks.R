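# Sliding-window correlation networks from ROI time series.

#' Number of sliding windows for a series
#'
#' Uses the convention `floor((T - W) / shift)`: 187 volumes with a 60-volume
#' window and shift 1 give 127 networks. Note this is one less than the count
#' of possible start positions (`T - W + 1` for shift 1); the final start
#' position is deliberately not used. See the methods vignette for the
#' rationale behind fixing this convention.
#'
#' @param n_volumes number of (retained) volumes T.
#' @param window window length W in volumes (>= 2).
#' @param shift shift size in volumes (>= 1).
#' @param label optional series label used in error messages.
#' @return integer number of windows.
#' @examples
#' count_windows(187, 60, 1)   # 127
#' @export
count_windows <- function(n_volumes, window, shift = 1L, label = NULL) {
  if (!is_count(window, 2)) stopf("window must be an integer >= 2")
  if (!is_count(shift)) stopf("shift must be an integer >= 1")
  if (!is_count(n_volumes, 2) || n_volumes < window + shift) {
    stopf("series%s has %d volumes; need at least window + shift = %d",
          if (is.null(label)) "" else paste0(" ", label),
          n_volumes, window + shift)
  }
  as.integer(floor((n_volumes - window) / shift))
}

# Pearson correlation with observation weights (weighted means/variances).
# With constant weights this reduces exactly to cor().
weighted_cor <- function(x, w) {
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc * w, xc)        # weighted covariance (biased form)
  s <- sqrt(diag(cv))
  r <- cv / outer(s, s)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Sliding-window correlation networks for one series
#'
#' Moves a window of `window` volumes across the series in steps of `shift`
#' and computes the Pearson correlation between all ROI pairs within each
#' window, yielding one weighted, fully connected network (positive and
#' negative edges, no thresholding) per window position. With
#' `window_shape = "hamming"` a weighted Pearson correlation with Hamming
#' weights of length `window` is used instead of the rectangular window.
#'
#' Windows are formed over the retained volumes in order; censored series are
#' treated as temporally concatenated, and the original volume indices remain
#' available in the input's `retained_volumes`.
#'
#' @param ts a [roi_timeseries], or a plain T x n numeric matrix.
#' @param window window length in volumes.
#' @param shift shift size in volumes.
#' @param window_shape `"rectangular"` (default) or `"hamming"`.
#' @return an object of class `dynamic_networks`: list with `matrices`
#'   (list of n x n correlation matrices in temporal order), `window_starts`
#'   (1-based first-volume index of each window), `window`, `shift`,
#'   `window_shape`, and the series labels.
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' dn <- sliding_correlations(x, window = 30, shift = 5)
#' length(dn$matrices)
#' @export
sliding_correlations <- function(ts, window = 60L, shift = 1L,
                                 window_shape = c("rectangular", "hamming")) {
  window_shape <- match.arg(window_shape)
  if (inherits(ts, "roi_timeseries")) {
    x <- ts$data
    subject_id <- ts$subject_id; group <- ts$group; condition <- ts$condition
  } else {
    x <- as.matrix(ts)
    subject_id <- group <- condition <- NA_character_
  }
  if (anyNA(x)) stopf("series contains missing values")
  window <- as.integer(window); shift <- as.integer(shift)
  k <- count_windows(nrow(x), window, shift, label = subject_id)
  starts <- 1L + (seq_len(k) - 1L) * shift
  w <- if (window_shape == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (seq_len(window) - 1L) / (window - 1L))
  } else {
    rep(1, window)
  }
  mats <- vector("list", k)
  for (i in seq_len(k)) {
    seg <- x[starts[i]:(starts[i] + window - 1L), , drop = FALSE]
    sds <- apply(seg, 2L, sd)
    if (any(sds == 0)) {
      stopf("constant ROI signal (ROI %d) within window %d of series %s",
            which(sds == 0)[1L], i, subject_id)
    }
    mats[[i]] <- if (window_shape == "rectangular") {
      r <- cor(seg); r[r > 1] <- 1; r[r < -1] <- -1; diag(r) <- 1; r
    } else {
      weighted_cor(seg, w)
    }
  }
  structure(list(
    subject_id = subject_id, group = group, condition = condition,
    matrices = mats, window_starts = starts,
    window = as.integer(window), shift = as.integer(shift),
    window_shape = window_shape
  ), class = "dynamic_networks")
}

#' @export
print.dynamic_networks <- function(x, ...) {
  cat(sprintf("Dynamic network series: %s (%s, %s), %d networks of %d ROIs (W=%d, shift=%d, %s)\n",
              x$subject_id, x$group, x$condition, length(x$matrices),
              ncol(x$matrices[[1L]]), x$window, x$shift, x$window_shape))
  invisible(x)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Extracts the values above the diagonal in row-major order (row 1 left to
#' right, then row 2, ...), the canonical edge ordering used throughout the
#' package: a 268-node network yields a vector of 35,778 edge weights. The
#' ordering is fixed so that [devectorize()] is an exact inverse and every
#' embedded point can be mapped back to its full network.
#'
#' @param m symmetric n x n matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length n(n-1)/2.
#' @examples
#' m <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3, 3)
#' vectorize_upper(m)  # .2 .3 .4
#' @export
vectorize_upper <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("expected a square matrix")
  if (max(abs(m - t(m))) > tol) {
    stopf("matrix is asymmetric beyond tolerance %g", tol)
  }
  tm <- t(m)
  tm[lower.tri(tm)]        # column-major lower of t(m) == row-major upper of m
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Exact inverse of [vectorize_upper()] with the diagonal set to 1.
#'
#' @param v edge vector of length n(n-1)/2.
#' @param n optional node count; inferred from `length(v)` when omitted.
#' @return n x n symmetric matrix with unit diagonal.
#' @export
devectorize <- function(v, n = NULL) {
  m_len <- length(v)
  n_implied <- (1 + sqrt(1 + 8 * m_len)) / 2
  if (is.null(n)) n <- n_implied
  if (abs(n - round(n)) > 1e-9 || n * (n - 1) / 2 != m_len) {
    stopf("edge vector of length %d does not match a node count (implied n = %.3f)",
          m_len, n_implied)
  }
  n <- as.integer(round(n))
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- v
  m <- t(tm) + tm
  diag(m) <- 1
  m
}

#' Stack a cohort's dynamic networks into one edge-vector matrix
#'
#' Vectorizes every network of every series and stacks them row-wise,
#' subject-by-subject in the given order with windows in temporal order
#' within each series — the (N x T) x m matrix that all embeddings operate
#' on. Row `k` of the result is `vectorize_upper()` of the k-th network, so
#' the stack preserves the one-to-one link between rows and networks.
#'
#' @param series_list list of `dynamic_networks` objects sharing one ROI count.
#' @return an object of class `edge_stack`: list with `values`
#'   (N_networks x m matrix), `row_meta` (data.frame subject_id, group,
#'   condition, window_index), and `n_rois`.
#' @export
stack_cohort <- function(series_list) {
  if (!length(series_list)) stopf("no series to stack")
  ok <- vapply(series_list, inherits, TRUE, what = "dynamic_networks")
  if (!all(ok)) stopf("all elements must be dynamic_networks objects")
  ns <- vapply(series_list, function(s) ncol(s$matrices[[1L]]), 0L)
  if (length(unique(ns)) != 1L) {
    stopf("mixed ROI counts across series: %s",
          paste(unique(ns), collapse = ", "))
  }
  n <- ns[[1L]]
  rows <- lapply(series_list, function(s) {
    t(vapply(s$matrices, vectorize_upper, numeric(n * (n - 1) / 2)))
  })
  meta <- lapply(series_list, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               condition = s$condition,
               window_index = seq_along(s$matrices),
               stringsAsFactors = FALSE)
  })
  structure(list(values = do.call(rbind, rows),
                 row_meta = do.call(rbind, meta),
                 n_rois = n),
            class = "edge_stack")
}

#' @export
print.edge_stack <- function(x, ...) {
  cat(sprintf("Edge-vector stack: %d networks x %d edges (%d ROIs, %d series)\n",
              nrow(x$values), ncol(x$values), x$n_rois,
              nrow(unique(x$row_meta[c("subject_id", "condition")]))))
  invisible(x)
}

#' Build the edge-vector stack for a whole cohort
#'
#' Convenience wrapper: applies [sliding_correlations()] to every series of a
#' cohort and stacks the results with [stack_cohort()].
#'
#' @inheritParams sliding_correlations
#' @param cohort a `net_cohort`.
#' @return an `edge_stack`.
#' @export
cohort_stack <- function(cohort, window = 60L, shift = 1L,
                         window_shape = "rectangular") {
  stopifnot(inherits(cohort, "net_cohort"))
  stack_cohort(lapply(cohort$series, sliding_correlations,
                      window = window, shift = shift,
                      window_shape = window_shape))
}

#' Persist an edge stack as TSV (values + row_meta sidecar)
#' @param stack an `edge_stack`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "edge_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(stack$values, file.path(dir, "stack_values.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- stack$row_meta
  meta$n_rois <- stack$n_rois
  write.table(meta, file.path(dir, "stack_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an edge stack written by [write_stack()]
#' @param dir directory holding `stack_values.tsv` and `stack_meta.tsv`.
#' @return an `edge_stack`.
#' @export
read_stack <- function(dir) {
  vals <- as.matrix(read.delim(file.path(dir, "stack_values.tsv"),
                               header = FALSE))
  dimnames(vals) <- NULL
  meta <- read.delim(file.path(dir, "stack_meta.tsv"),
                     stringsAsFactors = FALSE)
  n <- meta$n_rois[1L]
  meta$n_rois <- NULL
  structure(list(values = vals, row_meta = meta, n_rois = n),
            class = "edge_stack")
}
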