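# Spatial clustering statistics on embedded dynamic-network series.
#
# A "series" is the set of 2D points of one subject x condition embedding.
# Clustering is quantified as the ratio of mean within-label to mean
# between-label series distances (task/group level), or mean within-series to
# mean between-series point distances (individual level). Ratios below 1
# indicate clustering; permutation tests ask whether the observed ratio is
# smaller than expected under exchangeability.

#' Mean cross-distance between two embedded series
#'
#' The distance between two series is the average Euclidean distance over all
#' |A| x |B| pairs of points, one from each series.
#'
#' @param a,b point matrices (rows = points, columns = coordinates).
#' @return nonnegative scalar; symmetric in its arguments.
#' @export
series_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stopf("series must be non-empty")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(d2, 0)))
}

#' Mean within-series distance
#'
#' Average Euclidean distance over all unordered pairs of distinct points of
#' one embedded series.
#'
#' @param a point matrix with >= 2 rows.
#' @return nonnegative scalar.
#' @export
within_series_distance <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) < 2L) stopf("within-series distance needs >= 2 points")
  mean(dist(a))
}

# S x S matrix of pairwise series distances
series_distance_matrix <- function(series) {
  s <- length(series)
  d <- matrix(0, s, s)
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      d[i, j] <- d[j, i] <- series_distance(series[[i]], series[[j]])
    }
  }
  d
}

ratio_from_matrix <- function(d, labels, subject_ids = NULL) {
  s <- length(labels)
  same_lab <- outer(labels, labels, "==")
  pair <- upper.tri(d)
  within <- pair & same_lab
  if (!is.null(subject_ids)) {
    within <- within & outer(subject_ids, subject_ids, "!=")
  }
  between <- pair & !same_lab
  if (!any(within) || !any(between)) {
    stopf("need at least one within-label and one between-label series pair")
  }
  mean(d[within]) / mean(d[between])
}

#' Within/between clustering ratio at the task or group level
#'
#' `within` is the mean series distance over unordered pairs of distinct
#' series sharing a label; pairs of series from the same subject (e.g. the
#' two conditions of one subject in a group comparison) are excluded from the
#' within average so a paired design cannot masquerade as task clustering.
#' `between` is the mean over pairs with differing labels. Ratios well below
#' 1 indicate that series cluster by label; under exchangeable labels the
#' ratio is near 1.
#'
#' @param series list of point matrices (one per subject x condition).
#' @param labels label per series (task or group).
#' @param subject_ids optional subject id per series, enabling the
#'   same-subject exclusion.
#' @return positive scalar ratio.
#' @export
group_cluster_ratio <- function(series, labels, subject_ids = NULL) {
  if (length(series) != length(labels)) stopf("one label per series required")
  counts <- table(labels)
  if (any(counts < 2)) {
    stopf("label '%s' has a single series", names(counts)[which(counts < 2)[1L]])
  }
  ratio_from_matrix(series_distance_matrix(series), as.character(labels),
                    subject_ids)
}

#' Within/between clustering ratio at the individual level
#'
#' `within` is the mean of [within_series_distance()] over series; `between`
#' the mean of [series_distance()] over all unordered series pairs. Small
#' ratios mean each participant's embedded series forms its own tight,
#' separated cloud.
#'
#' @param series list of >= 2 point matrices, each with >= 2 points.
#' @return positive scalar ratio.
#' @export
individual_cluster_ratio <- function(series) {
  if (length(series) < 2L) stopf("need >= 2 series")
  within <- mean(vapply(series, within_series_distance, 0))
  d <- series_distance_matrix(series)
  within / mean(d[upper.tri(d)])
}

# individual-level ratio recomputed from a pooled point-distance matrix and a
# point -> series assignment; used by the permutation test
individual_ratio_from_pooled <- function(pd, assign) {
  s <- max(assign)
  idx <- split(seq_along(assign), assign)
  within <- mean(vapply(idx, function(i) mean(pd[i, i][upper.tri(pd[i, i])]), 0))
  btw <- 0; npair <- 0L
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      btw <- btw + mean(pd[idx[[i]], idx[[j]]])
      npair <- npair + 1L
    }
  }
  within / (btw / npair)
}

#' Permutation test for spatial clustering
#'
#' Tests whether the observed within/between ratio is smaller (stronger
#' clustering) than expected by chance. At the task/group level, series
#' labels are permuted across series. At the individual level, points are
#' reassigned to series at random (within label strata when `labels` are
#' supplied), preserving every series' size so the marginal geometry is
#' untouched. The p-value is `(1 + #{permuted ratio <= observed}) /
#' (1 + n_perm)`, one-sided.
#'
#' @param series list of point matrices.
#' @param labels series labels; required for `level = "group"`, optional
#'   strata for `level = "individual"`.
#' @param subject_ids optional subject ids (see [group_cluster_ratio()]).
#' @param level `"group"` or `"individual"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return object of class `cluster_stat`: list with `ratio`, `p_value`,
#'   `n_permutations`, `level`.
#' @export
cluster_permutation_test <- function(series, labels = NULL,
                                     subject_ids = NULL,
                                     level = c("group", "individual"),
                                     n_perm = 1000L, seed = 1L) {
  level <- match.arg(level)
  if (!is_count(n_perm, 99)) stopf("n_perm must be an integer >= 99")
  set.seed(hash_seed(seed, "permtest", level))
  if (level == "group") {
    if (is.null(labels)) stopf("group-level test requires labels")
    labels <- as.character(labels)
    d <- series_distance_matrix(series)
    obs <- ratio_from_matrix(d, labels, subject_ids)
    perm <- vapply(seq_len(n_perm), function(i) {
      ratio_from_matrix(d, sample(labels), subject_ids)
    }, 0)
  } else {
    sizes <- vapply(series, nrow, 0L)
    if (any(sizes < 2L)) stopf("every series needs >= 2 points")
    pooled <- do.call(rbind, series)
    pd <- as.matrix(dist(pooled))
    assign0 <- rep(seq_along(series), sizes)
    obs <- individual_ratio_from_pooled(pd, assign0)
    strata <- if (is.null(labels)) rep(1L, length(assign0))
              else rep(as.integer(factor(labels)), sizes)
    perm <- vapply(seq_len(n_perm), function(i) {
      shuffled <- assign0
      for (st in unique(strata)) {
        sel <- strata == st
        shuffled[sel] <- sample(assign0[sel])
      }
      individual_ratio_from_pooled(pd, shuffled)
    }, 0)
  }
  p <- (1 + sum(perm <= obs + 1e-12)) / (1 + n_perm)
  structure(list(ratio = obs, p_value = p,
                 n_permutations = as.integer(n_perm), level = level),
            class = "cluster_stat")
}

#' @export
print.cluster_stat <- function(x, ...) {
  cat(sprintf("%s-level clustering: within/between ratio %.4f, permutation p = %.4g (%d permutations)\n",
              x$level, x$ratio, x$p_value, x$n_permutations))
  invisible(x)
}

#' Split an embedding into per-(subject, condition) series
#'
#' Groups the embedded points by subject x condition and returns the point
#' sets together with the label and subject id of each series — the inputs
#' the clustering statistics operate on.
#'
#' @param embedding a `net_embedding` with row metadata.
#' @param label_col metadata column used as the series label.
#' @return list with `series` (list of point matrices), `labels`,
#'   `subject_ids`.
#' @export
embedding_series <- function(embedding, label_col = "condition") {
  meta <- embedding$row_meta
  if (is.null(meta)) stopf("embedding carries no row metadata")
  key <- interaction(meta$subject_id, meta$condition, drop = TRUE)
  idx <- split(seq_len(nrow(meta)), key)
  list(series = lapply(idx, function(i) embedding$coords[i, , drop = FALSE]),
       labels = vapply(idx, function(i) as.character(meta[[label_col]][i[1L]]), ""),
       subject_ids = vapply(idx, function(i) meta$subject_id[i[1L]], ""))
}

#' Clustering report over replicate embeddings
#'
#' Computes the within/between ratio and its permutation p-value for each
#' replicate embedding and summarises across replicates (mean ratio, SD, and
#' mean p). Single-embedding methods (the linear embedding) yield an `NA` SD,
#' matching the reporting convention for non-stochastic embeddings.
#'
#' @param embeddings a `net_embedding` or list of replicates.
#' @param label_col row_meta column defining the labels ("condition" or
#'   "group"); ignored at the individual level.
#' @param level `"group"` or `"individual"`.
#' @param n_perm permutations per replicate.
#' @param seed integer seed.
#' @return object of class `cluster_report`: `ratio_mean`, `ratio_sd`,
#'   `p_value`, `n_permutations`, `level`, `ratios` (per replicate).
#' @export
cluster_report <- function(embeddings, label_col = "condition",
                           level = c("group", "individual"),
                           n_perm = 1000L, seed = 1L) {
  level <- match.arg(level)
  if (inherits(embeddings, "net_embedding")) embeddings <- list(embeddings)
  res <- lapply(seq_along(embeddings), function(r) {
    es <- embedding_series(embeddings[[r]], label_col)
    cluster_permutation_test(es$series,
                             labels = es$labels,
                             subject_ids = es$subject_ids,
                             level = level, n_perm = n_perm,
                             seed = hash_seed(seed, "rep", r))
  })
  ratios <- vapply(res, `[[`, 0, "ratio")
  structure(list(
    ratio_mean = mean(ratios),
    ratio_sd = if (length(ratios) > 1L) sd(ratios) else NA_real_,
    p_value = mean(vapply(res, `[[`, 0, "p_value")),
    n_permutations = as.integer(n_perm),
    level = level, ratios = ratios
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("%s-level clustering over %d embedding(s)\n", x$level,
              length(x$ratios)))
  cat(sprintf("  Within/Between %.4f  (SD %s)  p = %.4g\n", x$ratio_mean,
              if (is.na(x$ratio_sd)) "-" else sprintf("%.4f", x$ratio_sd),
              x$p_value))
  invisible(x)
}

#' Compare clustering ratios between embedding methods
#'
#' Two-sample t-tests between every pair of replicate-ratio samples, and
#' one-sample t-tests of each replicate sample against each single-valued
#' method (the linear embedding yields one ratio, not a distribution), with
#' Bonferroni correction over all comparisons performed.
#'
#' @param ratio_samples named list; elements of length >= 2 are replicate
#'   ratio samples, elements of length 1 are scalar ratios.
#' @return data.frame with comparison, statistic, df, p_value, p_adjusted.
#' @export
compare_methods <- function(ratio_samples) {
  if (is.null(names(ratio_samples)) || any(!nzchar(names(ratio_samples)))) {
    stopf("ratio_samples must be a named list")
  }
  nm <- names(ratio_samples)
  len <- lengths(ratio_samples)
  if (!any(len >= 2)) stopf("need at least one replicate sample (length >= 2)")
  # zero-variance samples break t.test; an exactly null difference with no
  # spread is reported as no effect, a nonzero one as unboundedly significant
  safe_t <- function(expr, delta) {
    tryCatch(expr, error = function(e) {
      if (abs(delta) < 1e-12) list(statistic = c(t = 0), parameter = c(df = NA),
                                   p.value = 1)
      else list(statistic = c(t = sign(delta) * Inf), parameter = c(df = NA),
                p.value = 0)
    })
  }
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      a <- ratio_samples[[i]]; b <- ratio_samples[[j]]
      if (len[i] >= 2 && len[j] >= 2) {
        tt <- safe_t(t.test(a, b), mean(a) - mean(b))
        lab <- sprintf("%s vs %s (two-sample)", nm[i], nm[j])
      } else if (len[i] >= 2 && len[j] == 1) {
        tt <- safe_t(t.test(a, mu = b), mean(a) - b)
        lab <- sprintf("%s vs %s (one-sample)", nm[i], nm[j])
      } else if (len[i] == 1 && len[j] >= 2) {
        tt <- safe_t(t.test(b, mu = a), mean(b) - a)
        lab <- sprintf("%s vs %s (one-sample)", nm[j], nm[i])
      } else {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = lab, statistic = unname(tt$statistic),
        df = unname(tt$parameter), p_value = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  out
}
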