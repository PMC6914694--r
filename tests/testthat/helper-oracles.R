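# Independent brute-force oracles used across the test files. These are kept
# deliberately naive (double loops, full enumeration) and never share code
# with the package implementation.

# random symmetric matrix with unit diagonal, entries in [-1, 1]
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# per-window Pearson correlation by direct loops
oracle_window_cor <- function(x, window, shift) {
  k <- floor((nrow(x) - window) / shift)
  lapply(seq_len(k), function(i) {
    s <- 1 + (i - 1) * shift
    cor(x[s:(s + window - 1), ])
  })
}

# mean cross-distance by double loop
oracle_series_distance <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      tot <- tot + sqrt(sum((a[i, ] - b[j, ])^2))
    }
  }
  tot / (nrow(a) * nrow(b))
}

oracle_within_distance <- function(a) {
  tot <- 0; np <- 0
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      tot <- tot + sqrt(sum((a[i, ] - a[j, ])^2))
      np <- np + 1
    }
  }
  tot / np
}

# all-pairs weighted shortest paths (Floyd-Warshall) with length = 1/weight
oracle_shortest_paths <- function(g) {
  n <- nrow(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && g[i, j] > 0) d[i, j] <- 1 / g[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(g) {
  d <- oracle_shortest_paths(g)
  n <- nrow(g)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(g) {
  n <- nrow(g)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(g[i, ] > 0)
    vals[i] <- if (length(nb) < 2) 0 else
      oracle_global_efficiency(g[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_assortativity <- function(g) {
  deg <- rowSums(g != 0)
  xs <- c(); ys <- c()
  n <- nrow(g)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (g[i, j] != 0) {
        xs <- c(xs, deg[i], deg[j]); ys <- c(ys, deg[j], deg[i])
      }
    }
  }
  cor(xs, ys)
}

# orthogonal Procrustes residual: min_R ||A R - B||_F over rotations/reflections
procrustes_residual <- function(a, b) {
  a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  r <- s$u %*% t(s$v)
  sqrt(sum((a %*% r - b)^2))
}

# small cohort used by several files; cached per session
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_rois = 12, n_subjects_per_group = c(g1 = 3),
                          conditions = c("rest", "task"), n_volumes = 70,
                          n_blocks = 2, condition_effect = 0.3,
                          subject_sd = 0.03, ar_coeff = 0.4, seed = 42)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})
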