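# Within/between distance ratios and permutation tests.

gauss_series <- function(n_series, n_pts, centres = NULL, sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_series), function(i) {
    c0 <- if (is.null(centres)) c(0, 0) else centres[[i]]
    cbind(rnorm(n_pts, c0[1], sd), rnorm(n_pts, c0[2], sd))
  })
}

test_that("series distances match hand values and a double-loop oracle", {
  expect_equal(series_distance(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  p <- rbind(c(1, 2))
  expect_equal(series_distance(p, p), 0)
  set.seed(2)
  a <- matrix(rnorm(8), 4, 2); b <- matrix(rnorm(10), 5, 2)
  expect_equal(series_distance(a, b), oracle_series_distance(a, b),
               tolerance = 1e-12)
  expect_equal(series_distance(a, b), series_distance(b, a))
  expect_error(series_distance(a[0, , drop = FALSE], b), "non-empty")

  two <- rbind(c(0, 0), c(0, 7))
  expect_equal(within_series_distance(two), 7)
  coll <- cbind(c(0, 1, 2), 0)
  expect_equal(within_series_distance(coll), 4 / 3)
  set.seed(3)
  six <- matrix(rnorm(12), 6, 2)
  expect_equal(within_series_distance(six), oracle_within_distance(six),
               tolerance = 1e-12)
  expect_error(within_series_distance(six[1, , drop = FALSE]), ">= 2")
})

test_that("group ratio separates tight clusters and matches full enumeration", {
  far <- gauss_series(6, 8, centres = c(rep(list(c(-20, 0)), 3),
                                        rep(list(c(20, 0)), 3)),
                      sd = 0.5, seed = 4)
  labs <- rep(c("x", "y"), each = 3)
  expect_lt(group_cluster_ratio(far, labs), 0.2)

  # enumeration oracle on 5 tiny series, incl. the same-subject exclusion:
  # subject s1 contributes two series to label x (a paired design)
  ser <- gauss_series(5, 3, seed = 5)
  labs5 <- c("x", "x", "x", "y", "y")
  subj <- c("s1", "s1", "s2", "s3", "s4")
  d <- outer(1:5, 1:5, Vectorize(function(i, j)
    oracle_series_distance(ser[[i]], ser[[j]])))
  within_excl <- mean(c(d[1, 3], d[2, 3], d[4, 5]))   # (1,2) excluded: same subject
  between <- mean(c(d[1, 4], d[1, 5], d[2, 4], d[2, 5], d[3, 4], d[3, 5]))
  expect_equal(group_cluster_ratio(ser, labs5, subj), within_excl / between,
               tolerance = 1e-12)
  # without subject ids the same-subject pair joins the within average
  within_all <- mean(c(d[1, 2], d[1, 3], d[2, 3], d[4, 5]))
  expect_equal(group_cluster_ratio(ser, labs5), within_all / between,
               tolerance = 1e-12)
  expect_error(group_cluster_ratio(ser, c("x", "y", "y", "y", "y")),
               "single series")
})

test_that("ratios sit near 1 under exchangeable labels", {
  ser <- gauss_series(20, 30, seed = 6)
  labs <- rep(c("x", "y"), 10)
  r <- group_cluster_ratio(ser, labs)
  expect_gt(r, 0.9); expect_lt(r, 1.1)
  ri <- individual_cluster_ratio(ser)
  expect_gt(ri, 0.9); expect_lt(ri, 1.1)
})

test_that("individual ratio matches enumeration and detects tight blobs", {
  blobs <- gauss_series(5, 6, centres = list(c(0, 0), c(30, 0), c(0, 30),
                                             c(-30, 0), c(0, -30)),
                        sd = 0.5, seed = 7)
  expect_lt(individual_cluster_ratio(blobs), 0.1)
  ser <- gauss_series(3, 3, seed = 8)
  within <- mean(sapply(ser, oracle_within_distance))
  between <- mean(c(oracle_series_distance(ser[[1]], ser[[2]]),
                    oracle_series_distance(ser[[1]], ser[[3]]),
                    oracle_series_distance(ser[[2]], ser[[3]])))
  expect_equal(individual_cluster_ratio(ser), within / between,
               tolerance = 1e-12)
})

test_that("ratios and p-values are scale equivariant / invariant", {
  ser <- gauss_series(8, 5, seed = 9)
  labs <- rep(c("x", "y"), 4)
  r1 <- group_cluster_ratio(ser, labs)
  ser_scaled <- lapply(ser, function(p) 3.7 * p)
  expect_equal(group_cluster_ratio(ser_scaled, labs), r1, tolerance = 1e-12)
  expect_equal(individual_cluster_ratio(ser_scaled),
               individual_cluster_ratio(ser), tolerance = 1e-12)
  t1 <- cluster_permutation_test(ser, labs, n_perm = 199, seed = 3)
  t2 <- cluster_permutation_test(ser_scaled, labs, n_perm = 199, seed = 3)
  expect_identical(t1$p_value, t2$p_value)
  expect_equal(series_distance(3.7 * ser[[1]], 3.7 * ser[[2]]),
               3.7 * series_distance(ser[[1]], ser[[2]]), tolerance = 1e-12)
})

test_that("permutation p-values hit their limits in extreme regimes", {
  # enough series that no permutation reproduces the observed partition
  far <- gauss_series(20, 6, centres = c(rep(list(c(-50, 0)), 10),
                                         rep(list(c(50, 0)), 10)),
                      sd = 0.3, seed = 10)
  labs <- rep(c("x", "y"), each = 10)
  t_sep <- cluster_permutation_test(far, labs, n_perm = 999, seed = 1)
  expect_equal(t_sep$p_value, 1 / 1000)
  # identical series: every permuted ratio ties the observed ratio of 1
  same <- rep(list(rbind(c(0, 0), c(1, 0), c(0, 1))), 6)
  t_same <- cluster_permutation_test(same, rep(c("x", "y"), 3),
                                     n_perm = 199, seed = 1)
  expect_equal(t_same$ratio, 1, tolerance = 1e-12)
  expect_gt(t_same$p_value, 0.99)
  expect_error(cluster_permutation_test(far, labs, n_perm = 50), "n_perm")
})

test_that("individual-level permutation preserves series sizes and calibrates", {
  ser <- gauss_series(6, 4, seed = 11)
  t_ind <- cluster_permutation_test(ser, level = "individual",
                                    n_perm = 199, seed = 5)
  expect_gt(t_ind$p_value, 0.05)   # exchangeable points: no clustering signal
  blobs <- gauss_series(6, 4, centres = as.list(as.data.frame(
    t(cbind(seq(-50, 50, length.out = 6), 0)))), sd = 0.3, seed = 12)
  t_blob <- cluster_permutation_test(blobs, level = "individual",
                                     n_perm = 199, seed = 5)
  expect_lt(t_blob$p_value, 0.05)
})

test_that("method comparison runs the stated t-tests with Bonferroni correction", {
  set.seed(13)
  tsne2 <- rnorm(50, 0.62, 0.001)
  tsne99 <- rnorm(50, 0.70, 0.001)
  out <- compare_methods(list(tsne2 = tsne2, tsne99 = tsne99, pca2 = 0.65))
  expect_identical(nrow(out), 3L)
  expect_true(all(out$p_adjusted <= 1))
  expect_true(all(out$p_adjusted >= out$p_value - 1e-15))
  # one-sample t of tsne2 against the scalar is strongly significant
  one <- out[grepl("tsne2 vs pca2", out$comparison), ]
  expect_lt(one$p_adjusted, 1e-6)
  # closed-form check of the one-sample statistic
  expect_equal(one$statistic,
               (mean(tsne2) - 0.65) / (sd(tsne2) / sqrt(50)),
               tolerance = 1e-10)
  # two samples 5 SDs apart are significant after correction
  two <- out[grepl("two-sample", out$comparison), ]
  expect_lt(two$p_adjusted, 0.001)
  # identical samples give t = 0, corrected p = 1
  a <- rnorm(30, 0.6, 0.01)
  ident <- compare_methods(list(m1 = a, m2 = a))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_adjusted, 1)
  # degenerate (zero-variance) sample equal to the scalar: defined as no effect
  flat <- compare_methods(list(m1 = rep(0.5, 5), m2 = 0.5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_adjusted, 1)
  expect_error(compare_methods(list(a = 1, b = 2)), "replicate")
})
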