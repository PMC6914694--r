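# Synthetic multi-subject, multi-condition ROI time-series cohorts.
#
# The generator emulates the geometry of a working-memory fMRI study at desk
# scale: a modular (block) correlation structure common to everyone, a graded
# condition effect and a graded group effect placed on fixed, disjoint sets of
# between-block edges, a per-series subject perturbation, AR(1) temporal
# autocorrelation, and optional volume censoring. Ground truth is known by
# construction, so every downstream stage can be tested without imaging data.

#' Specify a synthetic cohort
#'
#' Constructs and validates the full parameterisation of a synthetic cohort of
#' ROI time series. The defaults describe the regime used throughout the
#' package's examples and tests: 30 ROIs in 3 covariance blocks, two scan
#' conditions per subject, 180 volumes at a 2 s sampling interval, and AR(1)
#' temporal autocorrelation of 0.6 (a stand-in for band-passed BOLD signal,
#' not a haemodynamic simulator).
#'
#' Effect placement is fixed and documented so tests are reproducible:
#' the condition effect is added to all edges between block 1 and block 2,
#' the group effect to all edges between block 1 and block 3 (disjoint sets).
#' With ordered condition labels `c_1 .. c_K`, condition `c_j` adds
#' `(j-1)/(K-1) * condition_effect` to its designated edges, emulating a
#' graded task load; groups are graded the same way in the order of
#' `names(n_subjects_per_group)`.
#'
#' @param n_rois number of regions (columns of each series).
#' @param n_subjects_per_group named integer vector, group label -> number of
#'   subjects in that group.
#' @param conditions ordered character vector of condition labels.
#' @param n_volumes number of time points T before censoring.
#' @param sampling_interval seconds per volume (metadata only).
#' @param n_blocks number of contiguous covariance blocks; must be >= 3 when
#'   `group_effect > 0` so the two effect edge sets stay disjoint.
#' @param within_block_corr target correlation inside a block, in (0, 1).
#' @param between_block_corr baseline correlation between blocks.
#' @param condition_effect magnitude in `[0, 1]` added (graded by condition
#'   order) to the block-1/block-2 edges.
#' @param group_effect magnitude in `[0, 1]` added (graded by group order) to
#'   the block-1/block-3 edges.
#' @param subject_sd standard deviation of the per-series Gaussian
#'   perturbation of all off-diagonal target correlations.
#' @param ar_coeff lag-1 autocorrelation of every ROI signal, in `[0, 1)`.
#' @param censor_fraction fraction of volumes dropped uniformly at random per
#'   series, in `[0, 0.5)`.
#' @param seed integer master seed; the cohort is a pure function of the spec.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects_per_group = c(young = 4),
#'                     condition_effect = 0.3, seed = 7)
#' spec
#' @export
cohort_spec <- function(n_rois = 30L,
                        n_subjects_per_group = c(young = 20L),
                        conditions = c("rest", "task"),
                        n_volumes = 180L,
                        sampling_interval = 2,
                        n_blocks = 3L,
                        within_block_corr = 0.5,
                        between_block_corr = 0.1,
                        condition_effect = 0,
                        group_effect = 0,
                        subject_sd = 0.05,
                        ar_coeff = 0.6,
                        censor_fraction = 0,
                        seed = 1L) {
  if (!is_count(n_rois, 2)) stopf("n_rois must be an integer >= 2")
  if (!is_count(n_volumes, 2)) stopf("n_volumes must be an integer >= 2")
  if (!is_count(n_blocks) || n_blocks > n_rois) {
    stopf("n_blocks must be an integer in [1, n_rois]")
  }
  if (is.null(names(n_subjects_per_group)) ||
      any(!nzchar(names(n_subjects_per_group)))) {
    stopf("n_subjects_per_group must be a named vector of group sizes")
  }
  if (any(n_subjects_per_group < 1)) stopf("every group needs >= 1 subject")
  if (anyDuplicated(names(n_subjects_per_group))) {
    stopf("duplicated group labels")
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    stopf("conditions must be distinct labels")
  }
  if (!is_number(within_block_corr) ||
      within_block_corr <= 0 || within_block_corr >= 1) {
    stopf("within_block_corr must lie in (0, 1)")
  }
  if (!is_number(between_block_corr) || abs(between_block_corr) >= 1) {
    stopf("between_block_corr must lie in (-1, 1)")
  }
  for (nm in c("condition_effect", "group_effect", "subject_sd")) {
    v <- get(nm)
    if (!is_number(v) || v < 0 || v > 1) stopf("%s must lie in [0, 1]", nm)
  }
  if (!is_number(ar_coeff) || ar_coeff < 0 || ar_coeff >= 1) {
    stopf("ar_coeff must lie in [0, 1)")
  }
  if (!is_number(censor_fraction) || censor_fraction < 0 ||
      censor_fraction >= 0.5) {
    stopf("censor_fraction must lie in [0, 0.5)")
  }
  if (group_effect > 0 && n_blocks < 3) {
    stopf("group_effect > 0 requires n_blocks >= 3 (disjoint effect edges)")
  }
  if (condition_effect > 0 && n_blocks < 2) {
    stopf("condition_effect > 0 requires n_blocks >= 2")
  }
  # effects must keep every target entry strictly inside (-1, 1)
  if (between_block_corr + condition_effect >= 1) {
    stopf("condition_effect pushes a target correlation to %g >= 1",
          between_block_corr + condition_effect)
  }
  if (between_block_corr + group_effect >= 1) {
    stopf("group_effect pushes a target correlation to %g >= 1",
          between_block_corr + group_effect)
  }
  structure(list(
    n_rois = as.integer(n_rois),
    n_subjects_per_group = stats::setNames(as.integer(n_subjects_per_group),
                                           names(n_subjects_per_group)),
    conditions = as.character(conditions),
    n_volumes = as.integer(n_volumes),
    sampling_interval = sampling_interval,
    n_blocks = as.integer(n_blocks),
    within_block_corr = within_block_corr,
    between_block_corr = between_block_corr,
    condition_effect = condition_effect,
    group_effect = group_effect,
    subject_sd = subject_sd,
    ar_coeff = ar_coeff,
    censor_fraction = censor_fraction,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d ROIs in %d blocks; %s subjects (%s); conditions: %s\n",
              x$n_rois, x$n_blocks, sum(x$n_subjects_per_group),
              paste(sprintf("%s=%d", names(x$n_subjects_per_group),
                            x$n_subjects_per_group), collapse = ", "),
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  T=%d volumes @ %gs; AR(1)=%g; censor=%g; seed=%d\n",
              x$n_volumes, x$sampling_interval, x$ar_coeff,
              x$censor_fraction, x$seed))
  cat(sprintf("  corr: within=%g between=%g; effects: condition=%g group=%g; subject_sd=%g\n",
              x$within_block_corr, x$between_block_corr,
              x$condition_effect, x$group_effect, x$subject_sd))
  invisible(x)
}

# contiguous, nearly equal block membership for each ROI
roi_blocks <- function(spec) {
  sort(rep_len(seq_len(spec$n_blocks), spec$n_rois))
}

#' Nearest correlation matrix by eigenvalue clipping
#'
#' Projects a symmetric matrix onto the positive semi-definite cone by
#' clipping negative eigenvalues at zero, then re-standardises to unit
#' diagonal. One pass is sufficient here: a diagonal congruence of a PSD
#' matrix stays PSD, so only floating-point error (~1e-15) remains.
#'
#' @param m symmetric matrix with unit diagonal intent.
#' @return a valid correlation matrix.
#' @export
nearest_correlation <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  d <- pmax(e$values, 0)
  r <- e$vectors %*% (d * t(e$vectors))
  s <- sqrt(pmax(diag(r), .Machine$double.eps))
  r <- r / outer(s, s)
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Target correlation matrix for one subject x condition
#'
#' Builds the ground-truth correlation matrix the simulator aims at: block
#' structure, plus the graded condition and group effects on their fixed edge
#' sets, plus the seeded per-series subject perturbation, finally repaired to
#' the nearest correlation matrix (see [nearest_correlation()]).
#'
#' @param spec a [cohort_spec()].
#' @param group group label (must exist in the spec).
#' @param condition condition label (must exist in the spec).
#' @param subject_index 1-based subject index within the group.
#' @return an n x n correlation matrix.
#' @export
target_correlation <- function(spec, group, condition, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- match(group, names(spec$n_subjects_per_group))
  if (is.na(g)) stopf("unknown group label '%s'", group)
  j <- match(condition, spec$conditions)
  if (is.na(j)) stopf("unknown condition label '%s'", condition)
  if (!is_count(subject_index) ||
      subject_index > spec$n_subjects_per_group[[g]]) {
    stopf("subject_index out of range for group '%s'", group)
  }
  blk <- roi_blocks(spec)
  n <- spec$n_rois
  m <- matrix(spec$between_block_corr, n, n)
  same <- outer(blk, blk, "==")
  m[same] <- spec$within_block_corr
  diag(m) <- 1

  grade <- function(idx, k) if (k <= 1) 0 else (idx - 1) / (k - 1)
  if (spec$condition_effect > 0 && spec$n_blocks >= 2) {
    sel <- outer(blk == 1, blk == 2, "&")
    dc <- grade(j, length(spec$conditions)) * spec$condition_effect
    m[sel | t(sel)] <- m[sel | t(sel)] + dc
  }
  if (spec$group_effect > 0 && spec$n_blocks >= 3) {
    sel <- outer(blk == 1, blk == 3, "&")
    dg <- grade(g, length(spec$n_subjects_per_group)) * spec$group_effect
    m[sel | t(sel)] <- m[sel | t(sel)] + dg
  }
  if (max(abs(m[upper.tri(m)])) >= 1) {
    stopf("effect magnitudes push a target correlation outside (-1, 1); reduce condition_effect/group_effect or between_block_corr")
  }
  if (spec$subject_sd > 0) {
    set.seed(hash_seed(spec$seed, "target", group, condition, subject_index))
    z <- matrix(rnorm(n * n, sd = spec$subject_sd), n, n)
    z <- (z + t(z)) / sqrt(2)
    diag(z) <- 0
    m <- m + z
    # perturbations are kept inside the open interval; the PSD repair below
    # handles any remaining indefiniteness
    m[m > 0.999] <- 0.999
    m[m < -0.999] <- -0.999
    diag(m) <- 1
  }
  nearest_correlation(m)
}

#' Simulate one ROI time-series matrix
#'
#' Draws a stationary Gaussian AR(1) process whose cross-sectional correlation
#' equals `target` and whose per-ROI lag-1 autocorrelation equals `ar_coeff`.
#' With `x_1 = L z_1` and `x_t = phi x_{t-1} + sqrt(1 - phi^2) L z_t`, where
#' `L` is the symmetric square root of `target`, the stationary covariance is
#' exactly `target` and all marginal variances are 1.
#'
#' @param target a valid correlation matrix (checked; non-PSD input errors).
#' @param n_volumes number of time points T >= 2.
#' @param ar_coeff lag-1 autocorrelation in `[0, 1)`.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return a T x n numeric matrix.
#' @export
simulate_timeseries_matrix <- function(target, n_volumes, ar_coeff, seed) {
  check_correlation_matrix(target)
  if (!is_count(n_volumes, 2)) stopf("n_volumes must be >= 2")
  if (!is_number(ar_coeff) || ar_coeff < 0 || ar_coeff >= 1) {
    stopf("ar_coeff must lie in [0, 1)")
  }
  n <- ncol(target)
  e <- eigen(target, symmetric = TRUE)
  l <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_volumes * n), n_volumes, n)
  innov <- z %*% l              # rows ~ N(0, target)
  x <- matrix(0, n_volumes, n)
  x[1L, ] <- innov[1L, ]
  if (n_volumes > 1L) {
    s <- sqrt(1 - ar_coeff^2)
    for (t in 2:n_volumes) {
      x[t, ] <- ar_coeff * x[t - 1L, ] + s * innov[t, ]
    }
  }
  x
}

new_roi_timeseries <- function(data, subject_id, group, condition,
                               sampling_interval, retained_volumes) {
  structure(list(
    subject_id = subject_id, group = group, condition = condition,
    data = data, sampling_interval = sampling_interval,
    retained_volumes = as.integer(retained_volumes)
  ), class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s (%s, %s), %d volumes x %d ROIs @ %gs\n",
              x$subject_id, x$group, x$condition,
              nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' One [roi_timeseries] per subject x condition, plus a manifest of ground
#' truth labels. Generation is a pure function of the spec: identical specs
#' give bit-identical cohorts, and each series depends only on its own
#' (group, condition, subject) seed, so adding subjects never changes
#' existing ones.
#'
#' Censoring drops `floor(censor_fraction * T)` volumes uniformly at random
#' per series; the surviving original volume indices (1-based) are recorded in
#' `retained_volumes`. A warning is recorded if a series retains fewer than
#' `min_volumes_warn` volumes (too short for the default 60-volume window).
#'
#' @param spec a [cohort_spec()].
#' @param min_volumes_warn warn when a censored series retains fewer volumes
#'   than this (default 61 = default window + shift).
#' @return an object of class `net_cohort`: list with `series` (list of
#'   [roi_timeseries]) and `manifest` (data.frame with subject_id, group,
#'   condition, n_volumes_retained).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects_per_group = c(g = 2),
#'                                   n_volumes = 80, seed = 1))
#' co$manifest
#' @export
generate_cohort <- function(spec, min_volumes_warn = 61L) {
  stopifnot(inherits(spec, "cohort_spec"))
  series <- list()
  rows <- list()
  t_full <- spec$n_volumes
  n_drop <- floor(spec$censor_fraction * t_full)
  for (g in names(spec$n_subjects_per_group)) {
    for (k in seq_len(spec$n_subjects_per_group[[g]])) {
      sid <- sprintf("%s_%02d", g, k)
      for (cond in spec$conditions) {
        tgt <- target_correlation(spec, g, cond, k)
        x <- simulate_timeseries_matrix(
          tgt, t_full, spec$ar_coeff,
          seed = hash_seed(spec$seed, "ts", g, cond, k))
        retained <- seq_len(t_full)
        if (n_drop > 0) {
          set.seed(hash_seed(spec$seed, "censor", g, cond, k))
          retained <- sort(sample(t_full, t_full - n_drop))
          x <- x[retained, , drop = FALSE]
        }
        if (length(retained) < min_volumes_warn) {
          warnf("series %s/%s retains only %d volumes; too short for a %d-volume window",
                sid, cond, length(retained), min_volumes_warn - 1L)
        }
        colnames(x) <- sprintf("roi%03d", seq_len(spec$n_rois))
        series[[length(series) + 1L]] <-
          new_roi_timeseries(x, sid, g, cond, spec$sampling_interval, retained)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, condition = cond,
          n_volumes_retained = length(retained), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(series = series, manifest = do.call(rbind, rows),
                 spec = spec),
            class = "net_cohort")
}

#' @export
print.net_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d series (%d subjects x %d conditions), %d ROIs\n",
              length(x$series), sum(x$spec$n_subjects_per_group),
              length(x$spec$conditions), x$spec$n_rois))
  invisible(x)
}

#' Write a cohort to TSV files plus a manifest
#'
#' One tab-delimited file per series (rows = time points, columns = ROIs) and
#' a `manifest.tsv` with columns subject_id, group, condition, path,
#' n_volumes_retained.
#'
#' @param cohort a `net_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "net_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- vapply(cohort$series, function(s) {
    f <- sprintf("%s_%s.tsv", s$subject_id, s$condition)
    write.table(s$data, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }, "")
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a manifest TSV with columns subject_id, group,
#'   condition, path (series TSV relative to the manifest's directory).
#' @param sampling_interval seconds per volume to attach to each series.
#' @return a `net_cohort` (without a generating spec).
#' @export
read_cohort <- function(manifest_path, sampling_interval = 2) {
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "path")
  if (!all(need %in% names(man))) {
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  series <- lapply(seq_len(nrow(man)), function(i) {
    x <- as.matrix(read.delim(file.path(base, man$path[i])))
    new_roi_timeseries(x, man$subject_id[i], man$group[i], man$condition[i],
                       sampling_interval, seq_len(nrow(x)))
  })
  man$n_volumes_retained <- vapply(series, function(s) nrow(s$data), 0L)
  structure(list(series = series, manifest = man, spec = NULL),
            class = "net_cohort")
}
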