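# Subject-grouped RBF-SVM classification of embedded dynamic networks.
#
# Protocol: repeated random subsampling into 68% train / 32% test at the
# SUBJECT level (every point of a subject lands on one side), 5-fold
# subject-grouped cross-validated grid search for (cost, gamma) within each
# training set, class weights inversely proportional to class size, and a
# majority vote over each test subject's points to label the subject. With
# replicate (t-SNE) embeddings the whole procedure is repeated per replicate
# and metrics are averaged over all replicate x split records.

#' Subject-level train/test split
#'
#' Splits subjects (never individual points) into train and test sets at
#' `train_fraction`, stratified by class so both sides keep the class
#' proportions of the cohort. Train size per class is rounded to the nearest
#' integer with ties toward train, then clamped so both sides keep at least
#' one subject per class. Deterministic under `(seed, split_index)`.
#'
#' @param subjects data.frame with columns `subject_id` and `class`.
#' @param train_fraction fraction of subjects used for training.
#' @param stratify stratify by class (default TRUE).
#' @param seed integer seed.
#' @param split_index index of the split (varies across the repeated splits).
#' @return list with character vectors `train` and `test`.
#' @export
split_subjects <- function(subjects, train_fraction = 0.68, stratify = TRUE,
                           seed = 1L, split_index = 1L) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "class") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) stopf("duplicated subject_id")
  counts <- table(subjects$class)
  if (any(counts < 2)) {
    stopf("class '%s' has fewer than 2 subjects",
          names(counts)[which(counts < 2)[1L]])
  }
  set.seed(hash_seed(seed, "split", split_index))
  pick_train <- function(ids) {
    n <- length(ids)
    n_train <- floor(n * train_fraction + 0.5)   # ties toward train
    n_train <- min(max(n_train, 1L), n - 1L)
    sample(ids, n_train)
  }
  train <- if (stratify) {
    unlist(lapply(split(subjects$subject_id, subjects$class), pick_train),
           use.names = FALSE)
  } else {
    pick_train(subjects$subject_id)
  }
  list(train = sort(train),
       test = sort(setdiff(subjects$subject_id, train)))
}

# default class weights: n_total / (2 * n_c), larger weight for the smaller class
default_class_weights <- function(labels) {
  tab <- table(labels)
  w <- as.numeric(length(labels) / (2 * tab))
  stats::setNames(w, names(tab))
}

#' Train an RBF-kernel SVM on embedded points
#'
#' @param points N x 2 numeric matrix of embedded coordinates.
#' @param labels factor (2 levels) of point classes.
#' @param cost soft-margin cost parameter.
#' @param gamma RBF kernel width parameter.
#' @param class_weights named weights per class; by default
#'   `n_total / (2 * n_c)`, which up-weights the minority class.
#' @return an [e1071::svm] model.
#' @export
train_svm <- function(points, labels, cost = 1, gamma = 1,
                      class_weights = NULL) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stopf("non-finite coordinates")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stopf("need exactly 2 classes, got %d",
                                   nlevels(labels))
  if (is.null(class_weights)) class_weights <- default_class_weights(labels)
  e1071::svm(x = points, y = labels, kernel = "radial", cost = cost,
             gamma = gamma, class.weights = class_weights, scale = FALSE)
}

#' Grid-search (cost, gamma) by subject-grouped 5-fold cross-validation
#'
#' Subjects (not points) are dealt into folds, so no subject's points inform
#' both sides of a CV fit. For each grid pair the mean point-level holdout
#' accuracy across folds is computed; the pair with the highest mean wins,
#' ties broken toward smaller cost then smaller gamma.
#'
#' @inheritParams train_svm
#' @param subject_ids subject id per point (grouping variable for folds).
#' @param cost_grid,gamma_grid candidate values; defaults are the canonical
#'   libsvm grids `2^(-5, -3, ..., 15)` and `2^(-15, -13, ..., 3)`.
#' @param n_folds number of CV folds.
#' @param seed integer seed (fold assignment).
#' @return list with `cost`, `gamma`, `cv_accuracy`.
#' @export
tune_svm <- function(points, labels, subject_ids,
                     cost_grid = 2^seq(-5, 15, 2),
                     gamma_grid = 2^seq(-15, 3, 2),
                     n_folds = 5L, seed = 1L) {
  if (!length(cost_grid) || !length(gamma_grid)) stopf("empty parameter grid")
  points <- as.matrix(points)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stopf("training data contain a single class")
  subs <- unique(subject_ids)
  n_folds <- min(n_folds, length(subs))
  set.seed(hash_seed(seed, "cvfolds"))
  fold_of_sub <- stats::setNames(
    rep_len(seq_len(n_folds), length(subs))[sample(length(subs))], subs)
  fold <- fold_of_sub[subject_ids]
  best <- list(cost = NA_real_, gamma = NA_real_, cv_accuracy = -Inf)
  for (cost in sort(cost_grid)) {
    for (gamma in sort(gamma_grid)) {
      accs <- c()
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (length(unique(labels[tr])) < 2L || !any(!tr)) next
        fit <- train_svm(points[tr, , drop = FALSE], labels[tr],
                         cost = cost, gamma = gamma)
        pred <- predict(fit, points[!tr, , drop = FALSE])
        accs <- c(accs, mean(pred == labels[!tr]))
      }
      acc <- if (length(accs)) mean(accs) else -Inf
      if (acc > best$cv_accuracy + 1e-12) {
        best <- list(cost = cost, gamma = gamma, cv_accuracy = acc)
      }
    }
  }
  if (!is.finite(best$cv_accuracy)) stopf("cross-validation failed on every fold")
  best
}

#' Majority-vote label for one subject's points
#'
#' Each of the subject's embedded networks is classified individually; the
#' label predicted for more than half of them labels the subject's whole
#' dynamic network series. An exact tie is broken by the sign of the mean
#' SVM decision-function value over the subject's points.
#'
#' @param model an SVM model from [train_svm()].
#' @param points the subject's embedded points (>= 1 row).
#' @return the predicted class label (character).
#' @export
predict_subject_majority <- function(model, points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stopf("subject has no points")
  pred <- predict(model, points, decision.values = TRUE)
  tab <- table(pred)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # even tie: decision values are signed w.r.t. the pair named "A/B"
  dv <- attr(pred, "decision.values")
  pair <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  if (mean(dv[, 1L]) >= 0) pair[1L] else pair[2L]
}

subject_confusion <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# per-point labels, per-vote-unit structure for one embedding.
# The vote unit is everything a subject contributed to one class: for a
# condition contrast that is one subject x condition series; for a group
# contrast it is all of a subject's points (one group per subject).
classification_units <- function(meta, label_col, class_levels = NULL) {
  if (is.null(meta) || !all(c("subject_id", label_col) %in% names(meta))) {
    stopf("embedding metadata must carry subject_id and '%s'", label_col)
  }
  lab <- as.character(meta[[label_col]])
  if (is.null(class_levels)) class_levels <- unique(lab)
  if (length(class_levels) != 2L) {
    stopf("need exactly 2 classes in '%s', got: %s", label_col,
          paste(unique(lab), collapse = ", "))
  }
  unit <- paste(meta$subject_id, lab, sep = "\r")
  units <- unique(data.frame(unit = unit, subject_id = meta$subject_id,
                             class = lab, stringsAsFactors = FALSE))
  list(point_label = factor(lab, levels = class_levels),
       point_unit = unit, units = units, class_levels = class_levels)
}

#' Evaluate subject-level classification of embedded networks
#'
#' Runs the full protocol for one embedding or a list of replicate
#' embeddings: for every replicate and every random subject-grouped 68/32
#' split, tunes (cost, gamma) on the training points, fits the weighted
#' RBF-SVM, majority-votes every test series, and scores accuracy,
#' sensitivity and specificity at the subject level. Splits are always at
#' the subject level — when classifying conditions, both of a subject's
#' condition series travel together — and are stratified by group so both
#' sides keep the cohort's class proportions. The first class listed in
#' `class_levels` (by default the first to appear in the metadata) is
#' "positive" for sensitivity. Reported means and SDs are taken across all
#' replicate x split records.
#'
#' Coordinates are standardised (z-scored per axis over all points of the
#' embedding) before the SVM, so results do not depend on the arbitrary
#' scale of the embedding; like the PCA, this is an unsupervised transform
#' applied before any split.
#'
#' @param embeddings a `net_embedding` or list of replicate `net_embedding`s
#'   (metadata must carry `subject_id` and the label column).
#' @param label_col metadata column holding the two classes: `"condition"`
#'   for task contrasts, `"group"` for population contrasts.
#' @param class_levels optional explicit class order; the first is the
#'   positive class.
#' @param n_splits random subject splits per replicate (reference: 100).
#' @param train_fraction subject fraction in training (reference: 0.68).
#' @param seed integer master seed; splits are re-randomised per replicate.
#' @param tune logical; tune (cost, gamma) per split (default) or use the
#'   supplied fixed `cost`/`gamma`.
#' @param cost_grid,gamma_grid grids passed to [tune_svm()].
#' @param cost,gamma fixed parameters used when `tune = FALSE`.
#' @param n_folds CV folds inside the tuner.
#' @return an object of class `classifier_eval` with fields
#'   `accuracy_mean/sd`, `sensitivity_mean/sd`, `specificity_mean/sd` (all
#'   percentages), `n_splits`, `n_replicates`, `positive_class`, and
#'   `records` (one row per replicate x split).
#' @export
evaluate_classifier <- function(embeddings, label_col = "condition",
                                class_levels = NULL,
                                n_splits = 100L, train_fraction = 0.68,
                                seed = 1L, tune = TRUE,
                                cost_grid = 2^seq(-5, 15, 2),
                                gamma_grid = 2^seq(-15, 3, 2),
                                cost = 1, gamma = 1, n_folds = 5L) {
  if (inherits(embeddings, "net_embedding")) embeddings <- list(embeddings)
  records <- list()
  positive <- NULL
  for (r in seq_along(embeddings)) {
    emb <- embeddings[[r]]
    meta <- emb$row_meta
    cu <- classification_units(meta, label_col, class_levels)
    class_levels <- cu$class_levels
    positive <- class_levels[1L]
    pts <- scale(emb$coords)
    pts[is.na(pts)] <- 0
    # stratify the subject split by group when available, else one stratum
    subjects <- unique(data.frame(
      subject_id = meta$subject_id,
      class = if (label_col == "group") as.character(meta$group)
              else if ("group" %in% names(meta)) as.character(meta$group)
              else "all",
      stringsAsFactors = FALSE))
    for (s in seq_len(n_splits)) {
      sp <- NULL
      for (try in 0:10) {
        sp <- split_subjects(subjects, train_fraction, stratify = TRUE,
                             seed = hash_seed(seed, "rep", r, try),
                             split_index = s)
        tr_classes <- unique(cu$units$class[cu$units$subject_id %in% sp$train])
        if (length(tr_classes) == 2L) break
        if (try == 10) stopf("could not draw a split with both classes in training")
        message(sprintf("split %d left a class out of training; resampled", s))
      }
      tr <- meta$subject_id %in% sp$train
      par <- if (tune) {
        tune_svm(pts[tr, , drop = FALSE], cu$point_label[tr],
                 meta$subject_id[tr],
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 n_folds = n_folds, seed = hash_seed(seed, "tune", r, s))
      } else {
        list(cost = cost, gamma = gamma)
      }
      fit <- train_svm(pts[tr, , drop = FALSE], cu$point_label[tr],
                       cost = par$cost, gamma = par$gamma)
      test_units <- cu$units[cu$units$subject_id %in% sp$test, ]
      pred <- vapply(test_units$unit, function(u) {
        predict_subject_majority(fit, pts[cu$point_unit == u, , drop = FALSE])
      }, "")
      met <- subject_confusion(test_units$class, pred, positive)
      records[[length(records) + 1L]] <- data.frame(
        replicate = r, split = s, cost = par$cost, gamma = par$gamma,
        accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
        specificity = met[["specificity"]])
    }
  }
  rec <- do.call(rbind, records)
  structure(list(
    accuracy_mean = mean(rec$accuracy),
    accuracy_sd = sd(rec$accuracy),
    sensitivity_mean = mean(rec$sensitivity, na.rm = TRUE),
    sensitivity_sd = sd(rec$sensitivity, na.rm = TRUE),
    specificity_mean = mean(rec$specificity, na.rm = TRUE),
    specificity_sd = sd(rec$specificity, na.rm = TRUE),
    n_splits = as.integer(n_splits),
    n_replicates = length(embeddings),
    positive_class = positive,
    records = rec
  ), class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("Subject-level classification (%d replicate(s) x %d splits; positive class: %s)\n",
              x$n_replicates, x$n_splits, x$positive_class))
  cat(sprintf("  Accuracy    %5.1f  (SD %4.1f)\n", x$accuracy_mean, x$accuracy_sd))
  cat(sprintf("  Sensitivity %5.1f  (SD %4.1f)\n", x$sensitivity_mean, x$sensitivity_sd))
  cat(sprintf("  Specificity %5.1f  (SD %4.1f)\n", x$specificity_mean, x$specificity_sd))
  invisible(x)
}

#' Averaged decision-boundary map
#'
#' For each of `n_splits` subject-grouped splits, fits the SVM on the
#' training points and labels every cell of a regular grid covering all
#' embedded points (with a margin). A cell counts as "boundary" for a split
#' when any 4-neighbour cell gets the opposite label; the returned map holds
#' the fraction of splits marking each cell, so darker regions of the plot
#' are locations where a decision boundary consistently appeared.
#'
#' @inheritParams evaluate_classifier
#' @param embedding a single `net_embedding`.
#' @param grid_resolution cells per axis (>= 10).
#' @param margin fractional margin added around the point cloud.
#' @return object of class `boundary_map`: list with `x`, `y` (cell-centre
#'   coordinates) and `frequency` (resolution x resolution matrix in [0,1]).
#' @export
boundary_map <- function(embedding, label_col = "condition",
                         class_levels = NULL, n_splits = 100L,
                         train_fraction = 0.68, seed = 1L,
                         grid_resolution = 100L, margin = 0.05,
                         tune = FALSE, cost = 1, gamma = 1,
                         cost_grid = 2^seq(-5, 15, 2),
                         gamma_grid = 2^seq(-15, 3, 2), n_folds = 5L) {
  stopifnot(inherits(embedding, "net_embedding"))
  if (!is_count(grid_resolution, 10)) {
    stopf("grid_resolution must be an integer >= 10")
  }
  meta <- embedding$row_meta
  cu <- classification_units(meta, label_col, class_levels)
  pt_lab <- cu$point_label
  pts <- scale(embedding$coords)
  pts[is.na(pts)] <- 0
  rng <- apply(pts, 2L, range)
  pad <- margin * (rng[2L, ] - rng[1L, ])
  gx <- seq(rng[1L, 1L] - pad[1L], rng[2L, 1L] + pad[1L],
            length.out = grid_resolution)
  gy <- seq(rng[1L, 2L] - pad[2L], rng[2L, 2L] + pad[2L],
            length.out = grid_resolution)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  subjects <- unique(data.frame(
    subject_id = meta$subject_id,
    class = if ("group" %in% names(meta)) as.character(meta$group) else "all",
    stringsAsFactors = FALSE))
  freq <- matrix(0, grid_resolution, grid_resolution)
  for (s in seq_len(n_splits)) {
    sp <- split_subjects(subjects, train_fraction, TRUE, seed, s)
    tr <- meta$subject_id %in% sp$train
    par <- if (tune) {
      tune_svm(pts[tr, , drop = FALSE], pt_lab[tr], meta$subject_id[tr],
               cost_grid, gamma_grid, n_folds,
               seed = hash_seed(seed, "tune", s))
    } else {
      list(cost = cost, gamma = gamma)
    }
    fit <- train_svm(pts[tr, , drop = FALSE], droplevels(pt_lab[tr]),
                     cost = par$cost, gamma = par$gamma)
    lab <- matrix(as.integer(predict(fit, grid)),
                  grid_resolution, grid_resolution)
    bnd <- matrix(FALSE, grid_resolution, grid_resolution)
    bnd[-1L, ] <- bnd[-1L, ] | (lab[-1L, ] != lab[-grid_resolution, ])
    bnd[-grid_resolution, ] <- bnd[-grid_resolution, ] |
      (lab[-grid_resolution, ] != lab[-1L, ])
    bnd[, -1L] <- bnd[, -1L] | (lab[, -1L] != lab[, -grid_resolution])
    bnd[, -grid_resolution] <- bnd[, -grid_resolution] |
      (lab[, -grid_resolution] != lab[, -1L])
    freq <- freq + bnd
  }
  structure(list(x = gx, y = gy, frequency = freq / n_splits,
                 n_splits = as.integer(n_splits)),
            class = "boundary_map")
}

#' @export
plot.boundary_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$frequency,
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  xlab = "dim 1", ylab = "dim 2",
                  main = "Average decision boundary", ...)
  invisible(x)
}
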