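# Subject-grouped SVM classification, majority voting and boundary maps.

make_two_cluster_embedding <- function(n_subj_per_class = 6, pts_per_subj = 10,
                                       sep = 6, seed = 1, sd_subj = 0.3) {
  set.seed(seed)
  rows <- list(); meta <- list()
  for (cls in 1:2) {
    for (s in seq_len(n_subj_per_class)) {
      centre <- c(ifelse(cls == 1, -sep / 2, sep / 2), 0) +
        rnorm(2, sd = sd_subj)
      pts <- cbind(rnorm(pts_per_subj, centre[1], 0.4),
                   rnorm(pts_per_subj, centre[2], 0.4))
      rows[[length(rows) + 1]] <- pts
      meta[[length(meta) + 1]] <- data.frame(
        subject_id = sprintf("c%d_s%d", cls, s),
        group = sprintf("grp%d", cls),
        condition = "cond", window_index = seq_len(pts_per_subj))
    }
  }
  netmanifold:::new_embedding(do.call(rbind, rows), do.call(rbind, meta),
                              "pca2")
}

test_that("subject splits use the stated rounding and keep subjects whole", {
  subjects <- data.frame(
    subject_id = sprintf("s%02d", 1:63),
    class = rep(c("younger", "older"), c(22, 41)))
  sp <- split_subjects(subjects, 0.68, stratify = TRUE, seed = 3,
                       split_index = 1)
  cls <- setNames(subjects$class, subjects$subject_id)
  expect_identical(sum(cls[sp$train] == "younger"), 15L)  # round(22 * .68)
  expect_identical(sum(cls[sp$train] == "older"), 28L)    # round(41 * .68)
  expect_length(sp$test, 63 - 43)
  expect_length(intersect(sp$train, sp$test), 0)

  ten <- data.frame(subject_id = sprintf("s%d", 1:10), class = "a")
  sp10 <- split_subjects(ten, 0.68, seed = 1)
  expect_length(sp10$train, 7)   # 10 * 0.68 = 6.8 -> 7, ties toward train
  expect_length(sp10$test, 3)
  expect_error(split_subjects(data.frame(subject_id = c("x", "y", "z"),
                                         class = c("a", "a", "b")), 0.68),
               "fewer than 2")
  # deterministic under (seed, split_index)
  expect_identical(sp, split_subjects(subjects, 0.68, TRUE, 3, 1))
  expect_false(identical(sp, split_subjects(subjects, 0.68, TRUE, 3, 2)))
})

test_that("no split ever places one subject's points on both sides", {
  emb <- make_two_cluster_embedding(seed = 2)
  subjects <- unique(data.frame(subject_id = emb$row_meta$subject_id,
                                class = emb$row_meta$group))
  for (s in 1:25) {
    sp <- split_subjects(subjects, 0.68, TRUE, seed = 7, split_index = s)
    side <- tapply(emb$row_meta$subject_id %in% sp$train,
                   emb$row_meta$subject_id, function(v) length(unique(v)))
    expect_true(all(side == 1))
  }
})

test_that("grid search finds a separating pair and stays near chance on shuffled labels", {
  emb <- make_two_cluster_embedding(seed = 3)
  pts <- scale(emb$coords)
  lab <- factor(emb$row_meta$group)
  best <- tune_svm(pts, lab, emb$row_meta$subject_id,
                   cost_grid = c(1, 10), gamma_grid = c(0.1, 1), seed = 1)
  expect_equal(best$cv_accuracy, 1, tolerance = 1e-8)
  # point-shuffled labels: best CV accuracy within binomial noise of 50%
  emb200 <- make_two_cluster_embedding(n_subj_per_class = 10, seed = 30)
  set.seed(11)
  lab_shuf <- factor(sample(rep(c("grp1", "grp2"), each = 100)))
  null_best <- tune_svm(scale(emb200$coords), lab_shuf,
                        emb200$row_meta$subject_id,
                        cost_grid = c(1, 10), gamma_grid = c(0.1, 1), seed = 1)
  expect_gt(null_best$cv_accuracy, 0.35)
  expect_lt(null_best$cv_accuracy, 0.65)
  # deterministic under fixed seed and grids
  expect_identical(best,
                   tune_svm(pts, lab, emb$row_meta$subject_id,
                            cost_grid = c(1, 10), gamma_grid = c(0.1, 1),
                            seed = 1))
  expect_error(tune_svm(pts, factor(rep("a", nrow(pts))),
                        emb$row_meta$subject_id), "single class")
})

test_that("the decision function is symmetric for a two-point problem", {
  pts <- rbind(c(-1, 0), c(1, 0))
  fit <- train_svm(pts, factor(c("a", "b")), cost = 10, gamma = 1)
  left <- predict(fit, rbind(c(-0.6, 0)))
  right <- predict(fit, rbind(c(0.6, 0)))
  expect_identical(as.character(left), "a")
  expect_identical(as.character(right), "b")
  # balanced classes get equal default weights
  w <- netmanifold:::default_class_weights(factor(c("a", "a", "b", "b")))
  expect_equal(unname(w), c(1, 1))
})

test_that("class weighting protects the minority class on imbalanced data", {
  set.seed(12)
  maj <- cbind(rnorm(90, -2, 0.5), rnorm(90, 0, 0.5))
  mino <- cbind(rnorm(10, 2, 0.5), rnorm(10, 0, 0.5))
  pts <- rbind(maj, mino)
  lab <- factor(rep(c("maj", "min"), c(90, 10)))
  w <- netmanifold:::default_class_weights(lab)
  expect_gt(w[["min"]], w[["maj"]])
  fit <- train_svm(pts, lab, cost = 1, gamma = 0.5)
  test_min <- cbind(rnorm(20, 2, 0.5), rnorm(20, 0, 0.5))
  expect_true(all(predict(fit, test_min) == "min"))
})

test_that("majority voting follows the >half rule with the stated tie-break", {
  set.seed(13)
  train <- rbind(cbind(rnorm(30, -3, .5), rnorm(30)),
                 cbind(rnorm(30, 3, .5), rnorm(30)))
  lab <- factor(rep(c("a", "b"), each = 30))
  fit <- train_svm(train, lab, cost = 10, gamma = 0.5)
  # clear majority: 2 points on the "a" side, 1 on "b" side
  expect_identical(predict_subject_majority(
    fit, rbind(c(-3, 0), c(-2.5, 0), c(3, 0))), "a")
  # 115 points, 58 on one side: strict majority wins
  pts115 <- rbind(cbind(rnorm(58, -3, .3), rnorm(58)),
                  cbind(rnorm(57, 3, .3), rnorm(57)))
  expect_identical(predict_subject_majority(fit, pts115), "a")
  # exact tie resolved by the mean decision value (nearer cluster wins)
  tie <- rbind(c(-3.5, 0), c(3, 0))
  dv <- attr(predict(fit, tie, decision.values = TRUE), "decision.values")
  expected <- strsplit(colnames(dv), "/")[[1]][if (mean(dv) >= 0) 1 else 2]
  expect_identical(predict_subject_majority(fit, tie), expected)
})

test_that("evaluation metrics equal a brute-force confusion-matrix oracle", {
  emb <- make_two_cluster_embedding(seed = 4)
  ev <- evaluate_classifier(emb, label_col = "group", n_splits = 4, seed = 9,
                            tune = FALSE, cost = 10, gamma = 0.5)
  # re-derive one split's metrics independently
  subjects <- unique(data.frame(subject_id = emb$row_meta$subject_id,
                                class = emb$row_meta$group))
  sp <- split_subjects(subjects, 0.68, TRUE,
                       seed = netmanifold:::hash_seed(9, "rep", 1, 0),
                       split_index = 2)
  pts <- scale(emb$coords)
  tr <- emb$row_meta$subject_id %in% sp$train
  fit <- train_svm(pts[tr, ], factor(emb$row_meta$group[tr],
                                     levels = c("grp1", "grp2")),
                   cost = 10, gamma = 0.5)
  cls <- setNames(subjects$class, subjects$subject_id)
  tp <- fn <- tn <- fp <- 0
  for (sid in sp$test) {
    pred <- predict_subject_majority(fit, pts[emb$row_meta$subject_id == sid,
                                              , drop = FALSE])
    truth <- cls[[sid]]
    if (truth == "grp1" && pred == "grp1") tp <- tp + 1
    if (truth == "grp1" && pred != "grp1") fn <- fn + 1
    if (truth != "grp1" && pred != "grp1") tn <- tn + 1
    if (truth != "grp1" && pred == "grp1") fp <- fp + 1
  }
  rec <- ev$records[ev$records$split == 2, ]
  expect_equal(rec$accuracy, 100 * (tp + tn) / length(sp$test))
  expect_equal(rec$sensitivity, 100 * tp / (tp + fn))
  expect_equal(rec$specificity, 100 * tn / (tn + fp))
  # aggregate equals mean over split records
  expect_equal(ev$accuracy_mean, mean(ev$records$accuracy))
  expect_true(ev$accuracy_mean >= 0 && ev$accuracy_mean <= 100)
})

test_that("separable embeddings classify perfectly; exchangeable labels stay near chance", {
  emb <- make_two_cluster_embedding(n_subj_per_class = 10, seed = 5)
  ev <- evaluate_classifier(emb, label_col = "group", n_splits = 10, seed = 2,
                            cost_grid = c(1, 10), gamma_grid = c(0.1, 1))
  expect_gte(ev$accuracy_mean, 90)
  # null: same geometry for both "groups" (labels carry no information)
  set.seed(21)
  null_emb <- make_two_cluster_embedding(n_subj_per_class = 10, sep = 0,
                                         sd_subj = 1, seed = 6)
  evn <- evaluate_classifier(null_emb, label_col = "group", n_splits = 20,
                             seed = 2, tune = FALSE, cost = 1, gamma = 0.5)
  expect_gte(evn$accuracy_mean, 35)
  expect_lte(evn$accuracy_mean, 65)
})

test_that("boundary maps concentrate between separated clusters", {
  emb <- make_two_cluster_embedding(seed = 7)
  bm <- boundary_map(emb, label_col = "group", n_splits = 10, seed = 3,
                     grid_resolution = 40, cost = 10, gamma = 0.5)
  expect_true(all(bm$frequency >= 0 & bm$frequency <= 1))
  # scaled coordinates: clusters sit near x = -1 and +1, boundary near 0
  mid <- which.min(abs(bm$x))
  near_left <- which.min(abs(bm$x + 1))
  y0 <- which.min(abs(bm$y))
  expect_gt(max(bm$frequency[mid + (-1:1), ]), 0.8)
  expect_lt(bm$frequency[near_left, y0], 0.2)   # quiet at a cluster centre
  expect_error(boundary_map(emb, label_col = "group", grid_resolution = 5),
               "grid_resolution")
})
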