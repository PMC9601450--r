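test_that("SMOTE balances classes with convex synthetic points", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60 * 2, 5), 60), matrix(rnorm(30 * 2), 30))
  y <- rep(c("PNES", "epilepsy"), c(60, 30))
  out <- smote_oversample(X, y, seed = 4)
  expect_identical(as.vector(table(out$y)), c(60L, 60L))
  expect_identical(out$X[1:90, ], X)  # originals untouched
  # every synthetic row lies inside the minority bounding box (convexity
  # of the interpolation between minority neighbours)
  Xm <- X[y == "epilepsy", ]
  synth <- out$X[-(1:90), , drop = FALSE]
  for (j in 1:2) {
    expect_true(all(synth[, j] >= min(Xm[, j]) - 1e-12))
    expect_true(all(synth[, j] <= max(Xm[, j]) + 1e-12))
  }
})

test_that("SMOTE handles degenerate and invalid inputs", {
  X <- rbind(matrix(rnorm(20), 10), matrix(1, 3, 2))
  y <- rep(c("PNES", "epilepsy"), c(10, 3))
  expect_warning(out <- smote_oversample(X, y, k_neighbors = 5, seed = 1),
                 "k = 2")
  # identical minority points: synthetic points identical to them
  expect_true(all(out$X[-(1:13), ] == 1))
  expect_error(smote_oversample(X[1:10, ], y[1:10]), "single-class")
})

test_that("PCA reduction recovers exact low-rank structure", {
  set.seed(11)
  B <- matrix(rnorm(30), 10, 3)
  scores <- matrix(rnorm(60 * 3), 60, 3) %*% t(B)  # exact 3-D subspace
  pr <- pca_reduce(scores, scores[1:5, , drop = FALSE], variance = 0.95)
  expect_identical(pr$n_components, 3L)
  expect_gte(pr$explained, 0.95)
  # reconstruction error of retained components <= 5% of total variance,
  # and the component count matches an independent eigen decomposition
  X <- matrix(rnorm(100 * 20), 100, 20)
  pr2 <- pca_reduce(X, variance = 0.95)
  expect_identical(pr2$n_components, pca_oracle_ncomp(X, 0.95))
  recon <- pr2$train %*% t(pr2$rotation)
  resid <- scale(X, pr2$center, FALSE) - recon
  expect_lt(sum(resid^2) / sum(scale(X, pr2$center, FALSE)^2), 0.05)
  expect_error(pca_reduce(X[1, , drop = FALSE]), "two")
})

test_that("metrics follow their closed forms and flag undefined cases", {
  m <- compute_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(m), c(1, 1, 1))
  m2 <- compute_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(unname(m2["balanced_accuracy"]), 0.85)
  expect_equal(unname(m2["precision"]), 9 / 11)
  # degenerate all-positive predictor on a balanced set
  m3 <- compute_metrics(list(TP = 10, FN = 0, TN = 0, FP = 10))
  expect_equal(unname(m3["balanced_accuracy"]), 0.5)
  # no positive predictions: precision undefined
  m4 <- compute_metrics(list(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_true(is.na(m4["precision"]))
})

test_that("all four classifiers separate a clean two-class problem", {
  # tight clusters, and every point duplicated across folds: tree-based
  # learners place their split flush against a class's training edge, so
  # each class's edge values must be present in every training fold
  toy <- toy_classes(n_pos = 20, n_neg = 15, sep = 8, sd = 0.5, seed = 12)
  X <- toy$X[rep(seq_len(35), 3), ]
  y <- toy$y[rep(seq_len(35), 3)]
  fm <- make_features(X, y)
  for (kind in c("svm", "knn", "rf", "gbm")) {
    cv <- run_cv(fm, classifier_spec(kind), folds = 5, seed = 2)
    expect_equal(unname(cv$mean_metrics["balanced_accuracy"]), 1,
                 info = kind)
  }
})

test_that("permuted labels give chance-level balanced accuracy", {
  set.seed(13)
  X <- matrix(rnorm(240 * 4), 240, 4)
  y <- sample(rep(c("PNES", "epilepsy"), c(140, 100)))
  cv <- run_cv(make_features(X, y), classifier_spec("knn"), folds = 10,
               seed = 3)
  se <- sd(cv$fold_metrics[, "balanced_accuracy"]) / sqrt(10)
  expect_lt(abs(cv$mean_metrics["balanced_accuracy"] - 0.5), 3 * se + 0.02)
})

test_that("fold partitions are disjoint, exhaustive, and stratified", {
  toy <- toy_classes(n_pos = 53, n_neg = 37, seed = 14)
  assign <- pnesentropy:::make_folds(toy$y, paste0("s", 1:90), 10, seed = 5)
  expect_identical(sort(unique(assign)), 1:10)
  expect_length(assign, 90)
  for (cl in c("PNES", "epilepsy")) {
    per_fold <- table(assign[toy$y == cl])
    expect_lte(diff(range(per_fold)), 1)
  }
  # subject-wise folds never split a subject
  subj <- rep(paste0("p", 1:18), each = 5)
  lab <- rep(rep(c("PNES", "epilepsy"), c(10, 8)), each = 5)
  aw <- pnesentropy:::make_folds(lab, subj, 4, seed = 6,
                                 subject_wise = TRUE)
  expect_true(all(tapply(aw, subj, function(v) length(unique(v))) == 1))
})

test_that("no test-fold information reaches the fitted transforms", {
  toy <- toy_classes(n_pos = 40, n_neg = 30, sep = 2, seed = 15)
  fm <- make_features(toy$X, toy$y)
  cv1 <- run_cv(fm, classifier_spec("knn"), folds = 5, seed = 7,
                keep_fits = TRUE)
  # corrupt the feature values of fold 1's test rows and rerun
  fm2 <- fm
  idx <- cv1$fits[[1]]$test_idx
  fm2$X[idx, ] <- fm2$X[idx, ] * 100 + 57
  cv2 <- run_cv(fm2, classifier_spec("knn"), folds = 5, seed = 7,
                keep_fits = TRUE)
  expect_identical(cv1$fold_assign, cv2$fold_assign)
  expect_equal(cv1$fits[[1]]$center, cv2$fits[[1]]$center)
  expect_equal(cv1$fits[[1]]$scale_sd, cv2$fits[[1]]$scale_sd)
  expect_equal(cv1$fits[[1]]$pca$rotation, cv2$fits[[1]]$pca$rotation)
  expect_identical(cv1$fits[[1]]$fit$model$k, cv2$fits[[1]]$fit$model$k)
})

test_that("cross-validation is deterministic under a fixed seed", {
  toy <- toy_classes(n_pos = 30, n_neg = 20, sep = 1, seed = 16)
  fm <- make_features(toy$X, toy$y)
  cv1 <- run_cv(fm, classifier_spec("rf"), folds = 5, seed = 8)
  cv2 <- run_cv(fm, classifier_spec("rf"), folds = 5, seed = 8)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
})

test_that("the SVM gamma rule and kNN search grid are honoured", {
  spec <- classifier_spec("knn")
  expect_identical(spec$knn_grid, c(2:10, 12, 15, 20))
  # gamma = 1/(p * var): fit on fixed data and compare against e1071 value
  set.seed(17)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- rep(c("PNES", "epilepsy"), c(30, 20))
  fit <- pnesentropy:::fit_classifier(X, y, classifier_spec("svm"))
  expect_equal(fit$model$gamma, 1 / (3 * var(as.vector(X))))
})
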