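# Classification protocol: stratified epoch-wise 10-fold CV; per training
# fold z-scoring -> SMOTE oversampling of the minority class -> PCA to 95%
# explained variance; RBF-SVM, kNN (inner-CV k search), random forest, and
# gradient boosting; precision / recall / balanced accuracy with PNES as
# the positive class.

POSITIVE_CLASS <- "PNES"

#' Classifier specification
#'
#' @param kind one of `"svm"` (RBF kernel, gamma = 1 / (n_features *
#'   variance of the training matrix)), `"knn"` (k selected per fold by
#'   inner 10-fold balanced-accuracy search over
#'   2,3,4,5,6,7,8,9,10,12,15,20), `"rf"` (random forest, 100 trees), or
#'   `"gbm"` (gradient boosting, 100 rounds, learning rate 0.1, depth 3).
#' @param knn_grid candidate neighbour counts for the kNN search.
#' @param rf_ntree,gbm_nrounds,gbm_eta,gbm_depth ensemble hyperparameters.
#' @param svm_cost SVM soft-margin cost.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "knn", "rf", "gbm"),
                            knn_grid = c(2:10, 12, 15, 20),
                            rf_ntree = 100, gbm_nrounds = 100,
                            gbm_eta = 0.1, gbm_depth = 3, svm_cost = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, knn_grid = knn_grid, rf_ntree = rf_ntree,
                 gbm_nrounds = gbm_nrounds, gbm_eta = gbm_eta,
                 gbm_depth = gbm_depth, svm_cost = svm_cost),
            class = "classifier_spec")
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic sample is a convex combination of a minority sample and
#' one of its k nearest minority neighbours; majority samples pass through
#' untouched.  Applied to training folds only.
#'
#' @param X numeric matrix (rows = samples).
#' @param y factor/character labels with exactly two classes present.
#' @param k_neighbors neighbour count (reduced with a warning if the
#'   minority class is too small).
#' @param seed integer seed.
#' @return List with balanced `X` and `y`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("single-class input: SMOTE undefined")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_need <- max(tab) - n_min
  if (n_need == 0) return(list(X = X, y = y))
  k <- k_neighbors
  if (n_min <= k) {
    k <- max(n_min - 1, 0)
    warning("minority class smaller than k_neighbors; using k = ", k)
  }
  Xm <- X[y == minority, , drop = FALSE]
  with_seed(seed, {
    if (k > 0) {
      D <- as.matrix(stats::dist(Xm))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
    }
    base_i <- rep_len(sample.int(n_min), n_need)
    synth <- t(vapply(base_i, function(i) {
      xi <- Xm[i, ]
      if (k == 0) return(xi)
      xj <- Xm[nn[i, sample.int(k, 1)], ]
      lam <- stats::runif(1)
      xi + lam * (xj - xi)
    }, numeric(ncol(X))))
    list(X = rbind(X, synth), y = c(y, rep(minority, n_need)))
  })
}

#' PCA reduction to a target explained variance
#'
#' Components are fitted on the training matrix only; the test matrix is
#' projected with the training loadings.
#'
#' @param X_train,X_test numeric matrices.
#' @param variance target cumulative explained-variance fraction.
#' @return List with `train`, `test`, `n_components`, `explained`, and the
#'   fitted `center`/`rotation`.
#' @export
pca_reduce <- function(X_train, X_test = NULL, variance = 0.95) {
  if (nrow(X_train) < 2) stop("need at least two training samples for PCA")
  pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= variance)[1]
  if (is.na(ncomp)) ncomp <- length(cum)
  list(train = pc$x[, seq_len(ncomp), drop = FALSE],
       test = if (!is.null(X_test))
         scale(X_test, pc$center, FALSE) %*%
           pc$rotation[, seq_len(ncomp), drop = FALSE],
       n_components = ncomp, explained = cum[ncomp],
       center = pc$center,
       rotation = pc$rotation[, seq_len(ncomp), drop = FALSE])
}

# Deterministic two-class kNN: Euclidean distance, majority vote, ties
# broken by the class of the nearest neighbour.  Voting is vectorized as
# cumulative counts of the first class along the sorted-neighbour axis.
knn_vote <- function(ord_labels_pos, k, nearest_pos, cls) {
  votes <- if (k == 1) ord_labels_pos[, 1]
    else rowSums(ord_labels_pos[, seq_len(k), drop = FALSE])
  out <- ifelse(2 * votes > k, cls[1], cls[2])
  tie <- 2 * votes == k
  out[tie] <- ifelse(nearest_pos[tie], cls[1], cls[2])
  out
}

knn_predict <- function(train, ytrain, test, k) {
  cls <- sort(unique(as.character(ytrain)))
  if (length(cls) == 1) return(rep(cls, nrow(test)))
  D2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
    2 * test %*% t(train)
  k <- min(k, ncol(D2))
  ord <- t(apply(D2, 1, order))[, seq_len(k), drop = FALSE]
  pos <- matrix(as.character(ytrain)[ord] == cls[1], nrow(ord))
  knn_vote(pos, k, pos[, 1], cls)
}

# Select k by inner nfold-CV balanced accuracy over the grid (ties -> the
# smaller k).
select_knn_k <- function(X, y, grid, nfold = 10, seed = 1) {
  n <- nrow(X)
  nfold <- min(nfold, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(nfold), n)))
  grid <- grid[grid < n]
  cls <- sort(unique(y))
  # one distance ordering per inner fold, reused for every k
  bacc <- matrix(NA_real_, nfold, length(grid))
  for (f in seq_len(nfold)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    D2 <- outer(rowSums(X[!tr, , drop = FALSE]^2),
                rowSums(X[tr, , drop = FALSE]^2), "+") -
      2 * X[!tr, , drop = FALSE] %*% t(X[tr, , drop = FALSE])
    kmax <- min(max(grid), ncol(D2))
    ord <- t(apply(D2, 1, order))[, seq_len(kmax), drop = FALSE]
    pos <- matrix(y[tr][ord] == cls[1], nrow(ord))
    for (g in seq_along(grid)) {
      kk <- min(grid[g], kmax)
      pred <- knn_vote(pos, kk, pos[, 1], cls)
      bacc[f, g] <- balanced_accuracy_simple(pred, y[!tr])
    }
  }
  mean_bacc <- colMeans(bacc, na.rm = TRUE)
  grid[which.max(mean_bacc)]  # which.max takes the first (smallest k) on ties
}

balanced_accuracy_simple <- function(pred, truth) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), 0))
}

# Fit one classifier on a processed training matrix.
fit_classifier <- function(X, y, spec, seed = 1) {
  y <- factor(y)
  model <- switch(spec$kind,
    svm = {
      gamma <- 1 / (ncol(X) * stats::var(as.vector(X)))
      e1071::svm(X, y, kernel = "radial", gamma = gamma,
                 cost = spec$svm_cost, scale = FALSE)
    },
    knn = {
      k <- select_knn_k(X, as.character(y), spec$knn_grid, seed = seed)
      list(train = X, y = as.character(y), k = k)
    },
    rf = with_seed(seed,
      randomForest::randomForest(X, y, ntree = spec$rf_ntree)),
    gbm = {
      ypos <- as.integer(as.character(y) == POSITIVE_CLASS)
      dtrain <- xgboost::xgb.DMatrix(X, label = ypos, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = spec$gbm_eta,
                      max_depth = spec$gbm_depth, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = spec$gbm_nrounds, verbose = 0)
    })
  structure(list(kind = spec$kind, model = model, levels = levels(y)),
            class = "entropy_classifier")
}

predict_classifier <- function(fit, X) {
  switch(fit$kind,
    svm = as.character(predict(fit$model, X)),
    knn = knn_predict(fit$model$train, fit$model$y, X, fit$model$k),
    rf = as.character(predict(fit$model, X)),
    gbm = {
      p <- predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1))
      ifelse(p > 0.5, POSITIVE_CLASS,
             setdiff(fit$levels, POSITIVE_CLASS)[1])
    })
}

#' Confusion counts with PNES as the positive class
#'
#' @param pred,truth character vectors of class labels.
#' @return Named list TP, FP, TN, FN.
#' @export
confusion_counts <- function(pred, truth) {
  pos <- POSITIVE_CLASS
  list(TP = sum(pred == pos & truth == pos),
       FP = sum(pred == pos & truth != pos),
       TN = sum(pred != pos & truth != pos),
       FN = sum(pred != pos & truth == pos))
}

#' Precision, recall, and balanced accuracy from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' balanced accuracy = (TP/(TP+FN) + TN/(TN+FP)) / 2.
#' A zero denominator yields `NA` for that metric (flagged, excluded from
#' fold averaging).
#'
#' @param counts list with TP, FP, TN, FN.
#' @return Named numeric vector.
#' @export
compute_metrics <- function(counts) {
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- safe_div(counts$TP, counts$TP + counts$FP)
  rec <- safe_div(counts$TP, counts$TP + counts$FN)
  spec <- safe_div(counts$TN, counts$TN + counts$FP)
  bacc <- if (is.na(rec) || is.na(spec)) NA_real_ else (rec + spec) / 2
  c(precision = prec, recall = rec, balanced_accuracy = bacc)
}

# Build stratified fold assignments (epoch-wise) or grouped subject-wise
# folds, keeping per-fold class ratios within one epoch of the global ratio.
make_folds <- function(labels, subject_ids, folds, seed,
                       subject_wise = FALSE) {
  assign <- integer(length(labels))
  if (subject_wise) {
    subj <- unique(subject_ids)
    subj_lab <- labels[match(subj, subject_ids)]
    subj_fold <- stats::setNames(integer(length(subj)), subj)
    with_seed(seed, for (cl in unique(subj_lab)) {
      s <- sample(subj[subj_lab == cl])
      subj_fold[s] <- rep_len(seq_len(folds), length(s))
    })
    assign <- unname(subj_fold[subject_ids])
  } else {
    with_seed(seed, for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      assign[ix] <- rep_len(seq_len(folds), length(ix))
    })
  }
  assign
}

#' Cross-validated classification of an entropy feature set
#'
#' Per fold: z-score with training statistics -> SMOTE -> PCA (95%
#' variance) -> fit -> predict the held-out fold.  Deterministic under
#' `seed`.
#'
#' @param features an `entropy_features` object.
#' @param spec a [classifier_spec()].
#' @param folds fold count.
#' @param seed integer seed.
#' @param subject_wise if `TRUE`, folds are grouped by subject (no subject
#'   appears in both train and test); default `FALSE` (epoch-wise folds).
#' @param standardize z-score features with training-fold statistics.
#' @param smote apply SMOTE to the training fold.
#' @param pca_variance PCA explained-variance target; `NULL` disables PCA.
#' @param keep_fits retain per-fold fitted pipelines (needed for permutation
#'   importance).
#' @return A `cv_result`: per-fold confusion counts and metrics, unweighted
#'   mean metrics, and optionally the fitted fold pipelines.
#' @export
run_cv <- function(features, spec, folds = 10, seed = 1,
                   subject_wise = FALSE, standardize = TRUE, smote = TRUE,
                   pca_variance = 0.95, keep_fits = FALSE) {
  X <- features$X; y <- as.character(features$labels)
  if (min(table(y)) < folds && !subject_wise)
    stop("need at least `folds` epochs per class")
  assign <- make_folds(y, features$subject_ids, folds, seed, subject_wise)
  seeds <- derive_seeds(seed + 1L, folds)
  fold_counts <- vector("list", folds)
  fold_metrics <- matrix(NA_real_, folds, 3,
                         dimnames = list(NULL, c("precision", "recall",
                                                 "balanced_accuracy")))
  fits <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    if (length(unique(y[tr])) < 2)
      stop("a class is absent from the training data of fold ", f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    pipe <- fit_pipeline(Xtr, ytr, spec, seed = seeds[f],
                         standardize = standardize, smote = smote,
                         pca_variance = pca_variance)
    pred <- predict_pipeline(pipe, Xte)
    cc <- confusion_counts(pred, yte)
    fold_counts[[f]] <- cc
    fold_metrics[f, ] <- compute_metrics(cc)
    if (keep_fits) {
      pipe$test_idx <- which(!tr)
      fits[[f]] <- pipe
    }
  }
  structure(list(
    fold_counts = fold_counts, fold_metrics = fold_metrics,
    mean_metrics = colMeans(fold_metrics, na.rm = TRUE),
    undefined_folds = which(apply(is.na(fold_metrics), 1, any)),
    spec = spec, folds = folds, seed = seed,
    subject_wise = subject_wise,
    fits = if (keep_fits) fits,
    fold_assign = assign,
    measure = features$feature$measure[1],
    bands = unique(features$groups)), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf(
    "<cv_result> %s | %s | bands: %s\n  %d-fold CV: bal.acc %.4f, precision %.4f, recall %.4f\n",
    x$spec$kind, x$measure, paste(x$bands, collapse = ","), x$folds,
    m["balanced_accuracy"], m["precision"], m["recall"]))
  invisible(x)
}

# Fit the full per-fold pipeline (scaler -> SMOTE -> PCA -> classifier) on
# raw-feature training data.
fit_pipeline <- function(Xtr, ytr, spec, seed, standardize = TRUE,
                         smote = TRUE, pca_variance = 0.95) {
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(Xtr)
    scale_sd <- apply(Xtr, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    Xtr <- scale(Xtr, center, scale_sd)
  }
  if (smote) {
    sm <- smote_oversample(Xtr, ytr, seed = seed)
    Xtr <- sm$X; ytr <- sm$y
  }
  pca <- NULL
  if (!is.null(pca_variance)) {
    pca <- pca_reduce(Xtr, variance = pca_variance)
    Xtr <- pca$train
  }
  fit <- fit_classifier(Xtr, ytr, spec, seed = seed)
  structure(list(center = center, scale_sd = scale_sd, pca = pca,
                 fit = fit), class = "entropy_pipeline")
}

predict_pipeline <- function(pipe, X) {
  if (is.function(pipe)) return(pipe(X))  # plain prediction functions
  if (!is.null(pipe$center)) X <- scale(X, pipe$center, pipe$scale_sd)
  if (!is.null(pipe$pca))
    X <- scale(X, pipe$pca$center, FALSE) %*% pipe$pca$rotation
  predict_classifier(pipe$fit, X)
}
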