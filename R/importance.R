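# Grouped permutation importance of frequency bands and the band-exclusion
# experiment.  A band's importance is the drop in balanced accuracy when
# all of its feature columns are shuffled in the validation data:
# i = s - (1/K) * sum_k s~_k.

#' Grouped permutation importance
#'
#' The reference score s is the balanced accuracy of the fitted pipeline on
#' the untouched validation data.  For each group, its columns are row
#' shuffled (each column independently by default, or all columns with one
#' shared permutation), the score is recomputed K times, and the importance
#' is s minus the mean corrupted score.
#'
#' @param pipe a fitted fold pipeline (from [run_cv()] with
#'   `keep_fits = TRUE`) or any object usable by the internal predictor.
#' @param X_val,y_val validation features (raw feature space) and labels.
#' @param groups character vector assigning each column to a group (band).
#' @param K permutation repetitions (>= 1).
#' @param seed integer seed.
#' @param mode `"independent"` permutes each column of the group with its
#'   own permutation (stronger corruption); `"shared"` applies a single row
#'   permutation to the whole block.
#' @param exhaustive if `TRUE`, enumerate all `nrow(X_val)!` permutations
#'   (shared mode, validation sets of at most 8 rows) instead of sampling K.
#' @return An `importance_result`: named importance per group, the
#'   reference score, and the per-repetition scores.
#' @export
grouped_permutation_importance <- function(pipe, X_val, y_val, groups,
                                           K = 10, seed = 1,
                                           mode = c("independent", "shared"),
                                           exhaustive = FALSE) {
  mode <- match.arg(mode)
  if (K < 1) stop("K must be >= 1")
  if (length(groups) != ncol(X_val))
    stop("groups must annotate every feature column")
  s <- balanced_accuracy_simple(predict_pipeline(pipe, X_val), y_val)
  n <- nrow(X_val)
  group_names <- unique(groups)
  score_perm <- function(g_cols, perm_list) {
    Xp <- X_val
    for (i in seq_along(g_cols))
      Xp[, g_cols[i]] <- X_val[perm_list[[i]], g_cols[i]]
    balanced_accuracy_simple(predict_pipeline(pipe, Xp), y_val)
  }
  imp <- numeric(length(group_names)); names(imp) <- group_names
  rep_scores <- list()
  seeds <- derive_seeds(seed, length(group_names))
  for (gi in seq_along(group_names)) {
    g_cols <- which(groups == group_names[gi])
    if (exhaustive) {
      if (n > 8) stop("exhaustive mode limited to 8 validation rows")
      perms <- all_permutations(n)
      scores <- vapply(perms, function(p)
        score_perm(g_cols, rep(list(p), length(g_cols))), 0)
    } else {
      scores <- with_seed(seeds[gi], vapply(seq_len(K), function(k) {
        perm_list <- if (mode == "shared")
          rep(list(sample.int(n)), length(g_cols))
        else replicate(length(g_cols), sample.int(n), simplify = FALSE)
        score_perm(g_cols, perm_list)
      }, 0))
    }
    imp[gi] <- s - mean(scores)
    rep_scores[[group_names[gi]]] <- scores
  }
  structure(list(importance = imp, reference_score = s,
                 scores = rep_scores, K = if (exhaustive) NA_integer_ else K,
                 mode = mode, exhaustive = exhaustive),
            class = "importance_result")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0
  for (p in sub) for (pos in seq_len(n)) {
    i <- i + 1
    out[[i]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Cross-validated band importance
#'
#' Runs [run_cv()] with retained fits and averages the grouped permutation
#' importance of each band over the folds' validation sets.
#'
#' @inheritParams run_cv
#' @param K permutation repetitions per fold.
#' @param mode see [grouped_permutation_importance()].
#' @return List with `importance` (named mean importance per band) and the
#'   underlying `cv` result.
#' @export
cv_band_importance <- function(features, spec, folds = 10, K = 10, seed = 1,
                               mode = "independent") {
  cv <- run_cv(features, spec, folds = folds, seed = seed, keep_fits = TRUE)
  seeds <- derive_seeds(seed + 2L, folds)
  per_fold <- vapply(seq_len(folds), function(f) {
    pipe <- cv$fits[[f]]
    idx <- pipe$test_idx
    res <- grouped_permutation_importance(
      pipe, features$X[idx, , drop = FALSE],
      as.character(features$labels)[idx], features$groups,
      K = K, seed = seeds[f], mode = mode)
    res$importance
  }, numeric(length(unique(features$groups))))
  list(importance = rowMeans(per_fold), cv = cv, per_fold = per_fold)
}

#' Band-exclusion experiment
#'
#' For each band, classification is re-run on the remaining bands' features
#' (the ECG features of the remaining bands stay in, so the ECG is present
#' in every configuration), plus a no-exclusion row; per-band permutation
#' importance comes from the all-bands model.
#'
#' @param features combined all-bands `entropy_features`.
#' @param spec a [classifier_spec()].
#' @param folds CV folds.
#' @param K permutation repetitions for the importance column.
#' @param seed integer seed.
#' @return An `exclusion_table` data frame: one row per excluded band plus
#'   `"none"`, with precision, recall, balanced accuracy, and band
#'   importance.
#' @export
band_exclusion_experiment <- function(features, spec, folds = 10, K = 10,
                                      seed = 1) {
  bands <- unique(features$groups)
  if (length(bands) < 2) stop("need at least two bands")
  imp <- cv_band_importance(features, spec, folds = folds, K = K,
                            seed = seed)
  rows <- list()
  for (b in bands) {
    cv <- run_cv(exclude_band(features, b), spec, folds = folds,
                 seed = seed)
    rows[[b]] <- data.frame(
      band_excluded = b,
      precision = unname(cv$mean_metrics["precision"]),
      recall = unname(cv$mean_metrics["recall"]),
      balanced_accuracy = unname(cv$mean_metrics["balanced_accuracy"]),
      band_importance = unname(imp$importance[b]))
  }
  none <- imp$cv$mean_metrics
  rows[["none"]] <- data.frame(
    band_excluded = "none", precision = unname(none["precision"]),
    recall = unname(none["recall"]),
    balanced_accuracy = unname(none["balanced_accuracy"]),
    band_importance = NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exclusion_table", class(out))
  out
}
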