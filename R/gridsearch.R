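# (m, r_sd) selection protocol for the template entropies: grid
# m in {1, 2} x r_sd in {0.1, 0.15, 0.2, 0.25}, evaluated on a subject
# subset with an RBF-SVM under 5-fold CV; the pair with the highest mean
# balanced accuracy wins (ties: smaller m, then smaller r_sd).

APEN_SAMPEN_GRID <- expand.grid(m = 1:2, r_sd = c(0.1, 0.15, 0.2, 0.25))

# ApEn and SampEn for every grid cell of one series in a single pairwise
# sweep (absolute tolerances r = r_sd * sd(x)).
grid_features_series <- function(x, r_sds = c(0.1, 0.15, 0.2, 0.25)) {
  s <- stats::sd(x)
  if (s == 0) {
    out <- matrix(0, 4, length(r_sds))
    rownames(out) <- c("apen_m1", "apen_m2", "sampen_m1", "sampen_m2")
    return(out)
  }
  apen_sampen_grid_cpp(x, r_sds * s)
}

#' Grid search for the approximate/sample entropy input parameters
#'
#' A deterministic subject subset (default ten per class) is drawn under
#' `seed`; ApEn and SampEn features are extracted for every (m, r_sd) grid
#' cell; each cell is scored by RBF-SVM balanced accuracy under 5-fold CV
#' (the classification module's conventions), either on the broad band only
#' or averaged over all six bands.
#'
#' @param banded_epochs named list of `epoch_set`s from
#'   [preprocess_cohort()].
#' @param n_subjects_per_class subset size per class.
#' @param folds CV folds per grid cell.
#' @param seed integer seed (subject sampling and CV).
#' @param band_mode `"average"` scores each cell by its mean balanced
#'   accuracy across the six bands; `"broad"` uses the broad band only.
#' @return A `grid_result`: the full per-cell table and the selected
#'   (m, r_sd) per measure.
#' @export
select_apen_sampen_params <- function(banded_epochs,
                                      n_subjects_per_class = 10,
                                      folds = 5, seed = 1,
                                      band_mode = c("average", "broad")) {
  band_mode <- match.arg(band_mode)
  es <- banded_epochs[[1]]
  subj <- unique(es$subject_ids)
  subj_lab <- es$class_labels[match(subj, es$subject_ids)]
  per_class <- split(subj, subj_lab)
  if (any(vapply(per_class, length, 0L) < n_subjects_per_class))
    stop("fewer than ", n_subjects_per_class, " subjects in a class")
  chosen <- unlist(with_seed(seed, lapply(per_class, sample,
                                          size = n_subjects_per_class)))
  use_bands <- if (band_mode == "broad") "broad" else names(banded_epochs)
  r_sds <- sort(unique(APEN_SAMPEN_GRID$r_sd))
  rows <- list()
  for (band in use_bands) {
    bes <- banded_epochs[[band]]
    keep <- bes$subject_ids %in% chosen
    bes <- subset_epochs(bes, keep)
    E <- n_epochs(bes); C <- length(bes$channels)
    # features: E x C per (measure, m, r_sd)
    feats <- array(NA_real_, c(4, length(r_sds), E, C))
    for (e in seq_len(E)) for (ch in seq_len(C))
      feats[, , e, ch] <- grid_features_series(bes$data[e, ch, ], r_sds)
    kinds <- c(apen_m1 = 1, apen_m2 = 2, sampen_m1 = 3, sampen_m2 = 4)
    for (g in seq_len(nrow(APEN_SAMPEN_GRID))) {
      m <- APEN_SAMPEN_GRID$m[g]; r_sd <- APEN_SAMPEN_GRID$r_sd[g]
      ri <- match(r_sd, r_sds)
      for (measure in c("apen", "sampen")) {
        M <- feats[kinds[[paste0(measure, "_m", m)]], ri, , ]  # E x C
        ok <- apply(is.finite(M), 1, all)
        fm <- structure(list(
          X = M[ok, , drop = FALSE],
          feature = data.frame(channel = bes$channels, band = band,
                               measure = measure),
          groups = rep(band, C), labels = bes$class_labels[ok],
          subject_ids = bes$subject_ids[ok]),
          class = "entropy_features")
        cv <- run_cv(fm, classifier_spec("svm"), folds = folds, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          measure = measure, band = band, m = m, r_sd = r_sd,
          balanced_accuracy = unname(cv$mean_metrics["balanced_accuracy"]))
      }
    }
  }
  tab <- do.call(rbind, rows)
  cell <- aggregate(balanced_accuracy ~ measure + m + r_sd, tab, mean)
  selected <- lapply(split(cell, cell$measure), function(d) {
    d <- d[order(-d$balanced_accuracy, d$m, d$r_sd), ]
    list(m = d$m[1], r_sd = d$r_sd[1],
         balanced_accuracy = d$balanced_accuracy[1])
  })
  structure(list(per_band = tab, table = cell, selected = selected,
                 band_mode = band_mode, subjects = chosen, seed = seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> (m, r_sd) selection, band mode:", x$band_mode, "\n")
  for (ms in names(x$selected))
    cat(sprintf("  %s: m = %d, r_sd = %.2f (bal.acc %.3f)\n", ms,
                x$selected[[ms]]$m, x$selected[[ms]]$r_sd,
                x$selected[[ms]]$balanced_accuracy))
  invisible(x)
}
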