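# Feature assembly: one entropy value per (epoch, channel, band).

measure_names <- function()
  c("apen", "sampen", "specen", "svden", "renyi", "waveen")

# Compute one measure for a single series under params.
compute_measure <- function(x, measure, params, fs) {
  switch(measure,
    apen = approximate_entropy(x, m = params$apen_m, r_sd = params$apen_r_sd),
    sampen = sample_entropy(x, m = params$sampen_m,
                            r_sd = params$sampen_r_sd),
    specen = spectral_entropy(x, fs, params$welch_seg_sec,
                              params$welch_overlap),
    svden = svd_entropy(x, params$svd_emb, params$svd_tau),
    renyi = renyi_entropy(x, params$alpha, params$n_hist_bins),
    waveen = wavelet_entropy(x, fs, params$wavelet_scales,
                             params$wavelet_fmin, params$wavelet_fmax),
    stop("unknown measure: ", measure))
}

#' Extract an entropy feature matrix from banded epochs
#'
#' One value per (epoch, channel) per band; bands are concatenated
#' column-wise with the band-group annotation preserved for grouped
#' permutation importance.  For approximate/sample entropy the tolerance is
#' r_sd * SD computed per epoch per channel.
#'
#' @param banded_epochs named list of `epoch_set`s (one per band), or a
#'   single `epoch_set`.
#' @param measure one of `"apen"`, `"sampen"`, `"specen"`, `"svden"`,
#'   `"renyi"`, `"waveen"`.
#' @param params an [entropy_params()].
#' @return An `entropy_features` object: `X` (epochs x features), `feature`
#'   (data frame: channel, band, measure), `groups` (band per column),
#'   `labels`, `subject_ids`, `params`.  Epochs with an undefined sample
#'   entropy (degenerate template counts) are dropped with a warning.
#' @export
extract_features <- function(banded_epochs, measure,
                             params = entropy_params()) {
  measure <- match.arg(measure, measure_names())
  if (inherits(banded_epochs, "epoch_set"))
    banded_epochs <- stats::setNames(list(banded_epochs), banded_epochs$band)
  es1 <- banded_epochs[[1]]
  E <- n_epochs(es1)
  blocks <- list()
  for (band in names(banded_epochs)) {
    es <- banded_epochs[[band]]
    stopifnot(n_epochs(es) == E)
    M <- matrix(NA_real_, E, length(es$channels))
    for (ch in seq_along(es$channels)) {
      series <- t(es$data[, ch, ])  # samples x epochs, one slice per channel
      if (measure == "renyi") {
        M[, ch] <- renyi_matrix_cpp(series, params$alpha, params$n_hist_bins)
      } else {
        for (e in seq_len(E)) {
          M[e, ch] <- suppressWarnings(
            compute_measure(series[, e], measure, params, es$fs))
        }
      }
    }
    colnames(M) <- paste(es$channels, band, measure, sep = ".")
    blocks[[band]] <- M
  }
  X <- do.call(cbind, blocks)
  groups <- rep(names(banded_epochs),
                vapply(blocks, ncol, 0L))
  bad_rows <- which(!apply(is.finite(X), 1, all))
  if (length(bad_rows)) {
    if (measure == "sampen") {
      warning(length(bad_rows),
              " epoch(s) dropped: undefined sample entropy")
      X <- X[-bad_rows, , drop = FALSE]
    } else {
      bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
      stop("non-finite ", measure, " feature at epoch ", bad[1],
           ", feature ", colnames(X)[bad[2]])
    }
  }
  keep <- if (length(bad_rows) && measure == "sampen")
    setdiff(seq_len(E), bad_rows) else seq_len(E)
  feature <- data.frame(
    channel = unlist(lapply(names(banded_epochs), function(b)
      banded_epochs[[b]]$channels)),
    band = groups, measure = measure, stringsAsFactors = FALSE)
  structure(list(X = X, feature = feature, groups = groups,
                 labels = es1$class_labels[keep],
                 subject_ids = es1$subject_ids[keep], params = params),
            class = "entropy_features")
}

#' @export
print.entropy_features <- function(x, ...) {
  cat(sprintf("<entropy_features> %d epochs x %d features (%s; bands: %s)\n",
              nrow(x$X), ncol(x$X), x$feature$measure[1],
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

# Drop one band's columns from a combined feature set (ECG features of the
# remaining bands stay, so the ECG is present in every configuration).
exclude_band <- function(features, band) {
  keep <- features$groups != band
  if (!any(!keep)) stop("band not present: ", band)
  features$X <- features$X[, keep, drop = FALSE]
  features$feature <- features$feature[keep, , drop = FALSE]
  features$groups <- features$groups[keep]
  features
}

#' Write a feature matrix as TSV (one row per epoch)
#'
#' @param features an `entropy_features` object.
#' @param path output file; a JSON sidecar `<path>.json` records the params.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(subject_id = features$subject_ids,
                   class_label = features$labels,
                   features$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(features$params[setdiff(names(features$params), "")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
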