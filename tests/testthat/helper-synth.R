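# Shared fixtures, generated in code.

# A small cohort configuration for fast unit tests.
tiny_cohort_config <- function(..., seed = 101) {
  cohort_config(n_per_class = c(PNES = 3, epilepsy = 2),
                epochs_per_subject = 3, seed = seed, ...)
}

# Build an epoch_set directly from a 3-D array (epoch x channel x sample).
make_epoch_set <- function(data, channels, subjects = NULL, labels = NULL,
                           fs = 256, band = "broad") {
  dimnames(data) <- list(NULL, channels, NULL)
  E <- dim(data)[1]
  pnesentropy:::new_epoch_set(
    data,
    subjects %||% rep("s1", E),
    labels %||% rep("PNES", E),
    fs, band, channels)
}

# Build an entropy_features object from a plain matrix (toy classification
# problems).
make_features <- function(X, labels, groups = rep("broad", ncol(X)),
                          subjects = NULL, measure = "renyi") {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(
    X = X,
    feature = data.frame(channel = colnames(X), band = groups,
                         measure = measure),
    groups = groups, labels = labels,
    subject_ids = subjects %||% paste0("s", seq_len(nrow(X))),
    params = entropy_params()),
    class = "entropy_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-class Gaussian toy features: class means separated by `sep` along
# every coordinate.
toy_classes <- function(n_pos = 30, n_neg = 20, p = 2, sep = 4, seed = 1,
                        sd = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_pos * p, sep, sd), n_pos),
               matrix(rnorm(n_neg * p, 0, sd), n_neg))
    list(X = X, y = rep(c("PNES", "epilepsy"), c(n_pos, n_neg)))
  })
}
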