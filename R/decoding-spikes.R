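#' Time-resolved aperture decoding from spike counts
#'
#' Trains a linear-kernel maximum-margin classifier (SVM) on per-unit
#' spike counts independently at every time bin, under stratified k-fold
#' cross-validation (default 10-fold: trained on 90% of labels, tested on
#' the held-out 10%). Feature standardization statistics are computed on
#' the training folds only. Returns the per-timepoint accuracy series and
#' the mean accuracy over a summary window (default trigger onset to
#' 400 ms post-onset).
#'
#' @param features A `wt_trial_features` object.
#' @param folds Number of cross-validation folds.
#' @param window Summary window (s) for the mean accuracy.
#' @param seed Seed for the fold assignment.
#' @param cost SVM cost parameter.
#' @param shuffle_labels Permute labels before training (chance control).
#' @return A `wt_decoding` list: `accuracy` tibble (`bin_t`, `accuracy`),
#'   `window_accuracy`, `fold_assignment`, `seed`.
#' @export
decode_spikes <- function(features, folds = 10, window = c(0, 0.4),
                          seed = 1, cost = 1, shuffle_labels = FALSE) {
  labels <- factor(features$labels)
  if (nlevels(labels) < 2) abort("need two label classes to decode")
  n_tr <- length(labels)
  if (n_tr < 20) abort("need at least 20 trials")
  if (shuffle_labels) {
    labels <- with_seed(substream_seed(seed, "shuffle"), sample(labels))
  }
  fold <- stratified_folds(labels, folds, substream_seed(seed, "folds"))
  n_bins <- dim(features$counts)[3]
  acc <- vapply(seq_len(n_bins), function(b) {
    X <- features$counts[, , b, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      if (nlevels(droplevels(labels[tr])) < 2) next
      m <- e1071::svm(Xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
      correct <- correct + sum(predict(m, Xte) == labels[te])
    }
    correct / n_tr
  }, numeric(1))
  in_win <- features$bin_t >= window[1] & features$bin_t <= window[2]
  structure(list(
    accuracy = tibble::tibble(bin_t = features$bin_t, accuracy = acc),
    window_accuracy = mean(acc[in_win]),
    fold_assignment = fold, seed = seed,
    shuffled = shuffle_labels
  ), class = "wt_decoding")
}
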