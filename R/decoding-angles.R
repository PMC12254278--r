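#' Aperture decoding from whisker-angle trajectories
#'
#' Binary classification of per-trial whisker angle trajectories (by
#' default 20 frames before to 100 frames after touch at 240 fps) with a
#' smooth additive logistic model: each per-frame angle enters through a
#' natural-spline basis (`df` functions per frame) and the additive model
#' is fitted with an elastic-net penalized logistic regression,
#' cross-validated on the training split only. The data are split 80/20
#' into training and test sets; the ROC curve on the test set carries
#' pointwise 95% confidence intervals from `n_boot` bootstrap resamples.
#' `shuffle_labels = TRUE` permutes the labels before training (chance
#' control).
#'
#' @param trajectories Numeric matrix, trials x frames.
#' @param labels Character or factor vector of trial labels (two classes).
#' @param split Training fraction.
#' @param df Spline basis functions per frame.
#' @param n_boot Bootstrap resamples for the pointwise ROC CIs.
#' @param shuffle_labels Permute labels before training.
#' @param seed Integer seed.
#' @return A `wt_roc_decoding` list: `accuracy`, `auc`, `auc_ci`
#'   (bootstrap 95%), `roc` tibble (`specificity`, `sensitivity`, with
#'   pointwise `lo` / `hi`), `n_test`, `seed`.
#' @export
decode_whisker_angles <- function(trajectories, labels, split = 0.8,
                                  df = 3, n_boot = 100,
                                  shuffle_labels = FALSE, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("need two label classes to decode")
  n <- nrow(trajectories)
  if (shuffle_labels) {
    labels <- with_seed(substream_seed(seed, "shuffle"), sample(labels))
  }
  idx_tr <- with_seed(substream_seed(seed, "split"), {
    unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      sample(i, round(split * length(i)))
    }))
  })
  te <- setdiff(seq_len(n), idx_tr)
  # per-frame natural-spline expansion; knots from the training data only
  basis <- lapply(seq_len(ncol(trajectories)), function(j) {
    b <- splines::ns(trajectories[idx_tr, j], df = df)
    list(train = b,
         test = predict(b, trajectories[te, j]))
  })
  Xtr <- do.call(cbind, lapply(basis, `[[`, "train"))
  Xte <- do.call(cbind, lapply(basis, `[[`, "test"))
  cvfit <- with_seed(substream_seed(seed, "glmnet"), {
    glmnet::cv.glmnet(Xtr, labels[idx_tr], family = "binomial",
                      nfolds = 5, alpha = 0.5)
  })
  prob <- as.numeric(predict(cvfit, Xte, s = "lambda.min",
                             type = "response"))
  truth <- labels[te]
  pred <- factor(levels(labels)[1 + (prob > 0.5)], levels = levels(labels))
  accuracy <- mean(pred == truth)
  roc_obj <- pROC::roc(response = truth, predictor = prob,
                       levels = levels(labels), direction = "<",
                       quiet = TRUE)
  spec_grid <- seq(0, 1, by = 0.05)
  ci <- with_seed(substream_seed(seed, "boot"), {
    tryCatch(suppressWarnings(
      pROC::ci.se(roc_obj, specificities = spec_grid,
                  boot.n = n_boot, conf.level = 0.95)),
      error = function(e) NULL)
  })
  auc_ci <- with_seed(substream_seed(seed, "bootauc"), {
    tryCatch(suppressWarnings(
      as.numeric(pROC::ci.auc(roc_obj, method = "bootstrap",
                              boot.n = n_boot))),
      error = function(e) rep(NA_real_, 3))
  })
  roc_tbl <- tibble::tibble(
    specificity = spec_grid,
    sensitivity = if (!is.null(ci)) ci[, 2] else NA_real_,
    lo = if (!is.null(ci)) ci[, 1] else NA_real_,
    hi = if (!is.null(ci)) ci[, 3] else NA_real_
  )
  structure(list(accuracy = accuracy, auc = as.numeric(roc_obj$auc),
                 auc_ci = auc_ci[c(1, 3)], roc = roc_tbl,
                 n_test = length(te), seed = seed,
                 shuffled = shuffle_labels),
            class = "wt_roc_decoding")
}
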