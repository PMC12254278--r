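#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a lick-latency fit
#' @param x A `wt_lick_fit` object.
#' @param ... Unused.
#' @return One row per parameter (`a`, `b`, `c`) with its estimate.
#' @export
tidy.wt_lick_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.wt_lick_fit
#' @export
glance.wt_lick_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), converged = x$converged)
}

#' Tidy a logistic learning-curve fit
#' @param x A `wt_learning_fit` object.
#' @param ... Unused.
#' @return One row per parameter (floor, ceiling, midpoint, slope).
#' @export
tidy.wt_learning_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.wt_learning_fit
#' @export
glance.wt_learning_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), converged = x$converged,
                 learning_speed = unname(x$params["slope"]))
}

#' Tidy a time-resolved decoding result
#' @param x A `wt_decoding` object.
#' @param ... Unused.
#' @return The per-timepoint accuracy tibble.
#' @export
tidy.wt_decoding <- function(x, ...) x$accuracy

#' @rdname tidy.wt_decoding
#' @export
glance.wt_decoding <- function(x, ...) {
  tibble::tibble(window_accuracy = x$window_accuracy,
                 n_folds = max(x$fold_assignment),
                 shuffled = x$shuffled, seed = x$seed)
}

#' Tidy an ROC decoding result
#' @param x A `wt_roc_decoding` object.
#' @param ... Unused.
#' @return The ROC tibble with pointwise confidence bounds.
#' @export
tidy.wt_roc_decoding <- function(x, ...) x$roc

#' @rdname tidy.wt_roc_decoding
#' @export
glance.wt_roc_decoding <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc,
                 auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 n_test = x$n_test, shuffled = x$shuffled, seed = x$seed)
}

#' Summarize a CNN decoding result
#' @param x A `wt_cnn_decoding` object.
#' @param ... Unused.
#' @export
glance.wt_cnn_decoding <- function(x, ...) {
  tibble::tibble(val_accuracy = x$val_accuracy,
                 train_accuracy = x$train_accuracy,
                 final_loss = x$loss_history[length(x$loss_history)],
                 n_train = x$n_train, n_val = x$n_val, seed = x$seed)
}
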