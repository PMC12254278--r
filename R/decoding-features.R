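#' Build a trial feature set of binned spike counts
#'
#' Aligns spikes to each trial's touch time (t = 0) and counts them per
#' unit in `bin_s` bins across `window`. The result feeds
#' [decode_spikes()].
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param trials Tibble with `t_touch` and `label` (`"wide"`/`"narrow"`).
#' @param window Length-2 numeric, window around touch (s).
#' @param bin_s Bin width (s).
#' @return A `wt_trial_features` list: `counts` (array trials x units x
#'   bins), `labels`, `bin_t` (bin centers, s), `unit_ids`.
#' @export
spike_trial_features <- function(spikes, trials, window = c(-0.8, 0.4),
                                 bin_s = 0.05) {
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  unit_ids <- sort(unique(spikes$unit_id))
  n_tr <- nrow(trials)
  counts <- array(0L, dim = c(n_tr, length(unit_ids), n_bins))
  for (ui in seq_along(unit_ids)) {
    ts <- spikes$t[spikes$unit_id == unit_ids[ui]]
    for (k in seq_len(n_tr)) {
      rel <- ts - trials$t_touch[k]
      rel <- rel[rel >= window[1] & rel < window[2]]
      counts[k, ui, ] <- tabulate(findInterval(rel, edges), nbins = n_bins)
    }
  }
  structure(list(counts = counts, labels = trials$label,
                 bin_t = edges[-1] - bin_s / 2, unit_ids = unit_ids),
            class = "wt_trial_features")
}

# Stratified fold assignment (balanced label proportions per fold).
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}
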