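#' Circular-shift shuffle null for a spike train
#'
#' Each shuffle shifts all spike times by a random interval drawn
#' uniformly from \[0, duration) and wraps times past the end back to the
#' beginning. Spike counts and the internal firing structure are preserved
#' exactly (the ISI multiset changes only at the single wrap point) while
#' the spikes are decoupled from behavior.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param duration Total recording duration (s).
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @return A list of `n_shuffles` sorted numeric vectors.
#' @export
circular_shift_null <- function(spike_times, duration, n_shuffles = 100,
                                seed = 1) {
  shifts <- with_seed(seed, runif(n_shuffles, 0, duration))
  purrr::map(shifts, ~ sort((spike_times + .x) %% duration))
}

# Total duration and a membership test for one segment family.
segment_family <- function(segments, label) {
  seg <- segments[segments$label == label, ]
  if (!nrow(seg)) abort(sprintf("no '%s' segments", label))
  seg <- seg[order(seg$t_start), ]
  list(
    total_s = sum(seg$t_end - seg$t_start),
    contains = function(t) {
      k <- findInterval(t, seg$t_start)
      k >= 1 & t < seg$t_end[pmax(k, 1)]
    }
  )
}

#' Firing-rate modulation between two behavioral states
#'
#' Rates are spikes-in-segments divided by total segment time for each
#' state. The absolute observed rate difference is compared with the 95th
#' percentile of absolute differences under the circular-shift shuffle
#' null; significant units are labeled `"enhanced"` (higher rate in
#' `state_a`) or `"suppressed"`.
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param segments A `wt_segments` tibble containing both state families.
#' @param state_a,state_b Segment labels to compare (e.g. `"locomotion"`
#'   vs `"rest"`, or `"whisking"` vs `"quiescent"`).
#' @param duration Recording duration (s) for the shuffles.
#' @param n_shuffles,seed Shuffle-null parameters.
#' @return A tibble with one row per unit: `unit_id`, `rate_a`, `rate_b`,
#'   `diff`, `null_95th`, `significant`, `direction`.
#' @export
state_rate_modulation <- function(spikes, segments, state_a = "locomotion",
                                  state_b = "rest", duration,
                                  n_shuffles = 100, seed = 1) {
  fa <- segment_family(segments, state_a)
  fb <- segment_family(segments, state_b)
  units <- unique(spikes$unit_id)
  purrr::map(seq_along(units), function(ui) {
    ts <- spikes$t[spikes$unit_id == units[ui]]
    rate_a <- sum(fa$contains(ts)) / fa$total_s
    rate_b <- sum(fb$contains(ts)) / fb$total_s
    obs <- rate_a - rate_b
    shifts <- with_seed(substream_seed(seed, paste0("state_", units[ui])),
                        runif(n_shuffles, 0, duration))
    null_abs <- vapply(shifts, function(s) {
      tsh <- (ts + s) %% duration
      abs(sum(fa$contains(tsh)) / fa$total_s -
            sum(fb$contains(tsh)) / fb$total_s)
    }, numeric(1))
    q95 <- quantile(null_abs, 0.95, names = FALSE)
    tibble::tibble(
      unit_id = units[ui], rate_a = rate_a, rate_b = rate_b, diff = obs,
      null_95th = q95, significant = abs(obs) > q95,
      direction = dplyr::case_when(
        abs(obs) <= q95 ~ "none",
        obs > 0 ~ "enhanced",
        TRUE ~ "suppressed"
      )
    )
  }) |> dplyr::bind_rows()
}
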