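#' Response onset latency from a Poisson baseline model
#'
#' Trial-aligned spike counts are binned at 1 ms after touch onset and
#' summed across trials. The baseline rate is estimated in a pre-stimulus
#' window (default 800 to 600 ms before touch). The onset latency is the
#' first bin within the 200 ms search window whose summed count exceeds
#' the baseline expectation under a Poisson model at `p <= alpha`
#' (upper tail only, so purely inhibited responses yield no latency). No
#' correction across the 200 bins is applied by default (each bin is
#' tested at `alpha`); `bonferroni = TRUE` divides alpha by the bin count.
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param touch_times Touch event times (s); at least 10 required.
#' @param baseline_window Length-2 numeric, baseline window relative to
#'   touch (s).
#' @param search_s Post-touch search window (s).
#' @param bin_s PSTH bin width (s).
#' @param alpha Per-bin significance level.
#' @param bonferroni Apply Bonferroni correction over bins.
#' @param baseline_floor_hz Baseline rate floor applied (with a flag) when
#'   the baseline window contains no spikes.
#' @return A tibble with one row per unit: `unit_id`, `latency_ms`
#'   (integer, `NA` if no significant bin), `baseline_rate` (Hz),
#'   `p_at_onset`, `baseline_floored`.
#' @export
onset_latency <- function(spikes, touch_times,
                          baseline_window = c(-0.8, -0.6), search_s = 0.2,
                          bin_s = 0.001, alpha = 0.05, bonferroni = FALSE,
                          baseline_floor_hz = 0.1) {
  if (length(touch_times) < 10) abort("need at least 10 touch events")
  n_trials <- length(touch_times)
  n_bins <- round(search_s / bin_s)
  a <- if (bonferroni) alpha / n_bins else alpha
  base_dur <- diff(baseline_window)
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise({
      ts <- .data$t
      rel <- as.vector(outer(ts, touch_times, "-"))
      base_n <- sum(rel >= baseline_window[1] & rel < baseline_window[2])
      baseline_rate <- base_n / (base_dur * n_trials)
      floored <- baseline_rate == 0
      if (floored) baseline_rate <- baseline_floor_hz
      post <- rel[rel > 0 & rel <= search_s]
      counts <- tabulate(ceiling(post / bin_s), nbins = n_bins)
      mu <- baseline_rate * n_trials * bin_s
      p <- ppois(counts - 1, mu, lower.tail = FALSE)
      hit <- which(p <= a)
      tibble::tibble(
        latency_ms = if (length(hit)) as.integer(hit[1]) else NA_integer_,
        baseline_rate = baseline_rate,
        p_at_onset = if (length(hit)) p[hit[1]] else NA_real_,
        baseline_floored = floored
      )
    }, .groups = "drop")
}

#' Touch modulation of spiking activity, per aperture
#'
#' For each unit and each aperture state, per-trial spike counts in a
#' 200 ms response window after touch are compared with counts in an
#' equally long baseline window before touch using a two-sided Wilcoxon
#' signed rank test; a significant *increase* additionally requires a
#' positive median paired difference. Units are categorized as
#' `"wide-only"`, `"narrow-only"`, `"both"` or `"none"`.
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param touches Tibble with `t` (touch times) and `aperture`
#'   (`"wide"`/`"narrow"`).
#' @param response_s,baseline_s Window lengths (s).
#' @param alpha Significance level.
#' @return A tibble with one row per unit: `unit_id`, `p_wide`,
#'   `p_narrow`, `sig_wide`, `sig_narrow`, `category`.
#' @export
touch_modulation_ephys <- function(spikes, touches, response_s = 0.2,
                                   baseline_s = 0.2, alpha = 0.05) {
  test_aperture <- function(ts, tt) {
    if (!length(tt)) return(list(p = NA_real_, sig = FALSE))
    base <- vapply(tt, function(x)
      sum(ts > x - baseline_s & ts <= x), numeric(1))
    resp <- vapply(tt, function(x)
      sum(ts > x & ts <= x + response_s), numeric(1))
    d <- resp - base
    if (all(d == 0)) return(list(p = 1, sig = FALSE))
    p <- suppressWarnings(
      wilcox.test(resp, base, paired = TRUE, exact = FALSE)$p.value)
    list(p = p, sig = !is.na(p) && p <= alpha && median(d) > 0)
  }
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise({
      ts <- .data$t
      w <- test_aperture(ts, touches$t[touches$aperture == "wide"])
      n <- test_aperture(ts, touches$t[touches$aperture == "narrow"])
      tibble::tibble(
        p_wide = w$p, p_narrow = n$p,
        sig_wide = w$sig, sig_narrow = n$sig,
        category = dplyr::case_when(
          w$sig & n$sig ~ "both",
          w$sig ~ "wide-only",
          n$sig ~ "narrow-only",
          TRUE ~ "none"
        )
      )
    }, .groups = "drop")
}

#' Touch modulation of calcium activity
#'
#' Per touch, the summed dF/F over a 400 ms window (12 frames at 30 Hz)
#' before the touch is compared with the sum over the matching window
#' after it, with a paired two-tailed t-test per unit. Windows are
#' converted by time, so sampling rates other than 30 Hz are handled
#' correctly.
#'
#' @param calcium A `wt_calcium` tibble (`unit_id`, `t`, `dff`).
#' @param touch_times Touch event times (s).
#' @param window_s Window length on each side of the touch (s).
#' @param alpha Significance level.
#' @return A tibble with one row per unit: `unit_id`, `p_value`,
#'   `mean_diff`, `significant`.
#' @export
touch_modulation_calcium <- function(calcium, touch_times, window_s = 0.4,
                                     alpha = 0.05) {
  fps <- attr(calcium, "fps") %||% (1 / median(diff(unique(calcium$t))))
  n_frames <- round(window_s * fps)
  calcium |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise({
      tt <- .data$t; dff <- .data$dff
      sums <- purrr::map(touch_times, function(x) {
        i0 <- which.min(abs(tt - x))
        pre_i <- seq(i0 - n_frames, i0 - 1)
        post_i <- seq(i0, i0 + n_frames - 1)
        if (min(pre_i) < 1 || max(post_i) > length(dff)) return(NULL)
        c(pre = sum(dff[pre_i]), post = sum(dff[post_i]))
      })
      sums <- do.call(rbind, purrr::compact(sums))
      if (is.null(sums) || nrow(sums) < 3 || sd(sums[, "post"] - sums[, "pre"]) == 0) {
        tibble::tibble(p_value = NA_real_, mean_diff = NA_real_,
                       significant = FALSE)
      } else {
        ht <- t.test(sums[, "post"], sums[, "pre"], paired = TRUE)
        tibble::tibble(p_value = ht$p.value,
                       mean_diff = mean(sums[, "post"] - sums[, "pre"]),
                       significant = ht$p.value <= alpha)
      }
    }, .groups = "drop")
}
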