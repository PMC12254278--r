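# Map spike times onto trace frame indices (1-based; NA outside the trace).
spike_frames <- function(t_spk, n_frames, fps) {
  idx <- round(t_spk * fps)
  idx[idx < 1 | idx > n_frames] <- NA_integer_
  as.integer(idx)
}

depth_from_counts <- function(counts, occ_s, keep) {
  rates <- counts[keep] / occ_s[keep]
  r_mean <- mean(rates)
  if (r_mean <= 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  c(max(rates), min(rates), r_mean, (max(rates) - min(rates)) / r_mean)
}

#' Whisking-angle (or head-angle) tuning with a shuffle null
#'
#' Bins the angle trace into `bin_deg` intervals over `range_deg`
#' (defaults: 5 degree bins from 0, maximal retraction, to 180, maximal
#' protraction; use `c(-90, 90)` for head azimuth), computes the firing
#' rate per bin as spikes divided by time in the bin, and quantifies
#' modulation depth as (r_max - r_min) / r_mean. Spikes and frames during
#' or within `exclusion_s` of touch events are excluded. Significance:
#' depth above the 95th percentile of depths from the circular-shift
#' shuffle null. Bins with occupancy below `min_occupancy_s` are excluded
#' from the depth; units with undefined mean rate are returned with `NA`
#' depth.
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param angle_trace A `wt_angle_trace` (`t`, `angle`).
#' @param bin_deg Bin width (degrees).
#' @param range_deg Angle range covered by the bins.
#' @param touch_times Touch event times (s).
#' @param exclusion_s Touch exclusion half-width (s).
#' @param min_occupancy_s Minimum per-bin occupancy (s).
#' @param n_shuffles,seed Shuffle-null parameters.
#' @param duration Recording duration (s); defaults to the trace end.
#' @return A `wt_angle_tuning` tibble, one row per unit: `unit_id`,
#'   `r_max`, `r_min`, `r_mean`, `modulation_depth`, `null_95th`,
#'   `significant`, `peak_angle_deg`, and a list-column `curve`
#'   (tibble of bin centers and rates).
#' @export
angle_tuning <- function(spikes, angle_trace, bin_deg = 5,
                         range_deg = c(0, 180), touch_times = NULL,
                         exclusion_s = 0.1, min_occupancy_s = 0.5,
                         n_shuffles = 100, seed = 1, duration = NULL) {
  fps <- trace_fps(angle_trace)
  touch_times <- touch_times %||% attr(angle_trace, "touch_times") %||%
    numeric(0)
  duration <- duration %||% max(angle_trace$t)
  n <- nrow(angle_trace)
  edges <- seq(range_deg[1], range_deg[2], by = bin_deg)
  n_bins <- length(edges) - 1L
  centers <- edges[-1] - bin_deg / 2
  # frame validity and frame -> bin map
  valid <- !is.na(angle_trace$angle)
  for (tt in touch_times) {
    valid <- valid & !(angle_trace$t >= tt - exclusion_s &
                         angle_trace$t <= tt + exclusion_s)
  }
  fbin <- findInterval(angle_trace$angle, edges, rightmost.closed = TRUE)
  fbin[fbin < 1 | fbin > n_bins] <- NA_integer_
  fbin[!valid] <- NA_integer_
  occ_s <- tabulate(fbin[!is.na(fbin)], nbins = n_bins) / fps
  keep <- occ_s >= min_occupancy_s
  units <- unique(spikes$unit_id)
  purrr::map(units, function(u) {
    ts <- spikes$t[spikes$unit_id == u]
    sf <- spike_frames(ts, n, fps)
    sb <- fbin[sf]
    counts <- tabulate(sb[!is.na(sb)], nbins = n_bins)
    obs <- depth_from_counts(counts, occ_s, keep)
    if (is.na(obs[4])) {
      return(tibble::tibble(unit_id = u, r_max = NA_real_, r_min = NA_real_,
                            r_mean = NA_real_, modulation_depth = NA_real_,
                            null_95th = NA_real_, significant = FALSE,
                            peak_angle_deg = NA_real_,
                            curve = list(tibble::tibble())))
    }
    shifts <- with_seed(substream_seed(seed, paste0("angle_", u)),
                        runif(n_shuffles, 0, duration))
    null_depth <- vapply(shifts, function(s) {
      sfh <- spike_frames((ts + s) %% duration, n, fps)
      sbh <- fbin[sfh]
      depth_from_counts(tabulate(sbh[!is.na(sbh)], nbins = n_bins),
                        occ_s, keep)[4]
    }, numeric(1))
    q95 <- quantile(null_depth, 0.95, na.rm = TRUE, names = FALSE)
    rates <- rep(NA_real_, n_bins)
    rates[keep] <- counts[keep] / occ_s[keep]
    tibble::tibble(
      unit_id = u, r_max = obs[1], r_min = obs[2], r_mean = obs[3],
      modulation_depth = obs[4], null_95th = q95,
      significant = is.finite(q95) && obs[4] > q95,
      peak_angle_deg = centers[keep][which.max(rates[keep])],
      curve = list(tibble::tibble(angle_deg = centers, rate_hz = rates,
                                  occupancy_s = occ_s))
    )
  }) |> dplyr::bind_rows() |> new_wt_tbl(class = "wt_angle_tuning")
}
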