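#' Kuiper one-sample test of circular uniformity
#'
#' Tests whether angles on \[0, 2pi) are uniformly distributed, using the
#' rotation-invariant Kuiper statistic V = D+ + D- and the standard
#' asymptotic tail series with the finite-sample stretch factor
#' (sqrt(n) + 0.155 + 0.24 / sqrt(n)).
#'
#' @param angles Numeric vector of angles in radians.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
kuiper_test <- function(angles) {
  x <- sort((angles %% (2 * pi)) / (2 * pi))
  n <- length(x)
  if (n < 5) abort("need at least 5 angles")
  i <- seq_len(n)
  d_plus <- max(i / n - x)
  d_minus <- max(x - (i - 1) / n)
  v <- d_plus + d_minus
  lambda <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * v
  m <- 1:100
  p <- 2 * sum((4 * m^2 * lambda^2 - 1) * exp(-2 * m^2 * lambda^2))
  list(statistic = v, p_value = min(max(p, 0), 1))
}

#' Whisking-phase tuning via sine fit
#'
#' Each whisk cycle is divided into `n_bins` phase bins spanning 2pi;
#' firing rates per bin are fitted with a sine wave of period 2pi by
#' standard linear least squares:
#' lambda(phi) = <lambda> + Amp cos(phi - phi_preferred),
#' solved via the regression of bin rates on (cos phi, sin phi). The
#' signal-to-noise ratio is SNR = 2 Amp sqrt(T / <lambda>) with T the
#' Poisson temporal window estimated from the average whisk cycle
#' (0.111 s). phi_preferred = 0 corresponds to full retraction and pi to
#' full protraction. Significance is a Kuiper test of the spike phases
#' against circular uniformity (`kuiper_on = "spikes"`, default) or of
#' the binned-rate distribution (`"bins"`).
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param phase_trace A `wt_phase_trace` (`t`, `phase`; `NA` outside
#'   whisking).
#' @param n_bins Number of phase bins per cycle.
#' @param T_s Poisson temporal window for the SNR (s).
#' @param kuiper_on `"spikes"` or `"bins"`.
#' @return A `wt_phase_tuning` tibble, one row per unit: `unit_id`,
#'   `mean_rate`, `amp`, `phase_pref`, `snr`, `kuiper_stat`, `kuiper_p`,
#'   `n_spikes`, plus a `curve` list-column of bin centers and rates.
#' @export
phase_tuning <- function(spikes, phase_trace, n_bins = 32, T_s = 0.111,
                         kuiper_on = c("spikes", "bins")) {
  kuiper_on <- match.arg(kuiper_on)
  fps <- trace_fps(phase_trace)
  n <- nrow(phase_trace)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  centers <- edges[-1] - pi / n_bins
  fbin <- findInterval(phase_trace$phase, edges, rightmost.closed = TRUE)
  fbin[fbin < 1 | fbin > n_bins] <- NA_integer_
  occ_s <- tabulate(fbin[!is.na(fbin)], nbins = n_bins) / fps
  if (sum(occ_s > 0) < 2) abort("fewer than 2 occupied phase bins")
  units <- unique(spikes$unit_id)
  purrr::map(units, function(u) {
    ts <- spikes$t[spikes$unit_id == u]
    sf <- spike_frames(ts, n, fps)
    sb <- fbin[sf]
    spike_phase <- phase_trace$phase[sf]
    ok_spk <- !is.na(sb)
    counts <- tabulate(sb[ok_spk], nbins = n_bins)
    occupied <- occ_s > 0
    rates <- counts[occupied] / occ_s[occupied]
    X <- cbind(1, cos(centers[occupied]), sin(centers[occupied]))
    beta <- stats::lm.fit(X, rates)$coefficients
    amp <- sqrt(beta[2]^2 + beta[3]^2)
    phase_pref <- atan2(beta[3], beta[2]) %% (2 * pi)
    mean_rate <- beta[1]
    snr <- if (mean_rate > 0) 2 * amp * sqrt(T_s / mean_rate) else NA_real_
    kp <- if (kuiper_on == "spikes") {
      if (sum(ok_spk) >= 5) kuiper_test(spike_phase[ok_spk])
      else list(statistic = NA_real_, p_value = NA_real_)
    } else {
      # binned-rate variant: resample spike-equivalent phases in
      # proportion to the occupancy-corrected rates
      w <- pmax(counts, 0) / pmax(occ_s, 1e-9)
      w <- w / sum(w)
      reps <- round(w * max(sum(counts), n_bins))
      if (sum(reps) >= 5) kuiper_test(rep(centers, reps))
      else list(statistic = NA_real_, p_value = NA_real_)
    }
    full_rates <- rep(NA_real_, n_bins)
    full_rates[occupied] <- counts[occupied] / occ_s[occupied]
    tibble::tibble(
      unit_id = u, mean_rate = unname(mean_rate), amp = unname(amp),
      phase_pref = unname(phase_pref), snr = unname(snr),
      kuiper_stat = kp$statistic, kuiper_p = kp$p_value,
      n_spikes = sum(ok_spk),
      curve = list(tibble::tibble(phase = centers, rate_hz = full_rates,
                                  occupancy_s = occ_s))
    )
  }) |> dplyr::bind_rows() |> new_wt_tbl(class = "wt_phase_tuning")
}

#' Fit the sine model to an already-binned phase profile
#'
#' Convenience for noiseless checks and plotting: given per-bin rates,
#' returns the linear-least-squares estimates of mean rate, modulation
#' amplitude, preferred phase, and SNR.
#'
#' @param phase Bin-center phases (radians).
#' @param rates Firing rate per bin (Hz).
#' @param T_s Poisson temporal window (s).
#' @return A one-row tibble with `mean_rate`, `amp`, `phase_pref`, `snr`.
#' @export
fit_phase_profile <- function(phase, rates, T_s = 0.111) {
  X <- cbind(1, cos(phase), sin(phase))
  beta <- stats::lm.fit(X, rates)$coefficients
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  tibble::tibble(
    mean_rate = unname(beta[1]), amp = unname(amp),
    phase_pref = unname(atan2(beta[3], beta[2]) %% (2 * pi)),
    snr = unname(2 * amp * sqrt(T_s / beta[1]))
  )
}

#' Population vector of preferred phases
#'
#' Circular mean of the preferred phases of significant units, optionally
#' weighted by modulation amplitude.
#'
#' @param results A `wt_phase_tuning` tibble.
#' @param alpha Significance level on `kuiper_p` for inclusion.
#' @param amplitude_weighted Weight unit vectors by `amp`.
#' @return A list with `mean_phase` (radians in \[0, 2pi)),
#'   `resultant_length` (in \[0, 1\]), `n_units`.
#' @export
population_phase_vector <- function(results, alpha = 0.05,
                                    amplitude_weighted = FALSE) {
  sel <- !is.na(results$kuiper_p) & results$kuiper_p <= alpha
  ph <- results$phase_pref[sel]
  w <- if (amplitude_weighted) results$amp[sel] else rep(1, sum(sel))
  if (!length(ph)) {
    return(list(mean_phase = NA_real_, resultant_length = NA_real_,
                n_units = 0L))
  }
  z <- sum(w * exp(1i * ph)) / sum(w)
  list(mean_phase = Arg(z) %% (2 * pi), resultant_length = Mod(z),
       n_units = sum(sel))
}
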