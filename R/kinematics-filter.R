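#' Band-pass filter a whisker angle trace
#'
#' Zero-phase (forward-backward) Butterworth band-pass isolating the
#' whisking band. The default 2-30 Hz band removes both slow set-point
#' drift and tracking noise; DC is removed by construction. Applied
#' forward-backward the filter has no phase distortion, which matters for
#' the downstream Hilbert phase.
#'
#' @param trace A `wt_angle_trace` tibble (columns `t`, `angle`).
#' @param lo,hi Band edges in Hz; the sampling rate must exceed `2 * hi`.
#' @param order Effective Butterworth order (default 4).
#' @return The trace with `angle` replaced by the filtered signal (zero
#'   mean), same length.
#' @export
bandpass_whisker <- function(trace, lo = 2, hi = 30, order = 4) {
  fps <- trace_fps(trace)
  if (fps < 2 * hi) {
    abort(sprintf("sampling rate %.1f Hz is below 2 x upper band edge (%g Hz)",
                  fps, hi))
  }
  bf <- signal::butter(order / 2, c(lo, hi) / (fps / 2), type = "pass")
  x <- trace$angle - mean(trace$angle)
  out <- trace
  out$angle <- as.numeric(signal::filtfilt(bf, x))
  attr(out, "band_hz") <- c(lo, hi)
  out
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, inverse-transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous whisking phase via the Hilbert transform
#'
#' Extracts the analytic-signal angle of the band-passed whisker trace and
#' maps it to \[0, 2pi) with the convention that phase 0 corresponds to
#' full retraction and phase pi to full protraction (the protraction peak
#' of the filtered angle).
#'
#' @param filtered A band-passed `wt_angle_trace` (see
#'   [bandpass_whisker()]).
#' @return A `wt_phase_trace` tibble with columns `t`, `phase` (radians in
#'   \[0, 2pi), all `NA` with a warning for an all-zero input).
#' @export
whisking_phase <- function(filtered) {
  x <- filtered$angle
  if (all(abs(x) < .Machine$double.eps * 100)) {
    warn("all-zero input: whisking phase undefined")
    return(new_wt_tbl(tibble::tibble(t = filtered$t,
                                     phase = rep(NA_real_, length(x))),
                      class = "wt_phase_trace", fps = trace_fps(filtered)))
  }
  z <- analytic_signal(x)
  # Arg(z) = 0 at the protraction peak; shift so protraction maps to pi
  phase <- (atan2(Im(z), Re(z)) + pi) %% (2 * pi)
  new_wt_tbl(tibble::tibble(t = filtered$t, phase = phase),
             class = "wt_phase_trace", fps = trace_fps(filtered))
}

# Running max/min over a centered window of `w` samples, O(n w) by shifted
# pmax/pmin; edge windows are truncated to the available samples.
run_extreme <- function(x, w, max = TRUE) {
  n <- length(x)
  half <- w %/% 2
  acc <- x
  for (k in seq_len(half)) {
    lead <- c(x[-seq_len(k)], rep(NA, k))
    lag <- c(rep(NA, k), x[seq_len(n - k)])
    acc <- if (max) pmax(acc, lead, lag, na.rm = TRUE)
           else pmin(acc, lead, lag, na.rm = TRUE)
  }
  acc
}

#' Whisking amplitude (peak-to-peak in a moving window)
#'
#' Per-frame peak-to-peak angle within a centered window (default 100 ms,
#' i.e. a 50 ms margin before and after each time point). Edge frames are
#' computed on the truncated window and flagged.
#'
#' @param trace A `wt_angle_trace` (typically band-passed).
#' @param window_s Window length in seconds; must cover >= 3 samples.
#' @return A tibble with `t`, `amplitude` (degrees), `truncated` (logical).
#' @export
whisking_amplitude <- function(trace, window_s = 0.1) {
  fps <- trace_fps(trace)
  w <- 2L * floor(window_s * fps / 2) + 1L
  if (w < 3) abort("window shorter than 3 samples")
  n <- nrow(trace)
  amp <- run_extreme(trace$angle, w, max = TRUE) -
    run_extreme(trace$angle, w, max = FALSE)
  half <- w %/% 2
  truncated <- seq_len(n) <= half | seq_len(n) > n - half
  tibble::tibble(t = trace$t, amplitude = amp, truncated = truncated)
}

# Unwrap a phase series (radians): cumulative sum of wrapped increments.
unwrap_phase <- function(phase) {
  d <- diff(phase)
  d <- (d + pi) %% (2 * pi) - pi
  c(phase[1], phase[1] + cumsum(d))
}

#' Whisk-cycle counts and frequency per trial window
#'
#' Cycles are full 2pi progressions of the unwrapped Hilbert phase inside
#' each window; frequency is cycles per second of window duration.
#'
#' Phase only advances while the whisking amplitude exceeds `min_amp_deg`,
#' so quiescent (sub-threshold) stretches contribute no cycles.
#'
#' @param filtered A band-passed `wt_angle_trace`.
#' @param trial_windows Tibble with `t_start`, `t_end` (s).
#' @param min_amp_deg Minimum peak-to-peak amplitude for a frame's phase
#'   increment to count toward a cycle.
#' @return A tibble with one row per window: `t_start`, `t_end`, `cycles`,
#'   `duration_s`, `freq_hz`.
#' @export
whisk_cycle_stats <- function(filtered, trial_windows, min_amp_deg = 3) {
  ph <- whisking_phase(filtered)
  amp <- whisking_amplitude(filtered)$amplitude
  purrr::pmap(trial_windows[, c("t_start", "t_end")],
              function(t_start, t_end) {
    sel <- which(ph$t >= t_start & ph$t <= t_end)
    cyc <- 0
    if (length(sel) >= 2 && !anyNA(ph$phase[sel])) {
      d <- diff(unwrap_phase(ph$phase[sel]))
      d[amp[sel[-1]] < min_amp_deg] <- 0
      cyc <- max(0, floor(abs(sum(d)) / (2 * pi)))
    }
    tibble::tibble(t_start = t_start, t_end = t_end, cycles = cyc,
                   duration_s = t_end - t_start,
                   freq_hz = cyc / (t_end - t_start))
  }) |> dplyr::bind_rows()
}
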