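#' Simulate a whisker angle trace for a session
#'
#' Produces a 240 Hz whisker angle time series spanning the session:
#' alternating whisking bouts (a sinusoidal oscillation at `whisk_freq_hz`
#' with peak-to-peak amplitude `amp_deg` around `mid_deg`) and quiescent
#' bouts (slow sub-3 degree jitter), plus an exponential touch-locked
#' deflection transient at each trial's touch time. The angle convention is
#' 0 deg = maximal retraction, 180 deg = maximal protraction; output is
#' clipped to [0, 180].
#'
#' The returned tibble carries ground-truth columns: `whisking` (logical,
#' inside a whisking bout) and `phase` (the generator's oscillator phase in
#' \[0, 2pi), with pi = full protraction; `NA` during quiescence).
#'
#' @param session A `wt_session` tibble (used for duration and touch times).
#' @param whisk_freq_hz Whisking frequency in Hz; must lie strictly inside
#'   the 2-30 Hz analysis band.
#' @param amp_deg Peak-to-peak whisking amplitude in degrees.
#' @param seed Integer seed.
#' @param fps Sampling rate (Hz).
#' @param mid_deg Set-point angle in degrees.
#' @param bout_dur_s,quiet_dur_s Uniform ranges (s) for whisking / quiescent
#'   bout durations; `quiet_dur_s = c(0, 0)` yields continuous whisking.
#' @param touch_deflection_deg Amplitude of the touch transient.
#' @return A `wt_angle_trace` tibble with columns `t`, `angle`, `whisking`,
#'   `phase` and attribute `fps`.
#' @export
generate_whisker_trace <- function(session, whisk_freq_hz = 14.5,
                                   amp_deg = 20, seed = 1, fps = 240,
                                   mid_deg = 90, bout_dur_s = c(1.5, 3.5),
                                   quiet_dur_s = c(0.5, 2),
                                   touch_deflection_deg = 10) {
  if (whisk_freq_hz <= 2 || whisk_freq_hz >= 30) {
    abort("whisk_freq_hz must lie strictly inside the 2-30 Hz analysis band")
  }
  duration <- max(session$t_touch, session$t_beam, session$t_lick,
                  na.rm = TRUE) + 5
  with_seed(substream_seed(seed, "whisker"), {
    n <- floor(duration * fps)
    t <- seq_len(n) / fps
    # alternating whisking / quiescent bouts
    whisking <- logical(n)
    if (all(quiet_dur_s == 0)) {
      whisking[] <- TRUE
    } else {
      pos <- 0
      state <- TRUE
      while (pos < duration) {
        rng <- if (state) bout_dur_s else quiet_dur_s
        d <- max(runif(1, rng[1], rng[2]), 1 / fps)
        i0 <- floor(pos * fps) + 1L
        i1 <- min(n, floor((pos + d) * fps))
        if (i1 >= i0) whisking[i0:i1] <- state
        pos <- pos + d
        state <- !state
      }
    }
    # oscillator phase advances only while whisking (frozen in quiescence)
    theta <- cumsum(ifelse(whisking, 2 * pi * whisk_freq_hz / fps, 0))
    osc <- (amp_deg / 2) * cos(theta)
    jitter <- stats::filter(rnorm(n, 0, 2), rep(1 / 25, 25), sides = 2)
    jitter[is.na(jitter)] <- 0
    angle <- mid_deg + ifelse(whisking, osc, as.numeric(jitter))
    # touch-locked deflection transients
    touches <- session$t_touch[!is.na(session$t_touch)]
    for (tt in touches) {
      i0 <- floor(tt * fps) + 1L
      if (i0 > n) next
      i1 <- min(n, i0 + floor(0.1 * fps))
      rel <- (seq(i0, i1) - i0) / fps
      angle[i0:i1] <- angle[i0:i1] + touch_deflection_deg * exp(-rel / 0.03)
    }
    angle <- pmin(180, pmax(0, angle))
    phase <- ifelse(whisking, (theta + pi) %% (2 * pi), NA_real_)
    new_wt_tbl(tibble::tibble(t = t, angle = angle, whisking = whisking,
                              phase = phase),
               class = "wt_angle_trace", fps = fps,
               touch_times = touches)
  })
}

#' Simulate a linear-track position trace
#'
#' Run-pause locomotion on an 820 mm linear track (x in \[-410, 410\] mm,
#' 0 at the middle beam): dwell segments near the track ends alternate with
#' straight runs at approximately `run_speed_mms`. Velocity is the centered
#' finite difference of position, median-filtered over 50 ms.
#'
#' @param session A `wt_session` tibble (duration source).
#' @param run_speed_mms Run speed in mm/s (> 0).
#' @param seed Integer seed.
#' @param fps Sampling rate (Hz).
#' @param dwell_dur_s Uniform range (s) for dwell durations at track ends.
#' @param dwell_only If `TRUE`, the mouse never runs (stationary at one
#'   end); useful as a negative control for locomotion detection.
#' @param track_half_mm Half track length; position is clipped to this.
#' @return A `wt_position_trace` tibble with columns `t`, `x`, `velocity`
#'   and attribute `fps`.
#' @export
generate_position_trace <- function(session, run_speed_mms = 300, seed = 1,
                                    fps = 60, dwell_dur_s = c(2, 6),
                                    dwell_only = FALSE,
                                    track_half_mm = 410) {
  if (run_speed_mms <= 0) abort("run_speed_mms must be > 0")
  duration <- max(session$t_touch, session$t_beam, session$t_lick,
                  na.rm = TRUE) + 5
  with_seed(substream_seed(seed, "position"), {
    n <- floor(duration * fps)
    t <- seq_len(n) / fps
    x <- numeric(n)
    if (dwell_only) {
      x[] <- -track_half_mm + rnorm(n, 0, 0.5)
    } else {
      pos <- 0
      cur_end <- -1 # start at left end
      xs <- numeric(0)
      while (length(xs) < n) {
        d_dwell <- runif(1, dwell_dur_s[1], dwell_dur_s[2])
        n_dwell <- max(1L, floor(d_dwell * fps))
        xs <- c(xs, cur_end * track_half_mm + rnorm(n_dwell, 0, 0.5))
        run_t <- 2 * track_half_mm / run_speed_mms
        n_run <- max(2L, floor(run_t * fps))
        ramp <- seq(cur_end, -cur_end, length.out = n_run) * track_half_mm
        xs <- c(xs, ramp + rnorm(n_run, 0, 0.5))
        cur_end <- -cur_end
      }
      x <- xs[seq_len(n)]
    }
    x <- pmin(track_half_mm, pmax(-track_half_mm, x))
    new_wt_tbl(tibble::tibble(t = t, x = x,
                              velocity = trace_velocity(x, fps)),
               class = "wt_position_trace", fps = fps)
  })
}

# Centered 3-point finite difference, then 50 ms median filter (robust to
# tracking jitter); endpoints use one-sided differences.
trace_velocity <- function(x, fps, median_s = 0.05) {
  n <- length(x)
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fps / 2
  v[1] <- (x[2] - x[1]) * fps
  v[n] <- (x[n] - x[n - 1]) * fps
  k <- max(3L, 2L * floor(median_s * fps / 2) + 1L)
  if (n > k) v <- stats::runmed(v, k, endrule = "keep")
  as.numeric(v)
}
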