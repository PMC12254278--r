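#' Ground-truth tuning specification for one simulated unit
#'
#' Defines the multiplicative rate model an inhomogeneous-Poisson unit is
#' generated from:
#' rate(t) = baseline x touch kernel x locomotion gain x von Mises angle
#' factor x (1 + (phase_amp / baseline) cos(phi(t) - phase_pref)) x
#' (1 + (place_amp / baseline) Gaussian(x; center, sigma)), clipped at 0.
#' All gains default to neutral (an untuned homogeneous unit).
#'
#' @param unit_id Unit identifier.
#' @param region Brain region label (`"BC"`, `"VPM"`, `"POm"`, `"ZIv"`).
#' @param baseline_rate Baseline firing rate (Hz, > 0).
#' @param touch_gain_wide,touch_gain_narrow Multiplicative gain during the
#'   200 ms window after touches of the wide / narrow aperture.
#' @param angle_pref_deg,angle_kappa Preferred whisker angle (deg, on
#'   \[0, 180\] mapped to a full circle) and von Mises concentration
#'   (0 = flat).
#' @param phase_amp,phase_pref Whisking-phase modulation amplitude (Hz,
#'   must not exceed `baseline_rate`) and preferred phase (rad).
#' @param place_center_mm,place_sigma_mm,place_amp Gaussian place field
#'   center (mm), width (mm, > 0) and amplitude (Hz).
#' @param locomotion_gain Multiplicative gain while speed exceeds
#'   `100` mm/s.
#' @param trough_to_peak_us,isolation_distance Waveform / QC metadata.
#' @return A one-row tibble of class `wt_tuning_spec`.
#' @export
tuning_spec <- function(unit_id = "u01", region = "BC", baseline_rate = 10,
                        touch_gain_wide = 1, touch_gain_narrow = 1,
                        angle_pref_deg = 90, angle_kappa = 0,
                        phase_amp = 0, phase_pref = pi,
                        place_center_mm = 0, place_sigma_mm = 40,
                        place_amp = 0, locomotion_gain = 1,
                        trough_to_peak_us = 450, isolation_distance = 25) {
  if (baseline_rate <= 0) abort("baseline_rate must be > 0")
  if (place_sigma_mm <= 0) abort("place_sigma_mm must be > 0")
  if (phase_amp > baseline_rate) {
    abort("phase_amp must not exceed baseline_rate (rate would go negative)")
  }
  out <- tibble::tibble(
    unit_id = unit_id, region = region, baseline_rate = baseline_rate,
    touch_gain_wide = touch_gain_wide, touch_gain_narrow = touch_gain_narrow,
    angle_pref_deg = angle_pref_deg, angle_kappa = angle_kappa,
    phase_amp = phase_amp, phase_pref = phase_pref,
    place_center_mm = place_center_mm, place_sigma_mm = place_sigma_mm,
    place_amp = place_amp, locomotion_gain = locomotion_gain,
    trough_to_peak_us = trough_to_peak_us,
    isolation_distance = isolation_distance
  )
  class(out) <- c("wt_tuning_spec", class(out))
  out
}

# Evaluate the ground-truth rate model of one spec on a time grid.
unit_rate_on_grid <- function(spec, grid_t, session, traces,
                              loco_thresh = 100, touch_window_s = 0.2) {
  rate <- rep(spec$baseline_rate, length(grid_t))
  # touch kernel: rectangular gain for 200 ms post-touch, aperture-specific
  if (!is.null(session)) {
    touched <- session[!is.na(session$t_touch), ]
    for (k in seq_len(nrow(touched))) {
      g <- if (touched$aperture_mm[k] >= 45) spec$touch_gain_wide
           else if (touched$aperture_mm[k] <= 25) spec$touch_gain_narrow
           else 1
      if (g != 1) {
        sel <- grid_t >= touched$t_touch[k] &
          grid_t < touched$t_touch[k] + touch_window_s
        rate[sel] <- rate[sel] * g
      }
    }
  }
  if (!is.null(traces$whisker) && spec$angle_kappa != 0) {
    ang <- stats::approx(traces$whisker$t, traces$whisker$angle, grid_t,
                         rule = 2)$y
    th <- ang * pi / 90        # [0,180] deg -> full circle
    th0 <- spec$angle_pref_deg * pi / 90
    vm <- exp(spec$angle_kappa * cos(th - th0)) /
      besselI(spec$angle_kappa, 0)
    rate <- rate * vm
  }
  if (!is.null(traces$whisker) && spec$phase_amp > 0) {
    ph <- stats::approx(traces$whisker$t, traces$whisker$phase, grid_t,
                        rule = 2)$y
    fac <- 1 + (spec$phase_amp / spec$baseline_rate) *
      cos(ph - spec$phase_pref)
    fac[is.na(fac)] <- 1       # quiescence: no phase modulation
    rate <- rate * fac
  }
  if (!is.null(traces$position)) {
    if (spec$locomotion_gain != 1) {
      v <- stats::approx(traces$position$t, abs(traces$position$velocity),
                         grid_t, rule = 2)$y
      rate <- rate * ifelse(v > loco_thresh, spec$locomotion_gain, 1)
    }
    if (spec$place_amp != 0) {
      x <- stats::approx(traces$position$t, traces$position$x, grid_t,
                         rule = 2)$y
      gauss <- exp(-(x - spec$place_center_mm)^2 /
                     (2 * spec$place_sigma_mm^2))
      rate <- rate * (1 + (spec$place_amp / spec$baseline_rate) * gauss)
    }
  }
  pmax(rate, 0)
}

#' Simulate spike trains from ground-truth tuning specs
#'
#' Generates one inhomogeneous-Poisson spike train per [tuning_spec()] row
#' by Bernoulli thinning on a `dt_s` grid of the multiplicative rate model.
#' Each unit draws from an independent reproducible sub-stream of `seed`.
#'
#' @param session A `wt_session` (touch times and aperture identities).
#' @param traces Named list with optional elements `whisker` (a
#'   `wt_angle_trace`) and `position` (a `wt_position_trace`).
#' @param specs A tibble of stacked [tuning_spec()] rows.
#' @param dt_s Thinning resolution in seconds (default 1 ms, matching the
#'   1 ms PSTH bin of the latency analysis). An error is raised if
#'   `max(rate) * dt_s > 0.1` (thinning validity).
#' @param seed Integer seed.
#' @param duration Recording duration (s); defaults to the session span.
#' @param touch_window_s Duration of the rectangular touch-gain kernel (s).
#' @return A list with `units` (metadata tibble: `unit_id`, `region`,
#'   `trough_to_peak_us`, `isolation_distance`, `recording_duration`) and
#'   `spikes` (tibble: `unit_id`, `t`).
#' @export
generate_spike_trains <- function(session, traces, specs, dt_s = 0.001,
                                  seed = 1, duration = NULL,
                                  touch_window_s = 0.2) {
  if (is.null(duration)) {
    duration <- max(session$t_touch, session$t_beam, session$t_lick,
                    na.rm = TRUE) + 5
  }
  grid_t <- seq(dt_s / 2, duration, by = dt_s)
  spikes <- purrr::map(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    rate <- unit_rate_on_grid(spec, grid_t, session, traces,
                              touch_window_s = touch_window_s)
    if (max(rate) * dt_s > 0.1) {
      abort(sprintf(
        "dt_s too coarse: max(rate)*dt_s = %.3f > 0.1; reduce dt_s",
        max(rate) * dt_s))
    }
    with_seed(substream_seed(seed, paste0("spikes_", spec$unit_id)), {
      fire <- runif(length(grid_t)) < rate * dt_s
      t_sp <- grid_t[fire] + runif(sum(fire), -dt_s / 2, dt_s / 2)
      tibble::tibble(unit_id = spec$unit_id, t = sort(t_sp))
    })
  })
  list(
    units = tibble::tibble(
      unit_id = specs$unit_id, region = specs$region,
      trough_to_peak_us = specs$trough_to_peak_us,
      isolation_distance = specs$isolation_distance,
      recording_duration = duration
    ),
    spikes = dplyr::bind_rows(spikes)
  )
}

#' Double-exponential calcium impulse response
#'
#' `amp * (exp(-t / tau_decay) - exp(-t / tau_rise))`, normalized so the
#' continuous-time peak equals `amp`; zero for `t < 0`.
#'
#' @param t Time since the spike (s).
#' @param tau_rise_s,tau_decay_s Rise / decay time constants (s), with
#'   `tau_decay_s > tau_rise_s`.
#' @param amp Peak amplitude (dF/F units).
#' @export
calcium_kernel <- function(t, tau_rise_s = 0.05, tau_decay_s = 0.4,
                           amp = 1) {
  if (tau_decay_s <= tau_rise_s) abort("tau_decay_s must exceed tau_rise_s")
  t_peak <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
    (tau_decay_s - tau_rise_s)
  peak <- exp(-t_peak / tau_decay_s) - exp(-t_peak / tau_rise_s)
  out <- (exp(-t / tau_decay_s) - exp(-t / tau_rise_s)) / peak * amp
  out[t < 0] <- 0
  out
}

#' Simulate dF/F calcium traces from spike trains
#'
#' Convolves each unit's spike train with the double-exponential
#' [calcium_kernel()] and adds Gaussian noise, sampled at `fps` (default
#' 30 Hz, so 12 frames correspond to 400 ms). Noise draws use an
#' independent sub-stream per unit.
#'
#' @param spikes Tibble with `unit_id`, `t` (s).
#' @param tau_rise_s,tau_decay_s Kernel time constants (s).
#' @param noise_sd Gaussian noise SD (dF/F units).
#' @param fps Sampling rate (Hz).
#' @param duration Trace duration (s); defaults to last spike + 2 s.
#' @param seed Integer seed.
#' @param amp Kernel peak amplitude.
#' @return A `wt_calcium` tibble with columns `unit_id`, `t`, `dff` and
#'   attribute `fps`.
#' @export
generate_calcium <- function(spikes, tau_rise_s = 0.05, tau_decay_s = 0.4,
                             noise_sd = 0.05, fps = 30, duration = NULL,
                             seed = 1, amp = 1) {
  if (tau_decay_s <= tau_rise_s) abort("tau_decay_s must exceed tau_rise_s")
  if (is.null(duration)) {
    duration <- if (nrow(spikes)) max(spikes$t) + 2 else 10
  }
  n <- floor(duration * fps)
  t <- seq_len(n) / fps
  kern <- calcium_kernel(seq(0, 6 * tau_decay_s, by = 1 / fps),
                         tau_rise_s, tau_decay_s, amp)
  units <- unique(spikes$unit_id)
  out <- purrr::map(units, function(u) {
    ts <- spikes$t[spikes$unit_id == u]
    counts <- tabulate(pmin(n, floor(ts * fps) + 1L), nbins = n)
    dff <- as.numeric(stats::convolve(counts, rev(kern), type = "open"))
    dff <- dff[seq_len(n)]
    with_seed(substream_seed(seed, paste0("calcium_", u)), {
      dff <- dff + rnorm(n, 0, noise_sd)
    })
    tibble::tibble(unit_id = u, t = t, dff = dff)
  })
  new_wt_tbl(dplyr::bind_rows(out), class = "wt_calcium", fps = fps)
}
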