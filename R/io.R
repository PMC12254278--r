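EVENT_DEVICES <- c("beam_L", "beam_M", "beam_R", "lick_L", "lick_R",
                   "aperture_L", "aperture_R", "outcome")

#' Read a raw event-list CSV
#'
#' Columns `t_s` (seconds), `device` (one of beam_L/M/R, lick_L/R,
#' aperture_L/R, outcome) and `value`. Unknown device tokens raise an
#' error naming the offending line; rows out of time order are re-sorted
#' with a warning. An empty file yields an empty stream, not an error.
#'
#' @param path CSV path.
#' @return A tibble with columns `t_s`, `device`, `value`.
#' @export
read_event_csv <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          t_s = readr::col_double(),
                          device = readr::col_character(),
                          value = readr::col_double()))
  bad <- which(!ev$device %in% EVENT_DEVICES)
  if (length(bad)) {
    abort(sprintf("unknown device token '%s' at line %d (valid: %s)",
                  ev$device[bad[1]], bad[1] + 1L,
                  paste(EVENT_DEVICES, collapse = ", ")))
  }
  if (is.unsorted(ev$t_s)) {
    warn("event file not time-ordered; re-sorting by t_s")
    ev <- dplyr::arrange(ev, .data$t_s)
  }
  ev
}

#' Write an event stream to CSV
#' @param events Tibble with `t_s`, `device`, `value`.
#' @param path Output path.
#' @export
write_event_csv <- function(events, path) {
  readr::write_csv(events[, c("t_s", "device", "value")], path)
  invisible(path)
}

#' Read a uniformly sampled time-series CSV
#'
#' Expects a `t` column plus one or more value columns. Validates that the
#' median sampling rate is within 1% of `expected_fps` (error otherwise)
#' and fills dropped frames with explicit `NA` markers rather than
#' interpolating silently.
#'
#' @param path CSV path.
#' @param expected_fps Expected sampling rate (Hz).
#' @return A tibble on the full uniform time grid, attribute `fps`.
#' @export
read_timeseries_csv <- function(path, expected_fps) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"t" %in% names(d)) abort("time-series CSV must have a 't' column")
  dt <- median(diff(d$t))
  fps <- 1 / dt
  if (abs(fps - expected_fps) / expected_fps > 0.01) {
    abort(sprintf("sampling rate %.2f Hz differs from expected %.2f Hz by > 1%%",
                  fps, expected_fps))
  }
  # regrid onto the uniform frame grid; dropped frames become NA rows
  frame <- round(d$t * expected_fps)
  full <- tibble::tibble(frame = seq(min(frame), max(frame)))
  out <- dplyr::left_join(full, dplyr::mutate(d, frame = frame),
                          by = "frame")
  out$t <- out$frame / expected_fps
  out <- dplyr::select(out, -"frame")
  attr(out, "fps") <- expected_fps
  out
}

#' Write a time-series tibble to CSV
#' @param trace Tibble with a `t` column.
#' @param path Output path.
#' @export
write_timeseries_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Default run configuration
#'
#' Bundles every tunable parameter of the pipeline (synthetic generation,
#' scoring, kinematics, tuning, decoding) with its default, plus the
#' master seed. The structure serializes losslessly through YAML (see
#' [write_run_config()] / [read_run_config()]).
#'
#' @param seed Master seed.
#' @return A named list of class `wt_run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(
      stage = "initial", n_trials = 150L, iti_range_s = c(4, 8),
      learner = list(p_lick_go_initial = 0.5, p_lick_go_final = 0.95,
                     p_lick_nogo_initial = 0.5, p_lick_nogo_final = 0.05,
                     learning_midpoint_trials = 60,
                     learning_rate = 0.08),
      whisk_freq_hz = 14.5, whisk_amp_deg = 20,
      run_speed_mms = 300,
      n_units = 8L, baseline_rate_hz = 10,
      touch_gain_wide = 3, touch_gain_narrow = 1,
      calcium = list(tau_rise_s = 0.05, tau_decay_s = 0.4,
                     noise_sd = 0.05, fps = 30)
    ),
    behavior = list(dprime_window = 200L, expert_alpha = 0.05),
    kinematics = list(band_hz = c(2, 30), whisk_hi_deg = 5,
                      whisk_lo_deg = 3, loco_hi_mms = 100,
                      loco_lo_mms = 10, loco_min_dur_s = 0.2),
    tuning = list(n_shuffles = 100L, min_occupancy_s = 0.5,
                  angle_bin_deg = 5, phase_bins = 32L),
    decoding = list(folds = 10L, bin_s = 0.05, window_s = c(0, 0.4),
                    cnn_epochs = 100L, cnn_lr = 0.01)
  ), class = "wt_run_config")
}

#' @rdname default_run_config
#' @param config A `wt_run_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "wt_run_config")
}
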