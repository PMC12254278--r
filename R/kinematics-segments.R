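# Turn a per-frame logical vector into a segments tibble, keeping runs of
# at least `min_dur_s`.
frames_to_segments <- function(t, flag, label, fps, min_dur_s = 0) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fps) >= min_dur_s
  tibble::tibble(
    t_start = t[starts[keep]],
    t_end = t[ends[keep]] + 1 / fps,
    label = label
  )
}

#' Segment whisking and quiescent periods
#'
#' Whisking where the moving-window amplitude exceeds `hi` (default 5
#' degrees), quiescence where it stays below `lo` (default 3 degrees); the
#' 3-5 degree band is left unlabeled (excluded from both states). Frames
#' within `exclusion_s` of any touch event are excluded from both states to
#' avoid touch-related confounds.
#'
#' @param amplitude A tibble from [whisking_amplitude()] (`t`, `amplitude`).
#' @param hi,lo Amplitude thresholds in degrees.
#' @param touch_times Touch event times (s); may be empty.
#' @param exclusion_s Half-width of the touch exclusion window (s).
#' @param min_dur_s Minimum segment duration (s).
#' @return A `wt_segments` tibble with `t_start`, `t_end`, `label`
#'   (`"whisking"` / `"quiescent"`).
#' @export
segment_whisking <- function(amplitude, hi = 5, lo = 3,
                             touch_times = numeric(0), exclusion_s = 0.1,
                             min_dur_s = 0) {
  fps <- 1 / median(diff(amplitude$t))
  excl <- rep(FALSE, nrow(amplitude))
  for (tt in touch_times) {
    excl <- excl | (amplitude$t >= tt - exclusion_s &
                      amplitude$t <= tt + exclusion_s)
  }
  whisk <- amplitude$amplitude > hi & !excl
  quiet <- amplitude$amplitude < lo & !excl
  out <- dplyr::bind_rows(
    frames_to_segments(amplitude$t, whisk, "whisking", fps, min_dur_s),
    frames_to_segments(amplitude$t, quiet, "quiescent", fps, min_dur_s)
  )
  new_wt_tbl(dplyr::arrange(out, .data$t_start), class = "wt_segments")
}

#' Segment locomotion and rest periods
#'
#' Locomotion: sustained speed above `hi` (default 100 mm/s) for at least
#' `min_dur_s` (default 200 ms); rest: speed below `lo` (default 10 mm/s)
#' persisting at least as long. Analysis can be restricted to a region of
#' interest along the track (away from lick ports and apertures) via
#' `roi_mm`; frames outside it are unlabeled.
#'
#' @param position A `wt_position_trace` (`t`, `x`, `velocity`).
#' @param hi,lo Speed thresholds in mm/s.
#' @param min_dur_s Minimum segment duration (s).
#' @param roi_mm Length-2 numeric, region of interest on x (mm).
#' @return A `wt_segments` tibble with labels `"locomotion"` / `"rest"`.
#' @export
segment_locomotion <- function(position, hi = 100, lo = 10,
                               min_dur_s = 0.2, roi_mm = c(-Inf, Inf)) {
  fps <- trace_fps(position)
  speed <- abs(position$velocity)
  in_roi <- position$x >= roi_mm[1] & position$x <= roi_mm[2]
  out <- dplyr::bind_rows(
    frames_to_segments(position$t, speed > hi & in_roi, "locomotion",
                       fps, min_dur_s),
    frames_to_segments(position$t, speed < lo & in_roi, "rest",
                       fps, min_dur_s)
  )
  new_wt_tbl(dplyr::arrange(out, .data$t_start), class = "wt_segments")
}

#' Occupancy map and velocity-by-position profile
#'
#' Divides the track into rectangles (`bin_long_mm` along the track by
#' `bin_lat_mm` across it; half-open bins \[lo, hi)) and counts the video
#' frames spent in each. Also returns the mean and SD of speed per
#' longitudinal bin.
#'
#' @param position A `wt_position_trace`; an optional `y` column supplies
#'   the lateral coordinate (otherwise 0).
#' @param bin_long_mm,bin_lat_mm Bin sizes in mm.
#' @param range_mm Longitudinal extent (defaults to \[-410, 410\]).
#' @return A list of class `wt_occupancy` with `grid` (tibble: `x_bin`,
#'   `y_bin`, bin centers `x_mm`, `y_mm`, `frames`) and `velocity_profile`
#'   (tibble: `x_mm`, `mean_speed`, `sd_speed`, `frames`).
#' @export
occupancy_map <- function(position, bin_long_mm = 10, bin_lat_mm = 1,
                          range_mm = c(-410, 410)) {
  y <- if ("y" %in% names(position)) position$y else rep(0, nrow(position))
  xb <- seq(range_mm[1], range_mm[2], by = bin_long_mm)
  yr <- range(y)
  yb <- seq(floor(yr[1]), ceiling(yr[2]) + bin_lat_mm, by = bin_lat_mm)
  # half-open bins [lo, hi), except the last which closes at the track end
  ix <- findInterval(position$x, xb, rightmost.closed = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix < length(xb) & iy >= 1
  grid <- tibble::tibble(x_bin = ix[ok], y_bin = iy[ok]) |>
    dplyr::count(.data$x_bin, .data$y_bin, name = "frames") |>
    dplyr::mutate(x_mm = xb[.data$x_bin] + bin_long_mm / 2,
                  y_mm = yb[.data$y_bin] + bin_lat_mm / 2)
  vel <- tibble::tibble(x_bin = ix[ok],
                        speed = abs(position$velocity[ok])) |>
    dplyr::group_by(.data$x_bin) |>
    dplyr::summarise(mean_speed = mean(.data$speed),
                     sd_speed = sd(.data$speed),
                     frames = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(x_mm = xb[.data$x_bin] + bin_long_mm / 2)
  structure(list(grid = grid, velocity_profile = vel,
                 n_frames = sum(ok), bin_long_mm = bin_long_mm,
                 bin_lat_mm = bin_lat_mm),
            class = "wt_occupancy")
}
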