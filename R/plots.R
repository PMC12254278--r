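#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_ribbon
#'   geom_point geom_tile geom_col geom_abline labs facet_wrap
#'   scale_fill_viridis_c theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a running d-prime learning curve
#'
#' @param object A `wt_running_dprime` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wt_running_dprime <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 1.65
  ggplot(object, aes(x = .data$trial_index, y = .data$dprime)) +
    geom_hline(yintercept = thr, linetype = "dashed", color = "grey40") +
    geom_hline(yintercept = 0, color = "grey80") +
    geom_line(na.rm = TRUE, color = "#2166AC") +
    labs(x = "Trial", y = "d' (running window)",
         title = "Running-window discrimination performance") +
    theme_minimal()
}

#' Plot angle tuning curves
#'
#' @param object A `wt_angle_tuning` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by unit.
#' @export
autoplot.wt_angle_tuning <- function(object, ...) {
  curves <- tidyr::unnest(
    dplyr::select(object, "unit_id", "significant", "curve"), "curve")
  ggplot(curves, aes(x = .data$angle_deg, y = .data$rate_hz,
                     color = .data$significant)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~unit_id, scales = "free_y") +
    labs(x = "Whisker angle (deg)", y = "Firing rate (Hz)",
         color = "Tuned") +
    theme_minimal()
}

#' Plot phase tuning curves
#'
#' @param object A `wt_phase_tuning` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by unit.
#' @export
autoplot.wt_phase_tuning <- function(object, ...) {
  curves <- tidyr::unnest(
    dplyr::select(object, "unit_id", "curve"), "curve")
  ggplot(curves, aes(x = .data$phase, y = .data$rate_hz)) +
    geom_line(na.rm = TRUE, color = "#B2182B") +
    facet_wrap(~unit_id, scales = "free_y") +
    labs(x = "Whisking phase (rad; π = protraction)",
         y = "Firing rate (Hz)") +
    theme_minimal()
}

#' Plot a time-resolved decoding accuracy series
#'
#' @param object A `wt_decoding` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wt_decoding <- function(object, ...) {
  ggplot(object$accuracy, aes(x = .data$bin_t, y = .data$accuracy)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    geom_line(color = "#2166AC") +
    labs(x = "Time from touch (s)", y = "Decoding accuracy",
         title = sprintf("Windowed mean accuracy: %.2f",
                         object$window_accuracy)) +
    theme_minimal()
}

#' Plot an ROC curve with pointwise confidence band
#'
#' @param object A `wt_roc_decoding` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wt_roc_decoding <- function(object, ...) {
  ggplot(object$roc, aes(x = 1 - .data$specificity,
                         y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.2,
                fill = "#2166AC") +
    geom_line(color = "#2166AC") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC = %.3f", object$auc)) +
    coord_equal() +
    theme_minimal()
}

#' Plot an occupancy map with its velocity profile
#'
#' @param object A `wt_occupancy` object.
#' @param ... Unused.
#' @return A ggplot of the longitudinal occupancy and speed profile.
#' @export
autoplot.wt_occupancy <- function(object, ...) {
  long <- object$grid |>
    dplyr::group_by(.data$x_mm) |>
    dplyr::summarise(frames = sum(.data$frames), .groups = "drop")
  ggplot(long, aes(x = .data$x_mm, y = .data$frames)) +
    geom_col(fill = "#2166AC") +
    labs(x = "Track position (mm; 0 = middle beam)",
         y = "Frames occupied",
         title = "Track occupancy") +
    theme_minimal()
}
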