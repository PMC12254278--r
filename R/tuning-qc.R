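#' Quality-control filter for sorted units
#'
#' Retains units with isolation distance strictly greater than `iso_min`
#' and an inter-spike-interval (ISI) violation fraction strictly below
#' `isi_viol_max`, where a violation is an ISI shorter than
#' `isi_thresh_s`. The violation fraction is computed from the spike times;
#' the isolation distance is taken from the unit metadata (a unit with
#' missing isolation distance cannot be verified and is excluded with a
#' warning).
#'
#' @param units Metadata tibble with `unit_id`, `isolation_distance`.
#' @param spikes Tibble with `unit_id`, `t`.
#' @param iso_min Isolation-distance threshold (strict).
#' @param isi_viol_max Maximum ISI violation fraction (strict).
#' @param isi_thresh_s ISI threshold in seconds (default 1.5 ms).
#' @return The `units` tibble with added columns `isi_violation`, `qc_pass`.
#' @export
qc_filter_units <- function(units, spikes, iso_min = 15,
                            isi_viol_max = 0.03, isi_thresh_s = 0.0015) {
  viol <- spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(isi_violation = {
      isi <- diff(sort(.data$t))
      if (length(isi)) mean(isi < isi_thresh_s) else 0
    }, .groups = "drop")
  out <- dplyr::left_join(units, viol, by = "unit_id")
  out$isi_violation[is.na(out$isi_violation)] <- 0
  if (anyNA(out$isolation_distance)) {
    warn(sprintf("%d unit(s) with missing isolation distance excluded",
                 sum(is.na(out$isolation_distance))))
  }
  out$qc_pass <- !is.na(out$isolation_distance) &
    out$isolation_distance > iso_min &
    out$isi_violation < isi_viol_max
  out
}

#' Classify regular- vs fast-spiking units and apply region selection
#'
#' Units are split by spike trough-to-peak duration: the RS/FS threshold is
#' 350 us for cortex (BC) and zona incerta (ZIv) and 300 us for the
#' thalamic nuclei (VPM, POm); a unit with trough-to-peak above the
#' regional threshold is regular-spiking (RS), otherwise fast-spiking
#' (FS). For downstream analysis only RS units are kept in BC, VPM and
#' POm, while FS units are kept in ZIv.
#'
#' @param units Metadata tibble with `unit_id`, `region`,
#'   `trough_to_peak_us`.
#' @return `units` with added `threshold_us`, `unit_class` (`"RS"`/`"FS"`)
#'   and `kept` columns.
#' @export
classify_rs_fs <- function(units) {
  thalamic <- c("VPM", "POm")
  units |>
    dplyr::mutate(
      threshold_us = ifelse(.data$region %in% thalamic, 300, 350),
      unit_class = ifelse(.data$trough_to_peak_us > .data$threshold_us,
                          "RS", "FS"),
      kept = ifelse(.data$region == "ZIv",
                    .data$unit_class == "FS", .data$unit_class == "RS")
    )
}
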