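#' Reported touch-modulated unit counts per region
#'
#' Published per-region counts of touch-modulated units (total curated
#' units, touch-modulated units, and the wide / narrow / both breakdown)
#' for barrel cortex (BC), ventral posteromedial thalamus (VPM),
#' posterior medial complex (POm) and ventral zona incerta (ZIv) from
#' extracellular recordings, plus POm calcium imaging. Shipped as a small
#' CSV so the percentage arithmetic is reproducible offline.
#'
#' @return A tibble with columns `region`, `modality`, `n_total`,
#'   `n_modulated`, `n_wide`, `n_narrow`, `n_both`.
#' @export
touch_modulated_counts <- function() {
  path <- system.file("extdata", "touch_modulated_counts.csv",
                      package = "whiskertask")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Touch-modulated proportions recomputed from the counts
#'
#' Percentage of touch-modulated units per region, `100 * n_modulated /
#' n_total`, rounded half-up to one decimal as conventionally reported.
#'
#' @return [touch_modulated_counts()] with an added `pct_modulated`
#'   column.
#' @export
touch_modulated_proportions <- function() {
  cnt <- touch_modulated_counts()
  stopifnot(all(cnt$n_wide + cnt$n_narrow + cnt$n_both == cnt$n_modulated))
  dplyr::mutate(
    cnt,
    pct_modulated = floor(100 * .data$n_modulated / .data$n_total * 10 +
                            0.5) / 10)
}
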