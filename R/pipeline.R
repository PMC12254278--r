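#' Run the full synthetic pipeline end to end
#'
#' Executes synthetic generation, behavior scoring and d-prime statistics,
#' kinematics (filtering, whisking/locomotion segmentation, occupancy),
#' per-unit tuning statistics, and spike/angle decoding, writing every
#' stage's results plus a single JSON manifest that links all result files
#' with their MD5 hashes, parameters, and the master seed. A stage failure
#' is caught and recorded in the manifest as partial completion.
#'
#' @param config A `wt_run_config` list (see [default_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @param include_cnn Also run the calcium CNN decoder (the slowest
#'   stage).
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         include_cnn = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed, config = unclass(config), stages = list(),
                   files = list())
  out_file <- function(name) file.path(out_dir, name)
  run_stage <- function(name, fn) {
    res <- tryCatch(list(ok = TRUE, value = fn()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (res$ok) "complete" else "failed",
      error = if (res$ok) NULL else res$error,
      seed = seed
    )
    if (res$ok) res$value else NULL
  }

  sim <- run_stage("simulate", function() {
    sc <- config$synthetic
    learner <- do.call(learner_params, sc$learner)
    session <- generate_session_events(sc$stage, learner, sc$n_trials,
                                       seed = seed,
                                       iti_range_s = sc$iti_range_s)
    whisker <- generate_whisker_trace(session, sc$whisk_freq_hz,
                                      sc$whisk_amp_deg, seed = seed)
    position <- generate_position_trace(session, sc$run_speed_mms,
                                        seed = seed)
    specs <- dplyr::bind_rows(lapply(seq_len(sc$n_units), function(i) {
      tuning_spec(unit_id = sprintf("u%02d", i), region = "BC",
                  baseline_rate = sc$baseline_rate_hz,
                  touch_gain_wide = if (i %% 2 == 1) sc$touch_gain_wide else 1,
                  touch_gain_narrow = if (i %% 2 == 0) sc$touch_gain_wide else 1)
    }))
    trains <- generate_spike_trains(session, list(whisker = whisker,
                                                  position = position),
                                    specs, seed = seed)
    write_event_csv(session_to_events(session), out_file("events.csv"))
    write_timeseries_csv(whisker[, c("t", "angle")],
                         out_file("whisker.csv"))
    write_timeseries_csv(position, out_file("position.csv"))
    readr::write_csv(trains$spikes, out_file("spikes.csv"))
    readr::write_csv(trains$units, out_file("units.csv"))
    jsonlite::write_json(
      list(seed = seed, specs = specs,
           learner = unclass(learner)),
      out_file("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    list(session = session, whisker = whisker, position = position,
         specs = specs, trains = trains)
  })

  run_stage("behavior", function() {
    session <- sim$session
    cnt <- score_counts(session)
    dp <- session_dprime(session)
    rates <- success_rates(session)
    metrics <- dplyr::bind_cols(
      tibble::tibble(session_index = attr(session, "session_index"),
                     stage = attr(session, "stage"),
                     n_trials = nrow(session)),
      cnt, rates, dprime = dp$dprime)
    readr::write_csv(metrics, out_file("session_metrics.csv"))
    rd <- running_dprime(session, window = config$behavior$dprime_window)
    readr::write_csv(rd, out_file("running_dprime.csv"))
    metrics
  })

  kin <- run_stage("kinematics", function() {
    band <- config$kinematics$band_hz
    filt <- bandpass_whisker(sim$whisker, band[1], band[2])
    amp <- whisking_amplitude(filt)
    wseg <- segment_whisking(amp, hi = config$kinematics$whisk_hi_deg,
                             lo = config$kinematics$whisk_lo_deg,
                             touch_times = sim$session$t_touch)
    lseg <- segment_locomotion(sim$position,
                               hi = config$kinematics$loco_hi_mms,
                               lo = config$kinematics$loco_lo_mms,
                               min_dur_s = config$kinematics$loco_min_dur_s)
    segs <- dplyr::bind_rows(wseg, lseg)
    readr::write_csv(segs, out_file("segments.csv"))
    occ <- occupancy_map(sim$position)
    readr::write_csv(occ$grid, out_file("occupancy.csv"))
    list(filtered = filt, segments = segs,
         phase = whisking_phase(filt))
  })

  run_stage("tuning", function() {
    tp <- config$tuning
    spikes <- sim$trains$spikes
    units <- classify_rs_fs(
      qc_filter_units(sim$trains$units, spikes))
    touches <- tibble::tibble(
      t = sim$session$t_touch,
      aperture = ifelse(sim$session$aperture_mm >= 45, "wide", "narrow"))
    touch_mod <- touch_modulation_ephys(spikes, touches)
    lat <- onset_latency(spikes, touches$t)
    ang <- angle_tuning(spikes, sim$whisker,
                        bin_deg = tp$angle_bin_deg,
                        touch_times = sim$session$t_touch,
                        min_occupancy_s = tp$min_occupancy_s,
                        n_shuffles = tp$n_shuffles, seed = seed)
    ph <- phase_tuning(spikes, kin$phase, n_bins = tp$phase_bins)
    results <- units |>
      dplyr::left_join(touch_mod, by = "unit_id") |>
      dplyr::left_join(lat, by = "unit_id") |>
      dplyr::left_join(dplyr::select(ang, "unit_id", "modulation_depth",
                                     angle_sig = "significant"),
                       by = "unit_id") |>
      dplyr::left_join(dplyr::select(ph, "unit_id", "amp", "phase_pref",
                                     "snr", "kuiper_p"),
                       by = "unit_id")
    readr::write_csv(results, out_file("unit_results.csv"))
    results
  })

  run_stage("decoding", function() {
    dc <- config$decoding
    touched <- sim$session[!is.na(sim$session$t_touch) &
                             sim$session$aperture_mm %in% c(25, 45), ]
    trials <- tibble::tibble(
      t_touch = touched$t_touch,
      label = ifelse(touched$aperture_mm >= 45, "wide", "narrow"))
    feats <- spike_trial_features(sim$trains$spikes, trials,
                                  bin_s = dc$bin_s)
    dec <- decode_spikes(feats, folds = dc$folds, window = dc$window_s,
                         seed = seed)
    readr::write_csv(dec$accuracy, out_file("decoding_accuracy.csv"))
    res <- list(spike_window_accuracy = dec$window_accuracy)
    if (include_cnn) {
      ca <- generate_calcium(sim$trains$spikes,
                             noise_sd = config$synthetic$calcium$noise_sd,
                             fps = config$synthetic$calcium$fps,
                             duration = max(sim$whisker$t), seed = seed)
      cf <- calcium_trial_features(ca, trials)
      cnn <- decode_calcium_cnn(cf$tensor, cf$labels,
                                epochs = dc$cnn_epochs, lr = dc$cnn_lr,
                                seed = seed)
      res$cnn_val_accuracy <- cnn$val_accuracy
    }
    jsonlite::write_json(res, out_file("decoding_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) list(md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
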