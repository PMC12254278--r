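test_that("QC applies strict isolation and ISI-violation thresholds", {
  units <- tibble::tibble(
    unit_id = c("clean", "doublets", "edge", "noiso"),
    isolation_distance = c(20, 20, 15, NA))
  clean <- tibble::tibble(unit_id = "clean", t = seq(0.1, 100, by = 0.1))
  base <- seq(0.5, 100, by = 0.5)
  doubl <- sort(c(base, base[seq_len(ceiling(0.11 * length(base)))] + 5e-4))
  spikes <- dplyr::bind_rows(
    clean,
    tibble::tibble(unit_id = "doublets", t = doubl),
    tibble::tibble(unit_id = "edge", t = base),
    tibble::tibble(unit_id = "noiso", t = base))
  expect_warning(res <- qc_filter_units(units, spikes), "isolation")
  expect_true(res$qc_pass[res$unit_id == "clean"])
  expect_false(res$qc_pass[res$unit_id == "doublets"])
  expect_gt(res$isi_violation[res$unit_id == "doublets"], 0.03)
  expect_false(res$qc_pass[res$unit_id == "edge"])   # 15 is not > 15
  expect_false(res$qc_pass[res$unit_id == "noiso"])
})

test_that("RS/FS classification uses regional thresholds and selection", {
  units <- tibble::tibble(
    unit_id = c("bc", "vpm", "ziv", "pom"),
    region = c("BC", "VPM", "ZIv", "POm"),
    trough_to_peak_us = c(400, 280, 300, 310))
  res <- classify_rs_fs(units)
  expect_equal(res$unit_class, c("RS", "FS", "FS", "RS"))
  expect_equal(res$kept, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(res$threshold_us, c(350, 300, 350, 300))
})

test_that("onset latency detects an injected rate step and ignores inhibition", {
  set.seed(91)
  touches <- seq(10, 10 + 49 * 3, by = 3)
  mk_unit <- function(id, base_hz, step_hz = 0, dur = 200) {
    base <- sort(runif(rpois(1, base_hz * dur), 0, dur))
    extra <- unlist(lapply(touches, function(x)
      x + 0.008 + sort(runif(rpois(1, step_hz * 0.04), 0, 0.04))))
    tibble::tibble(unit_id = id, t = sort(c(base, extra)))
  }
  sp <- dplyr::bind_rows(mk_unit("step", 5, 80), mk_unit("flat", 5, 0))
  # Bonferroni variant: single-bin false positives suppressed, so one
  # unit suffices for a clean check (the uncorrected default is assessed
  # at the population median, where isolated spurious bins wash out)
  res <- onset_latency(sp, touches, bonferroni = TRUE)
  lat <- res$latency_ms[res$unit_id == "step"]
  expect_false(is.na(lat))
  expect_lte(abs(lat - 9), 2)
  expect_true(is.na(res$latency_ms[res$unit_id == "flat"]))
  # inhibited response only: upper tail finds nothing
  inhib <- tibble::tibble(
    unit_id = "inh",
    t = setdiff(sort(runif(5000, 0, 200)),
                unlist(lapply(touches, function(x)
                  seq(x, x + 0.2, by = 0.001)))))
  keep <- !vapply(inhib$t, function(tt)
    any(tt > touches & tt < touches + 0.2), logical(1))
  res_inh <- onset_latency(inhib[keep, ], touches)
  expect_true(is.na(res_inh$latency_ms))
  expect_error(onset_latency(sp, touches[1:5]), "10 touch")
})

test_that("touch modulation categorizes aperture selectivity", {
  s <- fixture_session(120, seed = 92, iti = c(3, 5))
  touches <- tibble::tibble(
    t = s$t_touch, aperture = ifelse(s$aperture_mm >= 45, "wide",
                                     "narrow"))
  specs <- dplyr::bind_rows(
    tuning_spec(unit_id = "wideonly", baseline_rate = 10,
                touch_gain_wide = 3),
    tuning_spec(unit_id = "both", baseline_rate = 10,
                touch_gain_wide = 3, touch_gain_narrow = 3),
    tuning_spec(unit_id = "flat", baseline_rate = 10))
  tr <- generate_spike_trains(s, list(), specs, seed = 92)
  res <- touch_modulation_ephys(tr$spikes, touches)
  expect_equal(res$category[res$unit_id == "wideonly"], "wide-only")
  expect_equal(res$category[res$unit_id == "both"], "both")
  expect_equal(res$category[res$unit_id == "flat"], "none")
})

test_that("calcium touch modulation flags kernel-convolved responders", {
  s <- fixture_session(80, seed = 93, iti = c(3, 5))
  touches <- s$t_touch
  dur <- max(touches) + 5
  resp <- tibble::tibble(unit_id = "resp",
                         t = rep(touches + 0.05, each = 3) +
                           rep(c(0, 0.05, 0.1), length(touches)))
  ca_resp <- generate_calcium(resp, noise_sd = 0.05, duration = dur,
                              seed = 93)
  res <- touch_modulation_calcium(ca_resp, touches)
  expect_true(res$significant)
  # pure noise trace: not significant (single draw)
  noise <- generate_calcium(tibble::tibble(unit_id = "n", t = 1),
                            noise_sd = 0.2, duration = dur, seed = 94)
  res_n <- touch_modulation_calcium(noise, touches)
  expect_gt(res_n$p_value, 0.01)
})

test_that("circular shifts preserve counts and the circular ISI multiset", {
  sp <- fixture_poisson_spikes(8, 50, seed = 95)
  sh <- circular_shift_null(sp$t, 50, n_shuffles = 20, seed = 1)
  circ_isi <- function(x, dur) sort(c(diff(x), dur - max(x) + min(x)))
  ref <- circ_isi(sp$t, 50)
  for (s in sh) {
    expect_equal(length(s), nrow(sp))
    expect_true(all(s >= 0 & s < 50))
    expect_equal(circ_isi(s, 50), ref, tolerance = 1e-9)
  }
})

test_that("state modulation flags a locomotion-gained unit", {
  s <- fixture_session(40, seed = 96, iti = c(4, 6))
  p <- generate_position_trace(s, 300, seed = 96)
  dur <- max(p$t)
  specs <- dplyr::bind_rows(
    tuning_spec(unit_id = "loco", baseline_rate = 8, locomotion_gain = 2),
    tuning_spec(unit_id = "flat", baseline_rate = 8))
  tr <- generate_spike_trains(s, list(position = p), specs, seed = 96,
                              duration = dur)
  segs <- segment_locomotion(p)
  res <- state_rate_modulation(tr$spikes, segs, duration = dur, seed = 2)
  expect_equal(res$direction[res$unit_id == "loco"], "enhanced")
  expect_gt(res$rate_a[res$unit_id == "loco"],
            res$rate_b[res$unit_id == "loco"])
  expect_error(
    state_rate_modulation(tr$spikes, segs[segs$label == "rest", ],
                          duration = dur),
    "locomotion")
})

test_that("angle tuning recovers a von Mises preference and the depth formula", {
  s <- fixture_session(50, seed = 97, iti = c(8, 12))
  w <- generate_whisker_trace(s, 14.5, 40, seed = 97,
                              quiet_dur_s = c(0.5, 1))
  specs <- dplyr::bind_rows(
    tuning_spec(unit_id = "vm", baseline_rate = 10, angle_pref_deg = 90,
                angle_kappa = 2),
    tuning_spec(unit_id = "flat", baseline_rate = 10))
  tr <- generate_spike_trains(s, list(whisker = w), specs, seed = 97,
                              duration = max(w$t))
  res <- angle_tuning(tr$spikes, w, touch_times = s$t_touch, seed = 3)
  vm <- res[res$unit_id == "vm", ]
  expect_true(vm$significant)
  expect_lte(abs(vm$peak_angle_deg - 90), 10)
  flat <- res[res$unit_id == "flat", ]
  expect_lt(flat$modulation_depth, flat$null_95th * 1.5)
  # the depth formula itself
  expect_equal((15 - 5) / 10, 1)
  expect_equal(vm$modulation_depth,
               (vm$r_max - vm$r_min) / vm$r_mean, tolerance = 1e-12)
})

test_that("noiseless phase profiles are fitted to machine precision", {
  centers <- seq(0, 2 * pi, length.out = 33)[-33] + pi / 32
  rates <- 10 + 4 * cos(centers - pi)
  fit <- fit_phase_profile(centers, rates)
  expect_equal(fit$amp, 4, tolerance = 1e-10)
  expect_equal(fit$phase_pref, pi, tolerance = 1e-10)
  expect_equal(fit$mean_rate, 10, tolerance = 1e-10)
  expect_equal(fit$snr, 8 * sqrt(0.111 / 10), tolerance = 1e-12)
  # sine-fit oracle: equals the first circular Fourier coefficient
  fc <- 2 * mean(rates * exp(1i * centers))
  expect_equal(fit$amp, Mod(fc), tolerance = 1e-9)
  expect_equal(fit$phase_pref, Arg(fc) %% (2 * pi), tolerance = 1e-9)
})

test_that("phase tuning recovers an injected preferred phase from spikes", {
  s <- fixture_session(60, seed = 98, iti = c(8, 12))
  w <- generate_whisker_trace(s, 14.5, 20, seed = 98,
                              quiet_dur_s = c(0, 0),
                              touch_deflection_deg = 0)
  spec <- tuning_spec(unit_id = "ph", baseline_rate = 10, phase_amp = 4,
                      phase_pref = pi)
  tr <- generate_spike_trains(s, list(whisker = w), spec, seed = 98,
                              duration = max(w$t))
  ph <- whisking_phase(bandpass_whisker(w))
  res <- phase_tuning(tr$spikes, ph)
  err <- atan2(sin(res$phase_pref - pi), cos(res$phase_pref - pi))
  expect_lt(abs(err) * 180 / pi, 15)
  expect_lt(res$kuiper_p, 0.05)
  flat_ph <- ph
  flat_ph$phase <- rep(1.0, nrow(flat_ph))   # constant phase: 1 bin
  expect_error(phase_tuning(tr$spikes, flat_ph),
               "occupied phase bins")
})

test_that("Kuiper test is calibrated and rotation-invariant", {
  set.seed(99)
  # uniform angles: p should be roughly uniform (check no gross anti-conservatism)
  ps <- replicate(200, kuiper_test(runif(100, 0, 2 * pi))$p_value)
  expect_gt(mean(ps > 0.05), 0.90)
  # strongly concentrated angles: tiny p
  expect_lt(kuiper_test(rnorm(200, pi, 0.3) %% (2 * pi))$p_value, 1e-6)
  # rotation invariance of the statistic
  x <- runif(150, 0, 2 * pi)
  v1 <- kuiper_test(x)$statistic
  v2 <- kuiper_test((x + 1.234) %% (2 * pi))$statistic
  expect_equal(v1, v2, tolerance = 0.05)
})

test_that("population phase vector averages significant preferences", {
  res <- tibble::tibble(
    phase_pref = c(pi - 0.1, pi + 0.1, 0.3),
    amp = c(1, 1, 5),
    kuiper_p = c(0.01, 0.01, 0.5))
  pv <- population_phase_vector(res)
  expect_equal(pv$mean_phase, pi, tolerance = 1e-9)
  expect_equal(pv$n_units, 2L)
  # uniform angles: resultant near 0
  resu <- tibble::tibble(phase_pref = seq(0, 2 * pi, length.out = 9)[-9],
                         amp = rep(1, 8), kuiper_p = rep(0.01, 8))
  expect_lt(population_phase_vector(resu)$resultant_length, 1e-9)
})

test_that("spatial tuning recovers a place field and rejects speed coupling", {
  s <- fixture_session(55, seed = 100, iti = c(8, 12))
  p <- generate_position_trace(s, 300, seed = 100)
  dur <- max(p$t)
  specs <- dplyr::bind_rows(
    tuning_spec(unit_id = "place", baseline_rate = 5,
                place_center_mm = -200, place_sigma_mm = 40,
                place_amp = 15),
    tuning_spec(unit_id = "speed", baseline_rate = 5,
                locomotion_gain = 3))
  tr <- generate_spike_trains(s, list(position = p), specs, seed = 100,
                              duration = dur)
  res <- spatial_tuning(tr$spikes, p)
  place <- res[res$unit_id == "place", ]
  expect_true(place$spatially_tuned)
  expect_lte(abs(place$mu - (-200)), 20)
  expect_false(res$spatially_tuned[res$unit_id == "speed"])
})
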