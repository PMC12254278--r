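test_that("deterministic learners produce the Table-style scores exactly", {
  perfect <- learner_params(p_lick_go_initial = 1, p_lick_go_final = 1,
                            p_lick_nogo_initial = 0, p_lick_nogo_final = 0)
  s <- generate_session_events("initial", perfect, 200, seed = 11)
  cnt <- score_counts(s)
  expect_equal(cnt$n_miss, 0)
  expect_equal(cnt$n_fa, 0)
  expect_equal(cnt$n_hit, sum(s$aperture_mm == 45))
  expect_equal(cnt$n_cr, sum(s$aperture_mm == 25))

  always <- learner_params(p_lick_go_initial = 1, p_lick_go_final = 1,
                           p_lick_nogo_initial = 1, p_lick_nogo_final = 1)
  s2 <- generate_session_events("initial", always, 150, seed = 12)
  expect_equal(score_counts(s2)$n_fa, sum(s2$aperture_mm == 25))
})

test_that("extinction outcomes are random and independent of aperture", {
  s <- generate_session_events("extinction", learner_params(), 400,
                               seed = 13)
  expect_true(all(s$score == "none"))
  licks <- s[s$response == "lick", ]
  p <- mean(licks$outcome == "reward")
  n <- nrow(licks)
  # binomial 95% CI around 0.5
  expect_lt(abs(p - 0.5), 1.96 * sqrt(0.25 / n))
})

test_that("unknown stage names raise an error naming the valid stages", {
  expect_error(generate_session_events("warmup", learner_params(), 10),
               "habituation.*initial.*neutral.*reversed.*extinction")
})

test_that("event-list conservation: scores partition trials", {
  s <- fixture_session(120, seed = 21)
  cnt <- score_counts(s)
  expect_equal(cnt$n_hit + cnt$n_miss, sum(s$is_go))
  expect_equal(cnt$n_fa + cnt$n_cr, sum(!s$is_go))
  expect_equal(sum(unlist(cnt)), nrow(s))
  expect_true(all(diff(s$t_beam) > 0))
  expect_true(all(s$t_touch >= s$t_beam))
  expect_true(all(s$t_lick[!is.na(s$t_lick)] >=
                    s$t_touch[!is.na(s$t_lick)]))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_session_events("initial", learner_params(), 50, seed = 5)
  b <- generate_session_events("initial", learner_params(), 50, seed = 5)
  expect_identical(a, b)
  s <- fixture_session(20, seed = 5)
  w1 <- generate_whisker_trace(s, seed = 9)
  w2 <- generate_whisker_trace(s, seed = 9)
  expect_identical(w1$angle, w2$angle)
})

test_that("whisker trace has its spectral peak at the requested frequency", {
  s <- fixture_session(30, seed = 31)
  w <- generate_whisker_trace(s, whisk_freq_hz = 14.5, amp_deg = 20,
                              seed = 31, quiet_dur_s = c(0, 0))
  sp <- spec.pgram(w$angle - mean(w$angle), plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)] * 240
  expect_lt(abs(peak_hz - 14.5), 0.3)
  expect_true(all(w$angle >= 0 & w$angle <= 180))
})

test_that("zero-amplitude whisking yields no whisking bouts", {
  s <- fixture_session(20, seed = 32)
  w <- generate_whisker_trace(s, amp_deg = 0, seed = 32,
                              touch_deflection_deg = 0)
  f <- bandpass_whisker(w)
  segs <- segment_whisking(whisking_amplitude(f),
                           touch_times = s$t_touch)
  expect_equal(sum(segs$label == "whisking"), 0)
})

test_that("out-of-band whisking frequencies are rejected", {
  s <- fixture_session(10, seed = 33)
  expect_error(generate_whisker_trace(s, whisk_freq_hz = 35), "band")
  expect_error(generate_whisker_trace(s, whisk_freq_hz = 1), "band")
})

test_that("position trace respects the track and the requested run speed", {
  s <- fixture_session(40, seed = 41)
  p <- generate_position_trace(s, run_speed_mms = 200, seed = 41)
  expect_true(all(abs(p$x) <= 410))
  segs <- segment_locomotion(p)
  loco <- segs[segs$label == "locomotion", ]
  expect_gt(nrow(loco), 0)
  sp_in <- unlist(purrr::map2(loco$t_start, loco$t_end, function(a, b) {
    abs(p$velocity[p$t >= a & p$t < b])
  }))
  expect_lt(abs(mean(sp_in) - 200) / 200, 0.10)

  pd <- generate_position_trace(s, run_speed_mms = 200, seed = 41,
                                dwell_only = TRUE)
  expect_equal(nrow(segment_locomotion(pd)[
    segment_locomotion(pd)$label == "locomotion", ]), 0)
})

test_that("an untuned unit's spike count matches its Poisson expectation", {
  s <- fixture_session(15, seed = 51)
  tr <- generate_spike_trains(s, list(), tuning_spec(baseline_rate = 10),
                              seed = 51, duration = 100)
  n <- nrow(tr$spikes)
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
})

test_that("spike generator enforces its validity invariants", {
  s <- fixture_session(10, seed = 52)
  expect_error(tuning_spec(baseline_rate = 0), "baseline_rate")
  expect_error(tuning_spec(baseline_rate = 5, phase_amp = 6), "phase_amp")
  expect_error(
    generate_spike_trains(s, list(), tuning_spec(baseline_rate = 200),
                          dt_s = 0.001, duration = 50),
    "dt_s")
})

test_that("calcium traces follow the double-exponential kernel", {
  # zero spikes, zero noise -> flat zero
  ca0 <- generate_calcium(tibble::tibble(unit_id = character(0),
                                         t = numeric(0))[0, ],
                          noise_sd = 0, duration = 5, seed = 1)
  expect_equal(nrow(ca0), 0)
  # single spike, zero noise -> peak equals the kernel maximum on the grid
  ca <- generate_calcium(tibble::tibble(unit_id = "c1", t = 2),
                         noise_sd = 0, fps = 30, duration = 8, seed = 1)
  kern_max <- max(calcium_kernel(seq(0, 2.4, by = 1 / 30), 0.05, 0.4))
  expect_equal(max(ca$dff), kern_max, tolerance = 1e-10)
  # two units share the seed but draw independent noise
  sp2 <- tibble::tibble(unit_id = c("a", "b"), t = c(1, 1))
  ca2 <- generate_calcium(sp2, noise_sd = 0.1, duration = 5, seed = 3)
  expect_false(identical(ca2$dff[ca2$unit_id == "a"],
                         ca2$dff[ca2$unit_id == "b"]))
  expect_error(generate_calcium(sp2, tau_rise_s = 0.5, tau_decay_s = 0.4),
               "tau_decay")
})
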