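test_that("band-pass filter passes whisking tones and rejects drift", {
  tone <- fixture_sine_trace(14.5, amp_pp = 20, duration = 20)
  f <- bandpass_whisker(tone)
  mid <- 1000:3000
  amp_out <- (max(f$angle[mid]) - min(f$angle[mid])) / 2
  expect_lt(abs(amp_out - 10) / 10, 0.05)
  expect_equal(nrow(f), nrow(tone))

  drift <- fixture_sine_trace(0.5, amp_pp = 20, duration = 20)
  fd <- bandpass_whisker(drift)
  expect_lt(sqrt(mean(fd$angle[mid]^2)) /
              sqrt(mean((drift$angle[mid] - 90)^2)), 0.05)

  const <- fixture_sine_trace(5, amp_pp = 0, duration = 5)
  fc <- bandpass_whisker(const)
  expect_true(all(abs(fc$angle) < 1e-8))

  low_fps <- fixture_sine_trace(10, duration = 5, fps = 50)
  expect_error(bandpass_whisker(low_fps), "sampling rate")
})

test_that("filter is near-idempotent on in-band tones", {
  tone <- fixture_sine_trace(10, amp_pp = 20, duration = 20)
  f1 <- bandpass_whisker(tone)
  f2 <- bandpass_whisker(f1)
  mid <- 1000:3000
  a1 <- diff(range(f1$angle[mid])); a2 <- diff(range(f2$angle[mid]))
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("Hilbert phase matches the analytic phase of a pure tone", {
  fps <- 240; freq <- 10
  t <- seq_len(20 * fps) / fps
  tr <- fixture_sine_trace(freq, amp_pp = 20, duration = 20)
  f <- bandpass_whisker(tr)
  ph <- whisking_phase(f)
  expect_true(all(ph$phase >= 0 & ph$phase < 2 * pi))
  expect_equal(nrow(ph), nrow(f))
  # cos(2 pi f t): protraction peak at t = k/f should map to phase pi
  core <- 500:4300
  truth <- (2 * pi * freq * t + pi) %% (2 * pi)
  err <- atan2(sin(ph$phase - truth), cos(ph$phase - truth))
  expect_lt(sqrt(mean(err[core]^2)), 0.05)
  # phase advances monotonically through each cycle
  expect_true(all(diff(unwrap_phase(ph$phase[core])) > 0))
  # sign flip shifts phase by pi
  f2 <- f
  f2$angle <- -f2$angle
  ph2 <- whisking_phase(f2)
  d <- atan2(sin(ph2$phase - ph$phase), cos(ph2$phase - ph$phase))
  expect_lt(max(abs(abs(d[core]) - pi)), 0.05)
  # all-zero input gives the undefined-phase marker
  fz <- f
  fz$angle <- rep(0, nrow(fz))
  expect_warning(phz <- whisking_phase(fz), "undefined")
  expect_true(all(is.na(phz$phase)))
})

test_that("whisking amplitude is peak-to-peak within the moving window", {
  tone <- fixture_sine_trace(14.5, amp_pp = 20, duration = 10)
  amp <- whisking_amplitude(tone)
  mid <- 500:1900
  expect_equal(mean(amp$amplitude[mid]), 20, tolerance = 0.05 * 20)
  # constant trace -> all zeros
  const <- fixture_sine_trace(5, amp_pp = 0, duration = 2)
  expect_true(all(whisking_amplitude(const)$amplitude == 0))
  # edge frames flagged as truncated
  expect_true(amp$truncated[1])
  expect_false(amp$truncated[500])
  expect_error(whisking_amplitude(const, window_s = 0.005), "3 samples")
})

test_that("whisking segmentation applies thresholds, dead band and touch exclusion", {
  t <- seq_len(2400) / 240
  amp6 <- tibble::tibble(t = t, amplitude = rep(6, 2400))
  seg <- segment_whisking(amp6, touch_times = 5)
  expect_true(all(seg$label == "whisking"))
  # no segment overlaps the touch exclusion
  expect_true(all(seg$t_end <= 5 - 0.1 + 1 / 240 |
                    seg$t_start >= 5 + 0.1))
  amp4 <- tibble::tibble(t = t, amplitude = rep(4, 2400))
  expect_equal(nrow(segment_whisking(amp4)), 0)
  amp2 <- tibble::tibble(t = t, amplitude = rep(2, 2400))
  seg2 <- segment_whisking(amp2)
  expect_true(all(seg2$label == "quiescent"))
})

test_that("whisk cycle counts match the phase-unwrap oracle", {
  tone <- fixture_sine_trace(14.5, amp_pp = 20, duration = 30)
  win <- tibble::tibble(t_start = c(5, 10), t_end = c(6, 12))
  st <- whisk_cycle_stats(bandpass_whisker(tone), win)
  expect_true(st$cycles[1] %in% c(14, 15))
  expect_true(abs(st$freq_hz[2] - 14.5) < 0.5)
  # quiescent window: zero cycles
  quiet <- fixture_sine_trace(14.5, amp_pp = 1, duration = 10)
  stq <- whisk_cycle_stats(bandpass_whisker(quiet),
                           tibble::tibble(t_start = 2, t_end = 4))
  expect_equal(stq$cycles, 0)
})

test_that("locomotion segmentation respects thresholds and minimum duration", {
  fps <- 60
  mk_pos <- function(v) {
    n <- length(v)
    p <- tibble::tibble(t = seq_len(n) / fps, x = cumsum(v) / fps,
                        velocity = v)
    attr(p, "fps") <- fps
    p
  }
  # 150 mm/s for 300 ms embedded in stillness
  v <- c(rep(0, 60), rep(150, 18), rep(0, 60))
  segs <- segment_locomotion(mk_pos(v), lo = 1)
  expect_equal(sum(segs$label == "locomotion"), 1)
  # 150 mm/s for 150 ms: below the minimum duration
  v2 <- c(rep(0, 60), rep(150, 9), rep(0, 60))
  segs2 <- segment_locomotion(mk_pos(v2), lo = 1)
  expect_equal(sum(segs2$label == "locomotion"), 0)
  # 5 mm/s for 1 s: rest
  v3 <- rep(5, 60)
  segs3 <- segment_locomotion(mk_pos(v3))
  expect_equal(sum(segs3$label == "rest"), 1)
  # labels never overlap in time
  p <- generate_position_trace(fixture_session(30, seed = 81), 300,
                               seed = 81)
  sl <- segment_locomotion(p)
  for (lab in unique(sl$label)) {
    fam <- sl[sl$label == lab, ]
    if (nrow(fam) > 1) {
      expect_true(all(fam$t_start[-1] >= fam$t_end[-nrow(fam)]))
    }
  }
})

test_that("occupancy map conserves frames and flags stationarity", {
  fps <- 60
  still <- tibble::tibble(t = seq_len(120) / fps, x = rep(100.2, 120),
                          velocity = rep(0, 120))
  attr(still, "fps") <- fps
  occ <- occupancy_map(still)
  expect_equal(nrow(occ$grid), 1)
  expect_equal(occ$grid$frames, 120)
  # uniform sweep: near-uniform longitudinal marginal
  n <- 8200
  sweep_x <- seq(-409.9, 409.9, length.out = n)
  pos <- tibble::tibble(t = seq_len(n) / fps, x = sweep_x,
                        velocity = rep(820 / (n / fps), n))
  attr(pos, "fps") <- fps
  occ2 <- occupancy_map(pos)
  expect_equal(sum(occ2$grid$frames), n)
  marg <- occ2$grid |>
    dplyr::group_by(x_bin) |>
    dplyr::summarise(frames = sum(frames), .groups = "drop")
  chi <- suppressWarnings(chisq.test(marg$frames))
  expect_gt(chi$p.value, 0.01)
})
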