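test_that("stage rules score canonical trials as in the paradigm table", {
  expect_equal(score_one("initial", 45, TRUE)$score, "hit")
  expect_equal(score_one("initial", 45, TRUE)$outcome, "reward")
  expect_equal(score_one("reversed", 45, TRUE)$score, "FA")
  expect_equal(score_one("reversed", 25, TRUE)$score, "hit")
  expect_equal(score_one("neutral", 35, TRUE)$score, "none")
  expect_equal(score_one("neutral", 35, TRUE)$outcome, "none")
  expect_equal(score_one("habituation", 45, FALSE)$score, "miss")
})

test_that("score_trials round-trips a synthetic event stream", {
  s <- fixture_session(80, seed = 61)
  ev <- session_to_events(s)
  s2 <- score_trials(ev, "initial")
  expect_equal(nrow(s2), nrow(s))
  expect_equal(score_counts(s2), score_counts(s))
  expect_equal(s2$response, s$response)
})

test_that("orphan licks are dropped with a warning", {
  s <- fixture_session(10, seed = 62)
  ev <- session_to_events(s)
  ev2 <- dplyr::arrange(
    dplyr::bind_rows(ev, tibble::tibble(t_s = 0.01, device = "lick_L",
                                        value = 1)),
    t_s)
  expect_warning(s2 <- score_trials(ev2, "initial"), "lick")
  expect_equal(nrow(s2), nrow(s))
})

test_that("d-prime matches the inverse-normal oracle and clips rates", {
  expect_equal(compute_dprime(5, 5, 5, 5)$dprime, 0)
  # full clipping: rates 0.95 / 0.05
  r <- compute_dprime(10, 0, 0, 10)
  expect_equal(r$hit_rate, 0.95)
  expect_equal(r$fa_rate, 0.05)
  expect_equal(r$dprime, 2 * qnorm(0.95), tolerance = 1e-12)
  expect_equal(r$dprime, 3.2897, tolerance = 1e-4)
  # z(0.69146) = 0.5 so these rates give d' = 1
  r2 <- compute_dprime(69146, 100000 - 69146, 30854, 100000 - 30854)
  expect_equal(r2$dprime, 1, tolerance = 1e-3)
  expect_error(compute_dprime(0, 0, 1, 1), "at least one")
})

test_that("d-prime oracle agreement, antisymmetry and clipping bound", {
  set.seed(77)
  for (i in 1:1000) {
    n_go <- sample(1:500, 1); n_nogo <- sample(1:500, 1)
    h <- sample(0:n_go, 1); f <- sample(0:n_nogo, 1)
    r <- compute_dprime(h, n_go - h, f, n_nogo - f)
    # independent oracle: direct inverse-normal evaluation
    hr <- h / n_go; fr <- f / n_nogo
    hr <- min(max(hr, 1 / (2 * n_go)), 1 - 1 / (2 * n_go))
    fr <- min(max(fr, 1 / (2 * n_nogo)), 1 - 1 / (2 * n_nogo))
    expect_equal(r$dprime, qnorm(hr) - qnorm(fr), tolerance = 1e-9)
    # antisymmetry
    expect_equal(compute_dprime(f, n_nogo - f, h, n_go - h)$dprime,
                 -r$dprime, tolerance = 1e-9)
    # clipping bound
    expect_lte(abs(r$dprime),
               qnorm(1 - 1 / (2 * n_go)) + qnorm(1 - 1 / (2 * n_nogo)) + 1e-12)
  }
  # monotonicity in hits and false alarms
  d_seq <- vapply(1:9, function(h) compute_dprime(h, 10 - h, 3, 7)$dprime,
                  numeric(1))
  expect_true(all(diff(d_seq) > 0))
  d_fa <- vapply(1:9, function(f) compute_dprime(5, 5, f, 10 - f)$dprime,
                 numeric(1))
  expect_true(all(diff(d_fa) < 0))
})

test_that("expert threshold reproduces the tabulated one-tailed z values", {
  expect_equal(expert_threshold(0.05), 1.65)
  expect_equal(expert_threshold(0.5), 0)
  expect_equal(expert_threshold(0.025), 1.96)
  expect_error(expert_threshold(0), "alpha")
  expect_error(expert_threshold(1.2), "alpha")
})

test_that("running d-prime behaves at chance, at ceiling, and with long windows", {
  chance <- learner_params(p_lick_go_initial = 0.5, p_lick_go_final = 0.5,
                           p_lick_nogo_initial = 0.5,
                           p_lick_nogo_final = 0.5)
  s <- generate_session_events("initial", chance, 600, seed = 71)
  rd <- running_dprime(s, window = 200)
  defined <- rd$dprime[!is.na(rd$dprime) & rd$trial_index > 200]
  expect_lt(mean(abs(defined)), 0.5)

  perfect <- learner_params(p_lick_go_initial = 1, p_lick_go_final = 1,
                            p_lick_nogo_initial = 0, p_lick_nogo_final = 0)
  sp <- generate_session_events("initial", perfect, 400, seed = 72)
  rdp <- running_dprime(sp, window = 200)
  n_go_win <- sum(sp$is_go[201:400])
  n_nogo_win <- 200 - n_go_win
  expect_equal(rdp$dprime[400],
               qnorm(1 - 1 / (2 * n_go_win)) +
                 qnorm(1 - 1 / (2 * n_nogo_win)),
               tolerance = 1e-9)

  # window larger than the session: last value equals the session d'
  s_small <- fixture_session(50, seed = 73)
  rd_all <- running_dprime(s_small, window = 1000)
  expect_equal(rd_all$dprime[50], session_dprime(s_small)$dprime)
})

test_that("success rates follow the count ratios", {
  cnt <- tibble::tibble(n_hit = 8, n_miss = 2, n_fa = 3, n_cr = 7)
  r <- success_rates(cnt)
  expect_equal(unlist(r), c(go_rate = 0.8, nogo_rate = 0.7,
                            all_rate = 0.75))
  r2 <- success_rates(tibble::tibble(n_hit = 10, n_miss = 0, n_fa = 0,
                                     n_cr = 10))
  expect_equal(unlist(r2), c(go_rate = 1, nogo_rate = 1, all_rate = 1))
  r3 <- success_rates(tibble::tibble(n_hit = 0, n_miss = 0, n_fa = 2,
                                     n_cr = 2))
  expect_true(is.na(r3$go_rate))
})

test_that("moment of insight detection applies the factor-of-five rule", {
  expect_equal(detect_insight(c(0.1, 0.5, 0.6)), 2L)
  expect_true(is.na(detect_insight(c(0.4, 0.6, 0.9))))
  expect_true(is.na(detect_insight(c(0.0, 0.3))))
  expect_error(detect_insight(0.5), "2 sessions")
  pop <- population_insight(tibble::tibble(
    animal = rep(c("m1", "m2"), each = 5),
    session_index = rep(1:5, 2),
    nogo_rate = c(0.1, 0.1, 0.55, 0.6, 0.7,
                  0.05, 0.3, 0.35, 0.4, 0.5)))
  expect_equal(pop$per_animal$insight_session, c(3L, 2L))
  expect_equal(pop$mean_progression, mean(c(2 / 4, 1 / 4)))
})

test_that("expert criterion requires sessions and trials above threshold", {
  d3 <- tibble::tibble(session_index = 1:3, dprime = c(2, 2, 2),
                       n_trials = c(100, 100, 100))
  expect_equal(nrow(expert_criterion(d3)), 0)
  d6 <- tibble::tibble(session_index = 1:6,
                       dprime = c(0.5, 2, 2, 2, 2, 2),
                       n_trials = rep(60, 6))
  res <- expert_criterion(d6)
  expect_equal(res$session_index, 5L)
  chance <- tibble::tibble(session_index = 1:8, dprime = rep(0.1, 8),
                           n_trials = rep(100, 8))
  expect_equal(nrow(expert_criterion(chance)), 0)
})

test_that("a simulated expert learner reaches criterion near its configured rise", {
  learner <- learner_params(learning_midpoint_trials = 400,
                            learning_rate = 0.02)
  s <- generate_session_events("initial", learner, 900, seed = 74)
  rd <- running_dprime(s, window = 200)
  cross <- first_sustained_crossing(rd, sustain = 100)
  expect_false(is.na(cross))
  # midpoint 400 + logistic rise (~2/rate) + half the 200-trial window lag
  expected <- 400 + 100
  expect_lt(abs(cross - expected) / expected, 0.5)
  expect_gt(session_dprime(s[s$trial_index > 500, ])$dprime, 1.65)
})

test_that("logistic learning-curve fits recover known parameters", {
  x <- 1:800
  true <- c(floor = 0, ceiling = 3, midpoint = 400, slope = 0.015)
  y <- true[1] + (true[2] - true[1]) /
    (1 + exp(-true[4] * (x - true[3])))
  fit <- fit_learning_curve(tibble::tibble(trial_index = x, dprime = y))
  expect_true(fit$converged)
  expect_equal(unname(fit$params["midpoint"]), 400, tolerance = 1e-3)
  expect_equal(unname(fit$params["slope"]), 0.015, tolerance = 1e-3)
  # flat series: slope ~ 0 effect (fitted curve nearly constant)
  flat <- fit_learning_curve(tibble::tibble(trial_index = x,
                                            dprime = rep(1.2, 800)))
  expect_lt(diff(range(flat$fitted)), 0.05)
  # noisy simulated learner: midpoint within 15%
  set.seed(75)
  yn <- y + rnorm(800, 0, 0.3)
  fitn <- fit_learning_curve(tibble::tibble(trial_index = x, dprime = yn))
  expect_lt(abs(fitn$params["midpoint"] - 400) / 400, 0.15)
})

test_that("lick-latency fits recover the asymptotic model", {
  x <- 1:300
  y <- 0.2 + 0.6 * exp(-0.01 * x)
  fit <- fit_lick_latency(tibble::tibble(trial_index = x, latency_s = y))
  expect_equal(unname(fit$params), c(0.2, 0.6, 0.01), tolerance = 1e-3)
  # constant latencies: b ~ 0
  fitc <- fit_lick_latency(tibble::tibble(trial_index = x,
                                          latency_s = rep(0.25, 300)))
  expect_lt(abs(fitc$params["b"]), 1e-4)
  # noisy: asymptote recovered within 0.03 s
  set.seed(76)
  yn <- y + rnorm(300, 0, 0.05)
  fitn <- fit_lick_latency(tibble::tibble(trial_index = x, latency_s = yn))
  expect_lt(abs(fitn$params["a"] - 0.2), 0.03)
  expect_error(fit_lick_latency(tibble::tibble(trial_index = 1:3,
                                               latency_s = c(1, 2, 3))),
               "at least 5")
})

test_that("retraction metrics locate the turning point", {
  # triangular trajectory peaking 0.8 s after beam, 50 mm past the aperture
  t <- seq(0, 2, by = 1 / 60)
  x <- ifelse(t <= 0.8, 100 * t / 0.8, 100 - 80 * (t - 0.8))
  snout <- tibble::tibble(t = t, x = x)
  m <- retraction_metrics(snout, t_touch = 0.2, t_beam = 0,
                          aperture_x = 50)
  expect_equal(m$retraction_time_s, 0.8, tolerance = 1 / 60)
  expect_equal(m$retraction_distance_mm, 50, tolerance = 100 / 48)
  # two equal maxima: earliest wins
  x2 <- c(0, 5, 10, 10, 4, 2)
  m2 <- retraction_metrics(tibble::tibble(t = 0:5, x = x2), t_touch = 0,
                           t_beam = 0, aperture_x = 0)
  expect_equal(m2$turn_t, 2)
  # monotone trajectory: none-marker (zero rows)
  m3 <- retraction_metrics(tibble::tibble(t = 0:5, x = 0:5 * 10),
                           t_touch = 0, t_beam = 0, aperture_x = 0)
  expect_equal(nrow(m3), 0)
  expect_error(retraction_metrics(snout, 0.2, 0, 50, licked = TRUE),
               "CR")
})
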