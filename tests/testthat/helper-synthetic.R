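# Shared fixture builders; everything is generated in code at test time.

# A short scored session with deterministic-ish learner.
fixture_session <- function(n_trials = 60, seed = 42, stage = "initial",
                            iti = c(4, 6)) {
  generate_session_events(stage, learner_params(), n_trials, seed = seed,
                          iti_range_s = iti)
}

# Homogeneous-Poisson spike table (no tuning), one unit.
fixture_poisson_spikes <- function(rate_hz = 10, duration = 100, seed = 1,
                                   unit_id = "u01") {
  n <- with_seed_local(seed, rpois(1, rate_hz * duration))
  t <- with_seed_local(seed + 1, sort(runif(n, 0, duration)))
  tibble::tibble(unit_id = unit_id, t = t)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Pure-tone angle trace at a given frequency (continuous whisking).
fixture_sine_trace <- function(freq_hz = 14.5, amp_pp = 20, duration = 60,
                               fps = 240, mid = 90) {
  t <- seq_len(floor(duration * fps)) / fps
  structure(
    tibble::as_tibble(list(t = t,
                           angle = mid + (amp_pp / 2) * cos(2 * pi * freq_hz * t))),
    fps = fps, class = c("wt_angle_trace", class(tibble::tibble())))
}
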