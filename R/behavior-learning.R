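#' Moment of insight from per-session no-go success rates
#'
#' The first session whose no-go success rate is at least `factor` times
#' the previous session's rate (previous rate strictly positive; a zero
#' denominator never qualifies).
#'
#' @param nogo_rates Numeric vector of per-session no-go success rates.
#' @param factor Required session-to-session jump factor.
#' @return Session index (position in `nogo_rates`), or `NA` if absent.
#' @export
detect_insight <- function(nogo_rates, factor = 5) {
  if (length(nogo_rates) < 2) abort("need at least 2 sessions")
  prev <- nogo_rates[-length(nogo_rates)]
  cur <- nogo_rates[-1]
  hit <- which(prev > 0 & cur / prev >= factor)
  if (length(hit)) hit[1] + 1L else NA_integer_
}

#' Population moment of insight
#'
#' Each animal's insight session is mapped onto a normalized stage
#' progression axis in \[0, 1\] (session j of m maps to (j - 1)/(m - 1)),
#' and the mean across animals with a detected insight is returned.
#'
#' @param rates_by_animal Tibble with columns `animal`, `session_index`,
#'   `nogo_rate` (sessions ordered within animal).
#' @param factor Jump factor passed to [detect_insight()].
#' @return A list with `mean_progression` (in \[0, 1\], `NA` if no animal
#'   shows insight) and `per_animal` (tibble: `animal`, `insight_session`,
#'   `progression`).
#' @export
population_insight <- function(rates_by_animal, factor = 5) {
  per <- rates_by_animal |>
    dplyr::group_by(.data$animal) |>
    dplyr::arrange(.data$session_index, .by_group = TRUE) |>
    dplyr::summarise(
      insight_session = detect_insight(.data$nogo_rate, factor = factor),
      n_sessions = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(progression = (.data$insight_session - 1) /
                    pmax(1, .data$n_sessions - 1))
  list(mean_progression = mean(per$progression, na.rm = TRUE),
       per_animal = per)
}

#' Four-parameter logistic fit of a d' learning curve
#'
#' Least-squares fit of d'(i) = floor + (ceiling - floor) /
#' (1 + exp(-slope (i - midpoint))) over trial index, with a small
#' multistart over midpoint and slope. The slope is the learning speed.
#'
#' @param dprime_series Tibble with `trial_index`, `dprime` (`NA` gaps
#'   allowed and dropped).
#' @param n_starts Number of random restarts beyond the grid starts.
#' @param seed Seed for the random restarts.
#' @return A `wt_learning_fit` object (list with `params`, `fitted`,
#'   `residuals`, `converged`, `rss`); non-convergence is flagged with
#'   `NaN` slope.
#' @export
fit_learning_curve <- function(dprime_series, n_starts = 10, seed = 1) {
  d <- dplyr::filter(dprime_series, !is.na(.data$dprime))
  x <- d$trial_index; y <- d$dprime
  if (length(x) < 8) abort("need at least 8 defined d' values")
  model <- function(p, x) p[1] + (p[2] - p[1]) /
    (1 + exp(-p[4] * (x - p[3])))
  starts <- with_seed(seed, {
    base <- list(c(min(y), max(y), stats::median(x), 0.01),
                 c(min(y), max(y), stats::quantile(x, 0.25), 0.05),
                 c(0, max(y), stats::quantile(x, 0.75), 0.002))
    rand <- purrr::map(seq_len(n_starts), ~ c(
      runif(1, min(y), stats::median(y)), runif(1, stats::median(y), max(y) + 1),
      runif(1, min(x), max(x)), 10^runif(1, -3, -0.5)))
    c(base, rand)
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p, x),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    params <- c(floor = NaN, ceiling = NaN, midpoint = NaN, slope = NaN)
    return(structure(list(params = params, fitted = rep(NA_real_, length(x)),
                          residuals = rep(NA_real_, length(x)),
                          converged = FALSE, rss = NaN,
                          data = d), class = "wt_learning_fit"))
  }
  p <- best$fit$par
  names(p) <- c("floor", "ceiling", "midpoint", "slope")
  structure(list(params = p, fitted = model(p, x),
                 residuals = y - model(p, x), converged = TRUE,
                 rss = best$rss, data = d),
            class = "wt_learning_fit")
}

#' Asymptotic fit of lick latencies over trials
#'
#' Fits y = a + b exp(-c x) to per-trial lick latencies by least squares
#' with a multistart (>= 20 random starts). `a` is the latency asymptote,
#' `b` the initial deviation from it, and `c` the decay rate of latency
#' reduction across trials. By default `a` is a free parameter initialized
#' at the median latency; `fix_asymptote = TRUE` pins it there instead.
#'
#' @param latencies Tibble with `trial_index`, `latency_s`.
#' @param n_starts Number of random starts (>= 20 by default).
#' @param fix_asymptote Fix `a` at the median latency rather than fitting.
#' @param seed Seed for the random starts.
#' @return A `wt_lick_fit` object (list with `params` = c(a, b, c), `rss`,
#'   `fitted`, `residuals`, `converged`).
#' @export
fit_lick_latency <- function(latencies, n_starts = 20,
                             fix_asymptote = FALSE, seed = 1) {
  x <- latencies$trial_index; y <- latencies$latency_s
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) abort("need at least 5 lick latencies")
  med <- median(y)
  model <- function(p, x) {
    a <- if (fix_asymptote) med else p[1]
    a + p[2] * exp(-pmax(p[3], 0) * x)
  }
  starts <- with_seed(seed, purrr::map(seq_len(n_starts), ~ c(
    med * runif(1, 0.5, 1.5),
    (y[which.min(x)] - med) * runif(1, 0.2, 2) + rnorm(1, 0, 0.05),
    10^runif(1, -4, -0.5))))
  starts <- c(list(c(med, y[which.min(x)] - med, 0.01)), starts)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p, x),
                         lower = c(-Inf, -Inf, 0),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) abort("lick-latency fit failed to converge")
  p <- best$fit$par
  a <- if (fix_asymptote) med else p[1]
  params <- c(a = a, b = p[2], c = max(p[3], 0))
  structure(list(params = params, rss = best$rss,
                 fitted = model(p, x), residuals = y - model(p, x),
                 converged = TRUE,
                 data = tibble::tibble(trial_index = x, latency_s = y)),
            class = "wt_lick_fit")
}

#' Retraction metrics of a correct-rejection approach
#'
#' During CR trials mice turn away from the lick port after palpating the
#' no-go aperture. The turning point is the global maximum of the approach
#' coordinate after touch (earliest sample on ties); retraction time is
#' measured from the beam break to the turning point and retraction
#' distance from the turning point to the aperture position.
#'
#' @param snout Tibble with `t` (s) and `x` (mm, approach coordinate
#'   increasing toward the lick port).
#' @param t_touch,t_beam Touch and beam-break times (s).
#' @param aperture_x Aperture position on the approach coordinate (mm).
#' @param licked Whether the trial ended in a lick; must be `FALSE` (this
#'   metric is defined for CR trials only).
#' @return A one-row tibble with `retraction_time_s`,
#'   `retraction_distance_mm`, `turn_t`, `turn_x`; a zero-row tibble if the
#'   trajectory never turns (monotone approach).
#' @export
retraction_metrics <- function(snout, t_touch, t_beam, aperture_x,
                               licked = FALSE) {
  if (isTRUE(licked)) abort("retraction metrics are defined for CR (no-lick) trials")
  post <- dplyr::filter(snout, .data$t >= t_touch)
  if (nrow(post) < 2) abort("trajectory does not span the post-touch period")
  i <- which.max(post$x)   # which.max takes the earliest maximum
  if (i == nrow(post)) {
    # monotone approach: never turns
    return(tibble::tibble(retraction_time_s = numeric(0),
                          retraction_distance_mm = numeric(0),
                          turn_t = numeric(0), turn_x = numeric(0)))
  }
  tibble::tibble(
    retraction_time_s = post$t[i] - t_beam,
    retraction_distance_mm = abs(post$x[i] - aperture_x),
    turn_t = post$t[i], turn_x = post$x[i]
  )
}
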