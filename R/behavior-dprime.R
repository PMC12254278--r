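#' Signal-detection discriminability (d-prime) from trial counts
#'
#' d' = z(hit rate) - z(false alarm rate), with the standard clipping for
#' degenerate rates: a rate of 0 is adjusted to 1/(2n) and a rate of 1 to
#' 1 - 1/(2n), where n is the number of go trials (hit rate) or no-go
#' trials (FA rate).
#'
#' @param n_hit,n_miss,n_fa,n_cr Trial counts (vectors recycle).
#' @return A `wt_dprime` tibble with `hit_rate`, `fa_rate` (post-clipping),
#'   `n_go`, `n_nogo`, `dprime`.
#' @export
compute_dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  n_go <- n_hit + n_miss
  n_nogo <- n_fa + n_cr
  if (any(n_go < 1) || any(n_nogo < 1)) {
    abort("need at least one go and one no-go trial")
  }
  clip <- function(k, n) {
    r <- k / n
    r[r == 0] <- 1 / (2 * n[r == 0])
    r[r == 1] <- 1 - 1 / (2 * n[r == 1])
    r
  }
  hit_rate <- clip(n_hit, n_go)
  fa_rate <- clip(n_fa, n_nogo)
  new_wt_tbl(
    tibble::tibble(hit_rate = hit_rate, fa_rate = fa_rate,
                   n_go = n_go, n_nogo = n_nogo,
                   dprime = qnorm(hit_rate) - qnorm(fa_rate)),
    class = "wt_dprime"
  )
}

#' d-prime of a scored session
#'
#' Computed over scored trials only; neutral-aperture and extinction trials
#' (score `"none"`) are excluded from the rates.
#'
#' @param session A scored `wt_session`.
#' @return A `wt_dprime` tibble (see [compute_dprime()]).
#' @export
session_dprime <- function(session) {
  cnt <- score_counts(session)
  compute_dprime(cnt$n_hit, cnt$n_miss, cnt$n_fa, cnt$n_cr)
}

#' Expert-performance threshold on the d' scale
#'
#' The z-value of a one-tailed significance level `alpha`, rounded to two
#' decimals for reporting with the conventional half-up rule applied at
#' the third decimal first (z = 1.6449 is tabulated as 1.645 and reported
#' as 1.65); alpha = 0.05 gives the 1.65 expert criterion.
#'
#' @param alpha One-tailed significance level in (0, 1).
#' @export
expert_threshold <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  half_up <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  half_up(half_up(qnorm(1 - alpha), 3), 2)
}

#' Running-window d-prime over trials
#'
#' At trial i, d' is computed from the scored trials in the half-open
#' window (i - window, i] (the preceding `window` trials, inclusive of i).
#' Windows lacking either trial class yield `NA` (a gap). The first
#' crossing of `threshold` is reported as an attribute and by
#' [first_sustained_crossing()].
#'
#' @param trials A scored session (ordered trials).
#' @param window Window length in trials.
#' @param threshold Expert threshold on the d' scale.
#' @return A `wt_running_dprime` tibble with `trial_index`, `dprime`;
#'   attributes `window`, `threshold`, `first_crossing` (trial index or
#'   `NA`).
#' @export
running_dprime <- function(trials, window = 200, threshold = 1.65) {
  if (window < 1) abort("window must be >= 1")
  sc <- trials$score
  is_hit <- cumsum(sc == "hit"); is_miss <- cumsum(sc == "miss")
  is_fa <- cumsum(sc == "FA"); is_cr <- cumsum(sc == "CR")
  n <- length(sc)
  win_sum <- function(cs, i) {
    prev <- numeric(length(i))
    has_prev <- i - window >= 1
    prev[has_prev] <- cs[i[has_prev] - window]
    cs[i] - prev
  }
  i <- seq_len(n)
  h <- win_sum(is_hit, i); m <- win_sum(is_miss, i)
  f <- win_sum(is_fa, i); c <- win_sum(is_cr, i)
  ok <- (h + m) >= 1 & (f + c) >= 1
  dp <- rep(NA_real_, n)
  if (any(ok)) dp[ok] <- compute_dprime(h[ok], m[ok], f[ok], c[ok])$dprime
  fc <- which(!is.na(dp) & dp >= threshold)
  new_wt_tbl(
    tibble::tibble(trial_index = trials$trial_index, dprime = dp),
    class = "wt_running_dprime", window = window, threshold = threshold,
    first_crossing = if (length(fc)) trials$trial_index[fc[1]] else NA_integer_
  )
}

#' First sustained crossing of the expert threshold
#'
#' The earliest trial at which the running d' reaches `threshold` and stays
#' at or above it for at least `sustain` subsequent defined values (or to
#' the end of the series, whichever is shorter).
#'
#' @param rd A `wt_running_dprime` tibble.
#' @param threshold d' threshold.
#' @param sustain Number of subsequent trials the crossing must hold for.
#' @return Trial index, or `NA` if never sustained.
#' @export
first_sustained_crossing <- function(rd, threshold = 1.65, sustain = 100) {
  dp <- rd$dprime
  n <- length(dp)
  above <- !is.na(dp) & dp >= threshold
  for (i in which(above)) {
    j <- min(n, i + sustain)
    seg <- dp[i:j]
    if (all(seg[!is.na(seg)] >= threshold)) return(rd$trial_index[i])
  }
  NA_integer_
}

#' Expert-level criterion over sessions
#'
#' The stage criterion: at least `min_sessions` sessions with session d'
#' above `threshold` and at least `min_trials` trials accumulated within
#' those above-threshold sessions. Returns the earliest session at which
#' both hold.
#'
#' @param sessions Tibble with one row per session: `session_index`,
#'   `dprime`, `n_trials`.
#' @param min_sessions,min_trials Criterion components.
#' @param threshold d' threshold.
#' @return A one-row tibble with `session_index` and `cumulative_trials`,
#'   or a zero-row tibble if the criterion is never met.
#' @export
expert_criterion <- function(sessions, min_sessions = 4, min_trials = 200,
                             threshold = 1.65) {
  above <- sessions$dprime > threshold
  n_above <- cumsum(above)
  trials_above <- cumsum(ifelse(above, sessions$n_trials, 0))
  hit <- which(n_above >= min_sessions & trials_above >= min_trials)
  if (!length(hit)) {
    return(tibble::tibble(session_index = integer(0),
                          cumulative_trials = numeric(0)))
  }
  j <- hit[1]
  tibble::tibble(session_index = sessions$session_index[j],
                 cumulative_trials = sum(sessions$n_trials[seq_len(j)]))
}
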