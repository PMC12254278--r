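#' Spatial tuning: Gaussian place field with a linear speed term
#'
#' Firing rates are computed in 100 ms time bins and averaged by maze
#' position (20 mm spatial bins). The position-binned rates are modeled as
#' rate(x, v) = A exp(-(x - mu)^2 / (2 sigma^2)) + speed_coef v +
#' intercept, fitted by nonlinear least squares with a multistart over mu
#' (position-bin quantiles) and sigma (20, 40, 80 mm). A unit is
#' spatially tuned when the Gaussian amplitude differs significantly from
#' zero (0 outside its 95% confidence interval) *and* the linear speed
#' coefficient is non-significant (0 inside its 95% CI), indicating a
#' location-specific response independent of locomotor velocity.
#' Non-convergence over the multistart yields an untuned result with
#' `converged = FALSE`.
#'
#' @param spikes Tibble with `unit_id`, `t`.
#' @param position A `wt_position_trace` (`t`, `x`, `velocity`).
#' @param time_bin_s Time bin for rate estimation (s).
#' @param pos_bin_mm Spatial bin width (mm).
#' @param range_mm Track extent (mm).
#' @param sigma_starts Multistart values for sigma (mm).
#' @param n_mu_starts Number of mu start values (position quantiles).
#' @param conf Confidence level for the classification CIs.
#' @param n_shuffles,seed Circular-shift shuffle null for the spatial
#'   structure gate: the occupancy-weighted variance of the binned rates
#'   must exceed its shuffle 95th percentile before a unit can be called
#'   tuned. This protects the amplitude CI (whose linearization does not
#'   account for the search over field position) from latching onto
#'   sampling noise.
#' @return A `wt_spatial_tuning` tibble, one row per unit: parameter
#'   estimates (`A`, `mu`, `sigma`, `speed_coef`, `intercept`), their
#'   standard errors and CI bounds, `structure_sig` (shuffle gate),
#'   `spatially_tuned`, `converged`, and a `curve` list-column of
#'   position-binned rates.
#' @export
spatial_tuning <- function(spikes, position, time_bin_s = 0.1,
                           pos_bin_mm = 20, range_mm = c(-410, 410),
                           sigma_starts = c(20, 40, 80), n_mu_starts = 5,
                           conf = 0.95, n_shuffles = 100, seed = 1) {
  fps <- trace_fps(position)
  duration <- max(position$t)
  n_tbins <- floor(duration / time_bin_s)
  tb <- findInterval(position$t, seq(0, duration, by = time_bin_s),
                     rightmost.closed = FALSE)
  tb[tb < 1 | tb > n_tbins] <- NA_integer_
  frame_df <- tibble::tibble(tb = tb, x = position$x,
                             v = abs(position$velocity))
  bin_pos <- frame_df |>
    dplyr::filter(!is.na(.data$tb)) |>
    dplyr::group_by(.data$tb) |>
    dplyr::summarise(x = mean(.data$x), v = mean(.data$v),
                     .groups = "drop")
  pos_edges <- seq(range_mm[1], range_mm[2], by = pos_bin_mm)
  z <- qnorm(1 - (1 - conf) / 2)
  tgrid <- seq(0, duration, by = time_bin_s)
  bin_pos <- dplyr::mutate(
    bin_pos, pbin = findInterval(.data$x, pos_edges, rightmost.closed = TRUE))
  bin_pos <- dplyr::filter(bin_pos, .data$pbin >= 1,
                           .data$pbin < length(pos_edges))
  bin_rates <- function(cnt) {
    dplyr::group_by(
      dplyr::mutate(bin_pos, rate = cnt[.data$tb] / time_bin_s),
      .data$pbin) |>
      dplyr::summarise(x = mean(.data$x), v = mean(.data$v),
                       rate = mean(.data$rate), n = dplyr::n(),
                       .groups = "drop")
  }
  wvar <- function(dat) {
    w <- dat$n / sum(dat$n)
    sum(w * (dat$rate - sum(w * dat$rate))^2)
  }
  # fast path for the shuffle null: occupancy-weighted variance of the
  # position-binned rates, computed with rowsum instead of dplyr
  bp_tb <- bin_pos$tb
  bp_pbin <- factor(bin_pos$pbin)
  npb <- as.numeric(table(bp_pbin))
  wpb <- npb / sum(npb)
  wvar_cnt <- function(cnt) {
    r <- rowsum(cnt[bp_tb] / time_bin_s, bp_pbin) / npb
    sum(wpb * (r - sum(wpb * r))^2)
  }
  units <- unique(spikes$unit_id)
  purrr::map(units, function(u) {
    ts <- spikes$t[spikes$unit_id == u]
    cnt <- tabulate(findInterval(ts, tgrid), nbins = n_tbins)
    dat <- bin_rates(cnt)
    # shuffle gate: spatial structure beyond the circular-shift null
    shifts <- with_seed(substream_seed(seed, paste0("spatial_", u)),
                        runif(n_shuffles, 0, duration))
    null_var <- vapply(shifts, function(s) {
      wvar_cnt(tabulate(findInterval((ts + s) %% duration, tgrid),
                        nbins = n_tbins))
    }, numeric(1))
    structure_sig <- wvar(dat) > quantile(null_var, 0.95, names = FALSE)
    fit <- fit_place_field(dat, sigma_starts, n_mu_starts,
                           sigma_min = pos_bin_mm)
    if (is.null(fit)) {
      return(tibble::tibble(
        unit_id = u, A = NA_real_, mu = NA_real_, sigma = NA_real_,
        speed_coef = NA_real_, intercept = NA_real_,
        A_se = NA_real_, speed_se = NA_real_,
        A_lo = NA_real_, A_hi = NA_real_,
        speed_lo = NA_real_, speed_hi = NA_real_,
        structure_sig = structure_sig,
        spatially_tuned = FALSE, converged = FALSE, curve = list(dat)))
    }
    p <- fit$par; se <- fit$se
    a_lo <- p[1] - z * se[1]; a_hi <- p[1] + z * se[1]
    s_lo <- p[4] - z * se[4]; s_hi <- p[4] + z * se[4]
    tibble::tibble(
      unit_id = u, A = p[1], mu = p[2], sigma = abs(p[3]),
      speed_coef = p[4], intercept = p[5],
      A_se = se[1], speed_se = se[4],
      A_lo = a_lo, A_hi = a_hi, speed_lo = s_lo, speed_hi = s_hi,
      structure_sig = structure_sig,
      spatially_tuned = structure_sig & (a_lo > 0 | a_hi < 0) &
        (s_lo <= 0 & s_hi >= 0),
      converged = TRUE, curve = list(dat)
    )
  }) |> dplyr::bind_rows() |> new_wt_tbl(class = "wt_spatial_tuning")
}

# Multistart Gaussian + speed fit on position-binned data; returns NULL if
# no start converges with an invertible information matrix. The fit is
# weighted by time-in-bin (rate estimates from well-sampled bins are more
# reliable) and sigma is bounded below by the spatial bin width: narrower
# fields are unresolvable at the binning resolution, and an unbounded
# sigma lets the Gaussian collapse onto a single noisy bin.
fit_place_field <- function(dat, sigma_starts, n_mu_starts,
                            sigma_min = 20) {
  if (nrow(dat) < 6) return(NULL)
  wts <- sqrt(dat$n / mean(dat$n))
  model <- function(p, d) {
    p[1] * exp(-(d$x - p[2])^2 / (2 * p[3]^2)) + p[4] * d$v + p[5]
  }
  mu_starts <- unname(quantile(dat$x, seq(0.1, 0.9,
                                          length.out = n_mu_starts)))
  span <- diff(range(dat$x))
  amp0 <- max(dat$rate) - min(dat$rate)
  best <- NULL
  lower <- c(-Inf, min(dat$x), sigma_min, -Inf, -Inf)
  upper <- c(Inf, max(dat$x), span, Inf, Inf)
  for (mu0 in mu_starts) for (s0 in sigma_starts) {
    p0 <- c(amp0, mu0, max(s0, sigma_min), 0, min(dat$rate))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, fn = function(p) wts * (dat$rate - model(p, dat)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(NULL)
  fit <- best$fit
  dof <- nrow(dat) - 5
  if (dof < 1) return(NULL)
  covm <- tryCatch(solve(fit$hessian) * best$rss / dof,
                   error = function(e) NULL)
  if (is.null(covm)) {
    # near-singular information (e.g. amplitude ~ 0 leaves mu/sigma
    # unidentified): ridge-regularize; the inflated SEs keep 0 inside the
    # amplitude CI, classifying the unit as untuned
    h <- fit$hessian
    covm <- tryCatch(solve(h + diag(1e-8 * max(diag(h), 1), nrow(h))) *
                       best$rss / dof,
                     error = function(e) NULL)
  }
  if (is.null(covm) || any(!is.finite(diag(covm))) ||
      any(diag(covm) < 0)) return(NULL)
  list(par = fit$par, se = sqrt(diag(covm)), rss = best$rss)
}
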