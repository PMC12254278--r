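#' Score a raw event stream into trials
#'
#' Reconstructs trials from the event-list dialect (`t_s`, `device`,
#' `value`): an aperture-state announcement followed by an outer-beam
#' crossing opens a trial; the trial resolves with the first subsequent
#' lick on the same side, or without a lick when the next trial begins (or
#' the stream ends). Each resolved episode becomes one trial row scored
#' under the stage rule. Lick events with no open trial are counted and
#' dropped with a warning.
#'
#' @param events Tibble with columns `t_s`, `device`, `value`, ordered in
#'   time (re-sorted with a warning otherwise).
#' @param stage Stage name (see [stage_rules()]).
#' @param mouse_id,session_index Metadata attributes for the result.
#' @return A `wt_session` tibble (see [generate_session_events()]); the
#'   `t_touch` column is `NA` (touch times come from high-speed video, not
#'   the event list).
#' @export
score_trials <- function(events, stage, mouse_id = NA_character_,
                         session_index = 1L) {
  rules <- stage_rules(stage)
  if (is.unsorted(events$t_s)) {
    warn("event stream not time-ordered; re-sorting")
    events <- dplyr::arrange(events, .data$t_s)
  }
  n_orphan <- 0L
  aperture_state <- c(L = NA_real_, R = NA_real_)
  open <- NULL   # list(side, aperture, t_beam)
  trials <- list()
  outcomes <- list()
  close_trial <- function(open, lick, t_lick, outcome) {
    sc <- score_one(stage, open$aperture, lick)
    out <- if (sc$outcome == "random") outcome %||% "none" else sc$outcome
    tibble::tibble(
      side = if (open$side == "L") "left" else "right",
      aperture_mm = open$aperture,
      is_go = !is.na(rules$go_mm) && open$aperture == rules$go_mm,
      response = if (lick) "lick" else "no-lick",
      score = sc$score, outcome = out,
      t_beam = open$t_beam, t_touch = NA_real_, t_lick = t_lick
    )
  }
  for (i in seq_len(nrow(events))) {
    dev <- events$device[i]
    tv <- events$t_s[i]
    val <- events$value[i]
    if (dev %in% c("aperture_L", "aperture_R")) {
      aperture_state[substr(dev, 10, 10)] <- val
    } else if (dev %in% c("beam_L", "beam_R")) {
      side <- substr(dev, 6, 6)
      if (!is.null(open)) {
        trials[[length(trials) + 1L]] <- close_trial(open, FALSE, NA_real_,
                                                     NULL)
        open <- NULL
      }
      ap <- aperture_state[[side]]
      if (!is.na(ap)) open <- list(side = side, aperture = ap, t_beam = tv)
    } else if (dev %in% c("lick_L", "lick_R")) {
      side <- substr(dev, 6, 6)
      if (!is.null(open) && open$side == side) {
        # outcome device may follow; look ahead for it
        outcome <- NULL
        if (i < nrow(events) && events$device[i + 1] == "outcome") {
          outcome <- if (events$value[i + 1] > 0) "reward" else "punishment"
        }
        trials[[length(trials) + 1L]] <- close_trial(open, TRUE, tv, outcome)
        open <- NULL
      } else {
        n_orphan <- n_orphan + 1L
      }
    }
  }
  if (!is.null(open)) {
    trials[[length(trials) + 1L]] <- close_trial(open, FALSE, NA_real_, NULL)
  }
  if (n_orphan > 0) {
    warn(sprintf("%d lick event(s) with no open trial dropped", n_orphan))
  }
  out <- dplyr::bind_rows(trials)
  if (nrow(out)) out <- dplyr::mutate(out, trial_index = dplyr::row_number(),
                                      .before = 1)
  new_wt_tbl(out, class = "wt_session", mouse_id = mouse_id, stage = stage,
             session_index = session_index, n_orphan_licks = n_orphan)
}

#' Go / no-go / overall success rates
#'
#' Hit/(Hit+Miss), CR/(CR+FA) and (Hit+CR)/(Hit+Miss+CR+FA). Empty
#' denominators yield `NA`, never 0.
#'
#' @param trials A scored session, or a one-row counts tibble from
#'   [score_counts()].
#' @return A one-row tibble with `go_rate`, `nogo_rate`, `all_rate`.
#' @export
success_rates <- function(trials) {
  cnt <- if (all(c("n_hit", "n_miss", "n_fa", "n_cr") %in% names(trials))) {
    trials
  } else {
    score_counts(trials)
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  tibble::tibble(
    go_rate = safe_div(cnt$n_hit, cnt$n_hit + cnt$n_miss),
    nogo_rate = safe_div(cnt$n_cr, cnt$n_cr + cnt$n_fa),
    all_rate = safe_div(cnt$n_hit + cnt$n_cr,
                        cnt$n_hit + cnt$n_miss + cnt$n_cr + cnt$n_fa)
  )
}
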