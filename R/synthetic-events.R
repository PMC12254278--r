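#' Parametric go/no-go learner
#'
#' Describes a simulated animal's lick policy over the course of a stage.
#' Lick probabilities for go and no-go apertures follow logistic
#' trajectories in trial index from their initial to their final values,
#' with a shared midpoint and rate, emulating the gradual increase in lick
#' rates for the rewarded aperture and the drop for the punished one. An
#' optional `insight_trial` applies an abrupt step: from that trial on the
#' no-go lick probability is divided by `insight_factor` (>= 5 produces a
#' moment-of-insight signature in per-session no-go success rates).
#'
#' @param p_lick_go_initial,p_lick_go_final Lick probability on go trials at
#'   the start / end of the stage.
#' @param p_lick_nogo_initial,p_lick_nogo_final Same for no-go trials.
#' @param learning_midpoint_trials Trial index of the logistic midpoint.
#' @param learning_rate Logistic rate (1/trials).
#' @param insight_trial Optional trial index of the abrupt no-go improvement.
#' @param insight_factor Step factor (>= 1) dividing p_lick_nogo from
#'   `insight_trial` onward.
#' @return An object of class `wt_learner`.
#' @export
learner_params <- function(p_lick_go_initial = 0.5, p_lick_go_final = 0.95,
                           p_lick_nogo_initial = 0.5,
                           p_lick_nogo_final = 0.05,
                           learning_midpoint_trials = 200,
                           learning_rate = 0.02,
                           insight_trial = NULL, insight_factor = 5) {
  stopifnot_prob(c(p_lick_go_initial, p_lick_go_final,
                   p_lick_nogo_initial, p_lick_nogo_final), "p_lick")
  if (learning_midpoint_trials <= 0) abort("learning_midpoint_trials must be > 0")
  structure(list(p_lick_go_initial = p_lick_go_initial,
                 p_lick_go_final = p_lick_go_final,
                 p_lick_nogo_initial = p_lick_nogo_initial,
                 p_lick_nogo_final = p_lick_nogo_final,
                 learning_midpoint_trials = learning_midpoint_trials,
                 learning_rate = learning_rate,
                 insight_trial = insight_trial,
                 insight_factor = insight_factor),
            class = "wt_learner")
}

# Lick probabilities at (global) trial indices `i` for go / no-go stimuli.
learner_probs <- function(learner, i) {
  s <- 1 / (1 + exp(-(i - learner$learning_midpoint_trials) *
                      learner$learning_rate))
  p_go <- learner$p_lick_go_initial +
    (learner$p_lick_go_final - learner$p_lick_go_initial) * s
  p_nogo <- learner$p_lick_nogo_initial +
    (learner$p_lick_nogo_final - learner$p_lick_nogo_initial) * s
  if (!is.null(learner$insight_trial)) {
    post <- i >= learner$insight_trial
    p_nogo[post] <- p_nogo[post] / learner$insight_factor
  }
  list(go = p_go, nogo = p_nogo)
}

#' Simulate one scored behavioral session
#'
#' Draws an i.i.d. uniform aperture sequence from the stage's aperture set,
#' samples lick responses from the learner's trial-indexed lick
#' probabilities, and scores every trial under the stage rule (hit / miss /
#' FA / CR; neutral apertures and the extinction stage are unscored). In the
#' extinction stage the outcome of a lick is drawn uniformly from reward and
#' punishment, independent of the aperture.
#'
#' @param stage Stage name (see [stage_rules()]).
#' @param learner A [learner_params()] object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the session is a deterministic function of
#'   (arguments, seed).
#' @param mouse_id,session_index Metadata carried in attributes.
#' @param trial_start_index Global index of the first trial (so that learner
#'   trajectories continue across sessions).
#' @param iti_range_s Inter-trial interval range in seconds (uniform draw).
#' @return A `wt_session` tibble with one row per trial: `trial_index`,
#'   `side`, `aperture_mm`, `is_go`, `response`, `score`, `outcome`,
#'   `t_beam`, `t_touch`, `t_lick`.
#' @export
generate_session_events <- function(stage, learner, n_trials, seed = 1,
                                    mouse_id = "sim01", session_index = 1L,
                                    trial_start_index = 1L,
                                    iti_range_s = c(5, 15)) {
  r <- stage_rules(stage)
  if (n_trials < 1) abort("n_trials must be >= 1")
  with_seed(substream_seed(seed, "events"), {
    idx <- seq_len(n_trials)
    global_idx <- trial_start_index - 1L + idx
    aperture <- sample(r$apertures, n_trials, replace = TRUE)
    pr <- learner_probs(learner, global_idx)
    # extinction: the learner keeps licking per its go policy on every trial
    p_lick <- dplyr::case_when(
      !r$scored ~ pr$go,
      !is.na(r$neutral_mm) & aperture == r$neutral_mm ~
        (pr$go + pr$nogo) / 2,
      !is.na(r$go_mm) & aperture == r$go_mm ~ pr$go,
      TRUE ~ pr$nogo
    )
    lick <- runif(n_trials) < p_lick
    scored <- purrr::map2(aperture, lick, ~ score_one(stage, .x, .y))
    score <- purrr::map_chr(scored, "score")
    outcome <- purrr::map_chr(scored, "outcome")
    rand_out <- outcome == "random"
    outcome[rand_out] <- sample(c("reward", "punishment"),
                                sum(rand_out), replace = TRUE)
    iti <- runif(n_trials, iti_range_s[1], iti_range_s[2])
    t_beam <- cumsum(iti)
    t_touch <- t_beam + runif(n_trials, 0.2, 0.5)
    t_lick <- ifelse(lick, t_touch + runif(n_trials, 0.1, 0.6), NA_real_)
    side <- rep_len(c("left", "right"), n_trials)
    new_wt_tbl(
      tibble::tibble(
        trial_index = global_idx, side = side, aperture_mm = aperture,
        is_go = !is.na(r$go_mm) & aperture == r$go_mm,
        response = ifelse(lick, "lick", "no-lick"),
        score = score, outcome = outcome,
        t_beam = t_beam, t_touch = t_touch, t_lick = t_lick
      ),
      class = "wt_session", mouse_id = mouse_id, stage = stage,
      session_index = session_index, seed = seed
    )
  })
}

#' Serialize a session into the raw event-stream dialect
#'
#' Produces the event list the pipeline reads back: one row per device
#' event, columns `t_s`, `device`, `value`. Aperture state is announced
#' before the outer beam crossing; lick events appear on the lick port of
#' the trial side; outcomes are encoded on the `outcome` device
#' (1 = reward, -1 = punishment). Touch times are not part of the event
#' stream (they come from high-speed video) and are carried separately.
#'
#' @param session A `wt_session` tibble.
#' @return A tibble with columns `t_s`, `device`, `value`.
#' @export
session_to_events <- function(session) {
  rows <- purrr::pmap(session, function(trial_index, side, aperture_mm,
                                        is_go, response, score, outcome,
                                        t_beam, t_touch, t_lick, ...) {
    sd <- if (side == "left") "L" else "R"
    ev <- list(
      tibble::tibble(t_s = t_beam - 0.5,
                     device = paste0("aperture_", sd), value = aperture_mm),
      tibble::tibble(t_s = t_beam, device = paste0("beam_", sd), value = 1)
    )
    if (response == "lick") {
      ev <- c(ev, list(
        tibble::tibble(t_s = t_lick, device = paste0("lick_", sd), value = 1)
      ))
      if (outcome != "none") {
        ev <- c(ev, list(tibble::tibble(
          t_s = t_lick + 0.05, device = "outcome",
          value = if (outcome == "reward") 1 else -1
        )))
      }
    } else {
      # trial resolved by return through the middle beam
      ev <- c(ev, list(tibble::tibble(
        t_s = t_touch + 1.5, device = "beam_M", value = 1
      )))
    }
    dplyr::bind_rows(ev)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$t_s)
}

#' Score counts of a session
#'
#' @param session A scored session (or any tibble with a `score` column).
#' @return A one-row tibble with `n_hit`, `n_miss`, `n_fa`, `n_cr`, `n_none`.
#' @export
score_counts <- function(session) {
  tibble::tibble(
    n_hit = sum(session$score == "hit"),
    n_miss = sum(session$score == "miss"),
    n_fa = sum(session$score == "FA"),
    n_cr = sum(session$score == "CR"),
    n_none = sum(session$score == "none")
  )
}
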