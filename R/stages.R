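#' Training-stage rule table
#'
#' The paradigm advances through five stages. Each stage defines the set of
#' aperture widths presented (mm), which width is the go (rewarded-on-lick)
#' stimulus, which is the no-go, and whether trials are scored at all.
#' Habituation presents only the wide aperture; the neutral stage adds an
#' unscored 35 mm aperture between go and no-go; the reversed stage swaps
#' reward and punishment contingencies; extinction randomizes outcomes and
#' suspends scoring.
#'
#' @param stage Stage name, one of `"habituation"`, `"initial"`, `"neutral"`,
#'   `"reversed"`, `"extinction"`.
#' @return A list with elements `apertures`, `go_mm`, `nogo_mm`,
#'   `neutral_mm`, `scored`.
#' @export
stage_rules <- function(stage) {
  rules <- list(
    habituation = list(apertures = 45, go_mm = 45, nogo_mm = NA_real_,
                       neutral_mm = NA_real_, scored = TRUE),
    initial     = list(apertures = c(45, 25), go_mm = 45, nogo_mm = 25,
                       neutral_mm = NA_real_, scored = TRUE),
    neutral     = list(apertures = c(45, 35, 25), go_mm = 45, nogo_mm = 25,
                       neutral_mm = 35, scored = TRUE),
    reversed    = list(apertures = c(45, 25), go_mm = 25, nogo_mm = 45,
                       neutral_mm = NA_real_, scored = TRUE),
    extinction  = list(apertures = c(45, 25), go_mm = NA_real_,
                       nogo_mm = NA_real_, neutral_mm = NA_real_,
                       scored = FALSE)
  )
  if (!stage %in% names(rules)) {
    abort(sprintf("unknown stage '%s'; valid stages: %s", stage,
                  paste(names(rules), collapse = ", ")))
  }
  rules[[stage]]
}

# Score one (aperture, response) pair under the stage rule. Extinction and
# neutral-aperture trials are unscored ("none"); the deterministic part of
# the outcome is returned (extinction outcomes are drawn by the caller).
score_one <- function(stage, aperture_mm, lick) {
  r <- stage_rules(stage)
  if (!r$scored) {
    return(list(score = "none", outcome = if (lick) "random" else "none"))
  }
  if (!is.na(r$neutral_mm) && aperture_mm == r$neutral_mm) {
    return(list(score = "none", outcome = "none"))
  }
  if (!is.na(r$go_mm) && aperture_mm == r$go_mm) {
    if (lick) list(score = "hit", outcome = "reward")
    else list(score = "miss", outcome = "none")
  } else if (!is.na(r$nogo_mm) && aperture_mm == r$nogo_mm) {
    if (lick) list(score = "FA", outcome = "punishment")
    else list(score = "CR", outcome = "none")
  } else {
    abort(sprintf("aperture %g mm is not part of stage '%s'",
                  aperture_mm, stage))
  }
}
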