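#' Contingent (reinforcement) threshold update
#'
#' After an inter-individual regulation act, the agent evaluates whether the
#' received response was large enough to satisfy the regulation need measured
#' *before* the response. If `rsp > diff` the behaviour is positively
#' reinforced and its threshold decreases (the behaviour becomes more likely);
#' otherwise a need remains, the behaviour is negatively reinforced and its
#' threshold increases. Only the acted behaviour's threshold changes, and the
#' result is clamped to `[ts_floor, ts_ceiling]`.
#'
#' @param ts Current threshold of the acted behaviour.
#' @param action `"admiration"` or `"rivalry"` (the behaviour actually shown).
#' @param rsp Signed response received.
#' @param diff Regulation need before the response.
#' @param params A [learning_params()] object.
#' @return The updated threshold.
#' @export
#' @examples
#' contingent_update(0.08, "admiration", rsp = 0.08, diff = 0.05,
#'                   learning_params()) # success: threshold drops to 0.0795
contingent_update <- function(ts, action, rsp, diff, params) {
  if (!action %in% c("admiration", "rivalry")) {
    abort("Contingent learning applies only to inter-individual behaviours.")
  }
  out <- if (rsp > diff) ts - params$cl_step else ts + params$cl_step
  min(params$ts_ceiling, max(params$ts_floor, out))
}

#' Non-contingent threshold update
#'
#' Environmental over-/devaluation changes thresholds independently of the
#' agent's behaviour: overvaluation (non-contingent appreciation) lowers the
#' admiration threshold; devaluation (non-contingent depreciation) lowers the
#' rivalry threshold. Both respect the learning floor.
#'
#' @param ts_admi,ts_riva Current thresholds.
#' @param event `"overvaluation"`, `"devaluation"`, or `"none"`.
#' @param params A [learning_params()] object.
#' @return A named list with updated `ts_admi` and `ts_riva`.
#' @export
noncontingent_update <- function(ts_admi, ts_riva, event, params) {
  switch(
    event,
    none = list(ts_admi = ts_admi, ts_riva = ts_riva),
    overvaluation = list(ts_admi = max(params$ts_floor, ts_admi - params$ncl_step),
                         ts_riva = ts_riva),
    devaluation = list(ts_admi = ts_admi,
                       ts_riva = max(params$ts_floor, ts_riva - params$ncl_step)),
    abort("`event` must be one of \"overvaluation\", \"devaluation\", \"none\".")
  )
}

#' Sample a non-contingent environment event
#'
#' One mutually exclusive draw per agent per timestep: overvaluation with
#' probability `p_overvaluation`, devaluation with probability
#' `p_devaluation`, otherwise no event.
#'
#' @param profile An [environment_profile()] object.
#' @param n Number of independent draws (default 1).
#' @return A character vector of events.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_environment_event(environment_profile("overvaluing"), n = 1000))
sample_environment_event <- function(profile, n = 1) {
  p_over <- profile$p_overvaluation
  p_deval <- profile$p_devaluation
  if (p_over + p_deval > 1) {
    abort("Event probabilities must sum to at most 1.")
  }
  u <- runif(n)
  dplyr::case_when(
    u < p_over ~ "overvaluation",
    u < p_over + p_deval ~ "devaluation",
    .default = "none"
  )
}
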