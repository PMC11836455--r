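#' Regulation need (self-esteem shortfall)
#'
#' The signed difference between the need for admiration (the agent's
#' expectancy value for its self-esteem) and current self-esteem. A positive
#' value is the dissonance that mobilises self-esteem regulation; a negative
#' value means surplus self-esteem and no need to act.
#'
#' @param se Self-esteem in `[0, 1]`. Vectorised.
#' @param nfa Need for admiration in `[0, 1]`. Vectorised.
#' @return `nfa - se`, the regulation need.
#' @export
#' @examples
#' compute_regulation_need(0.40, 0.52) # 0.12: regulation needed
#' compute_regulation_need(0.9, 0.5)   # -0.4: surplus, no need
compute_regulation_need <- function(se, nfa) {
  check_unit_interval(se, "se")
  check_unit_interval(nfa, "nfa")
  nfa - se
}

#' Self-esteem leakage
#'
#' Relative per-timestep decay of self-esteem: a fixed proportion of the
#' current level drains away each step, which is what makes regulation
#' necessary at all.
#'
#' @param se Self-esteem in `[0, 1]`. Vectorised.
#' @param leak_rate Proportion lost per step, in `[0, 1)`.
#' @return `se * (1 - leak_rate)`.
#' @export
apply_leakage <- function(se, leak_rate) {
  check_unit_interval(se, "se")
  if (any(leak_rate < 0 | leak_rate >= 1)) {
    abort("`leak_rate` must be in [0, 1).")
  }
  se * (1 - leak_rate)
}

#' Need-for-admiration habituation (tolerance development)
#'
#' The need for admiration tracks current self-esteem through an exponential
#' moving average: it rises after sustained high self-esteem (an ever
#' increasing demand for validation, akin to tolerance in addiction) and falls
#' after sustained low self-esteem. The fixed point is `nfa == se`, approached
#' geometrically at rate `(1 - nfa_adapt_rate)` per step.
#'
#' @param nfa,se Need for admiration and self-esteem, in `[0, 1]`. Vectorised.
#' @param nfa_adapt_rate Habituation speed in `[0, 1]`.
#' @return Updated need for admiration.
#' @export
update_need_for_admiration <- function(nfa, se, nfa_adapt_rate) {
  check_unit_interval(nfa, "nfa")
  check_unit_interval(se, "se")
  if (any(nfa_adapt_rate < 0 | nfa_adapt_rate > 1)) {
    abort("`nfa_adapt_rate` must be in [0, 1].")
  }
  nfa + nfa_adapt_rate * (se - nfa)
}

#' Hierarchical behaviour selection
#'
#' Picks the regulation behaviour for one timestep. Intra-individual
#' regulation has the lowest threshold; the inter-individual behaviours
#' (admiration, rivalry) require a partner. Among inter-individual thresholds
#' that the regulation need exceeds, the behaviour with the *highest* threshold
#' value wins (ties go to admiration). With no partner available, an agent
#' whose need exceeds `ts_intra` falls back to intra-individual regulation.
#'
#' @param diff Regulation need, see [compute_regulation_need()].
#' @param ts_intra,ts_admi,ts_riva Behaviour-initiation thresholds.
#' @param partner_available Is an interaction partner nearby?
#' @return One of `"none"`, `"intra"`, `"admiration"`, `"rivalry"`.
#' @export
#' @examples
#' select_behavior(0.10, 0.005, 0.08, 0.09, TRUE)  # "rivalry" (0.09 > 0.08)
#' select_behavior(0.10, 0.005, 0.08, 0.09, FALSE) # "intra" (nobody nearby)
select_behavior <- function(diff, ts_intra, ts_admi, ts_riva,
                            partner_available) {
  stopifnot(length(diff) == 1, is.logical(partner_available))
  if (diff <= ts_intra) return("none")
  exc_admi <- diff > ts_admi
  exc_riva <- diff > ts_riva
  if (!partner_available || (!exc_admi && !exc_riva)) return("intra")
  if (exc_admi && exc_riva) {
    if (ts_riva > ts_admi) "rivalry" else "admiration"
  } else if (exc_riva) {
    "rivalry"
  } else {
    "admiration"
  }
}

#' Intra-individual regulation
#'
#' A deterministic, relatively small self-esteem boost the agent can grant
#' itself without a partner (positive self-schemas, grandiose fantasies,
#' recalling past successes -- abstracted to a scalar here).
#'
#' @param se Self-esteem in `[0, 1]`. Vectorised.
#' @param intra_boost Boost size, `> 0`.
#' @return `min(1, se + intra_boost)`.
#' @export
apply_intra_regulation <- function(se, intra_boost) {
  check_unit_interval(se, "se")
  stopifnot(all(intra_boost > 0))
  pmin(1, se + intra_boost)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", name))
  }
  invisible(x)
}
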