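#' Find an interaction partner
#'
#' Interaction partners are agents "nearby": within the focal agent's Moore
#' neighbourhood, i.e. on the same cell or one of the 8 surrounding cells
#' (non-wrapping grid edges). If several candidates exist, one is selected
#' uniformly at random.
#'
#' @param focal A one-row data frame (or list) with `row` and `col` (0-based).
#' @param others A data frame of candidate agents with columns `agent_id`,
#'   `row`, `col`.
#' @param ... Unused; reserved.
#' @return The selected partner's row of `others` (a one-row tibble), or
#'   `NULL` if nobody is nearby. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
#' @examples
#' set.seed(1)
#' others <- tibble::tibble(agent_id = 2:3, row = c(0, 9), col = c(0, 9))
#' find_partner(list(row = 5, col = 5), others) # NULL: nobody nearby
find_partner <- function(focal, others, ...) {
  if (nrow(others) == 0) return(NULL)
  near <- abs(others$row - focal$row) <= 1 & abs(others$col - focal$col) <= 1
  idx <- which(near)
  if (length(idx) == 0) return(NULL)
  pick <- idx[sample.int(length(idx), 1L)]
  tibble::as_tibble(others[pick, , drop = FALSE])
}

#' Resolve a partner's response to inter-individual regulation
#'
#' The probability of a positive response is the behaviour's base probability
#' (higher for admiration than for rivalry) plus `status_coupling` times the
#' self-esteem gap `se_self - se_other` (status in the social hierarchy),
#' clamped to `[0, 1]`. The response magnitude is the behaviour's configured
#' magnitude, signed by the draw. Expected response is
#' `magnitude * (2p - 1)`.
#'
#' @param action `"admiration"` or `"rivalry"`.
#' @param se_self,se_other Self-esteem of actor and partner, in `[0, 1]`.
#' @param params A [response_params()] object.
#' @param n Number of independent draws (default 1); vectorised for
#'   Monte-Carlo checks.
#' @return A tibble with columns `rsp` (signed response) and `positive`.
#' @export
#' @examples
#' set.seed(1)
#' resolve_response("admiration", 0.9, 0.5, response_params())
resolve_response <- function(action, se_self, se_other, params, n = 1) {
  if (!action %in% c("admiration", "rivalry")) {
    abort("`action` must be \"admiration\" or \"rivalry\" (inter-individual).")
  }
  check_unit_interval(se_self, "se_self")
  check_unit_interval(se_other, "se_other")
  base <- if (action == "admiration") params$p_pos_admi else params$p_pos_riva
  mag <- if (action == "admiration") params$mag_admi else params$mag_riva
  p <- clamp01(base + params$status_coupling * (se_self - se_other))
  positive <- runif(n) < p
  tibble::tibble(rsp = ifelse(positive, mag, -mag), positive = positive)
}

#' Apply a response to the acting agent's self-esteem
#'
#' Only the acting agent's self-esteem changes; the responding partner's state
#' is untouched (the model focuses on the intrapsychic consequences for the
#' actor).
#'
#' @param se Self-esteem in `[0, 1]`. Vectorised.
#' @param rsp Signed response value.
#' @return `se + rsp` clamped to `[0, 1]`.
#' @export
apply_response <- function(se, rsp) {
  check_unit_interval(se, "se")
  clamp01(se + rsp)
}
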