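#' Core intra-agent parameters
#'
#' Constants of the agent-internal regulation circuit: the relative per-step
#' self-esteem leakage, the deterministic intra-individual boost, and the speed
#' at which the need for admiration habituates toward current self-esteem
#' (tolerance development).
#'
#' Defaults are the package's calibration of the baseline condition: with
#' `leak_rate = 0.04` and `intra_boost = 0.032` an undisturbed agent equilibrates
#' at self-esteem 0.8 (leakage 0.04 x 0.8 = 0.032 is exactly replaced by one
#' intra-individual boost), producing a per-step regulation need of about 0.032
#' -- inside the sensitive threshold band (0.0055, 0.08) and safely below the
#' default inter-individual thresholds.
#'
#' Tolerance development is asymmetric, mirroring tolerance in addiction: the
#' need for admiration chases *rising* self-esteem quickly
#' (`nfa_adapt_up = 0.4` per step), so regulation gains are immediately banked
#' as a higher expectation and the demand for validation keeps renewing, but
#' it lets go of *lost* self-esteem only slowly (`nfa_adapt_down = 0.1`), so
#' after a crash an elevated expectation keeps the regulation need high for
#' many timesteps.
#'
#' @param leak_rate Proportion of self-esteem lost per timestep, in `[0, 1)`.
#' @param intra_boost Deterministic self-esteem gain from one intra-individual
#'   regulation act, `> 0`.
#' @param nfa_adapt_up Habituation rate of the need for admiration while
#'   self-esteem exceeds it, in `[0, 1]`.
#' @param nfa_adapt_down Habituation rate while self-esteem is below it, in
#'   `[0, 1]`.
#' @return A list of class `ser_core_params`.
#' @export
#' @examples
#' core_params()
#' core_params(leak_rate = 0)
core_params <- function(leak_rate = 0.04, intra_boost = 0.032,
                        nfa_adapt_up = 0.4, nfa_adapt_down = 0.1) {
  stopifnot(
    is.numeric(leak_rate), length(leak_rate) == 1, leak_rate >= 0, leak_rate < 1,
    is.numeric(intra_boost), length(intra_boost) == 1, intra_boost > 0,
    is.numeric(nfa_adapt_up), length(nfa_adapt_up) == 1,
    nfa_adapt_up >= 0, nfa_adapt_up <= 1,
    is.numeric(nfa_adapt_down), length(nfa_adapt_down) == 1,
    nfa_adapt_down >= 0, nfa_adapt_down <= 1
  )
  structure(
    list(leak_rate = leak_rate, intra_boost = intra_boost,
         nfa_adapt_up = nfa_adapt_up, nfa_adapt_down = nfa_adapt_down),
    class = "ser_core_params"
  )
}

#' Social response parameters
#'
#' Governs how interaction partners react to admiration and rivalry. The
#' probability of a positive response is the behaviour's base probability plus
#' `status_coupling` times the self-esteem gap (actor minus partner), clamped
#' to `[0, 1]`; the response then shifts the actor's self-esteem by plus or
#' minus the behaviour's magnitude.
#'
#' @param p_pos_admi Base probability of a positive response to admiration.
#' @param p_pos_riva Base probability of a positive response to rivalry
#'   (must be below `p_pos_admi`: self-presentation is better received than
#'   derogation of others).
#' @param status_coupling Slope on the self-esteem gap `se_self - se_other`.
#' @param mag_admi,mag_riva Response magnitudes (absolute self-esteem change),
#'   `>= 0`. A magnitude of 0 encodes indifferent feedback.
#' @return A list of class `ser_response_params`.
#' @export
response_params <- function(p_pos_admi = 0.98, p_pos_riva = 0.3,
                            status_coupling = 0.25,
                            mag_admi = 0.048, mag_riva = 0.12) {
  stopifnot(
    p_pos_admi >= 0, p_pos_admi <= 1,
    p_pos_riva >= 0, p_pos_riva <= 1,
    p_pos_admi > p_pos_riva,
    is.numeric(status_coupling), length(status_coupling) == 1,
    mag_admi >= 0, mag_riva >= 0
  )
  structure(
    list(p_pos_admi = p_pos_admi, p_pos_riva = p_pos_riva,
         status_coupling = status_coupling,
         mag_admi = mag_admi, mag_riva = mag_riva),
    class = "ser_response_params"
  )
}

#' Threshold-learning parameters
#'
#' Step sizes of the two learning channels that move the admiration and rivalry
#' thresholds, and the hard bounds that keep thresholds inside the calibrated
#' range. `ts_floor = 0.0055` is the lowest calibrated threshold value and acts
#' as the lower limit of learning.
#'
#' @param cl_step Contingent (reinforcement) step per reinforced event,
#'   `>= 0` (0 disables contingent learning).
#' @param ncl_step Non-contingent step per environmental over-/devaluation
#'   event, `>= 0` (0 disables non-contingent learning).
#' @param ts_floor,ts_ceiling Lower/upper threshold bounds, `ts_floor < ts_ceiling`.
#' @return A list of class `ser_learning_params`.
#' @export
learning_params <- function(cl_step = 5e-4, ncl_step = 5e-4,
                            ts_floor = 0.0055, ts_ceiling = 0.15) {
  stopifnot(cl_step >= 0, ncl_step >= 0, ts_floor > 0, ts_floor < ts_ceiling)
  structure(
    list(cl_step = cl_step, ncl_step = ncl_step,
         ts_floor = ts_floor, ts_ceiling = ts_ceiling),
    class = "ser_learning_params"
  )
}

#' Learning-environment profiles
#'
#' An environment profile fixes the per-timestep probabilities of non-contingent
#' overvaluation and devaluation events and may override the contingent
#' response regime:
#'
#' * `"overvaluing"`: frequent non-contingent overvaluation
#'   (`p_overvaluation = 0.5`) and excessive, need-surpassing contingent praise
#'   (`p_pos_admi = p_pos_riva = 1`, both magnitudes raised to 0.15) -- a
#'   praising, overvaluing parenting style.
#' * `"devaluing"`: frequent non-contingent devaluation
#'   (`p_devaluation = 0.5`) and indifferent contingent feedback (both response
#'   magnitudes 0) -- a cold, devaluing parenting style.
#' * `"control"`: almost no non-contingent feedback
#'   (`p_overvaluation = p_devaluation = 0.01`) with behaviour-dependent
#'   contingent feedback (no overrides).
#'
#' @param name One of `"control"`, `"overvaluing"`, `"devaluing"`, `"custom"`.
#' @param p_overvaluation,p_devaluation Per-agent per-timestep event
#'   probabilities; their sum must not exceed 1. `NULL` keeps the named
#'   profile's default.
#' @param response_overrides Named list of [response_params()] fields replacing
#'   the run's response regime, or `NULL`.
#' @return A list of class `ser_environment`.
#' @export
#' @examples
#' environment_profile("overvaluing")
#' environment_profile("custom", p_overvaluation = 0.2, p_devaluation = 0.1)
environment_profile <- function(name = c("control", "overvaluing", "devaluing",
                                         "custom"),
                                p_overvaluation = NULL, p_devaluation = NULL,
                                response_overrides = NULL) {
  name <- match.arg(name)
  defaults <- switch(
    name,
    control     = list(p_over = 0.01, p_deval = 0.01, overrides = NULL),
    overvaluing = list(p_over = 0.5, p_deval = 0,
                       overrides = list(p_pos_admi = 1, p_pos_riva = 1,
                                        mag_admi = 0.15, mag_riva = 0.15)),
    devaluing   = list(p_over = 0, p_deval = 0.5,
                       overrides = list(mag_admi = 0, mag_riva = 0)),
    custom      = list(p_over = 0, p_deval = 0, overrides = NULL)
  )
  p_over <- p_overvaluation %||% defaults$p_over
  p_deval <- p_devaluation %||% defaults$p_deval
  overrides <- response_overrides %||% defaults$overrides
  stopifnot(p_over >= 0, p_over <= 1, p_deval >= 0, p_deval <= 1)
  if (p_over + p_deval > 1) {
    abort("`p_overvaluation + p_devaluation` must not exceed 1.")
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(response_params()))
    if (length(bad) > 0) {
      abort(paste0("Unknown response override field(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(name = name, p_overvaluation = p_over, p_devaluation = p_deval,
         response_overrides = overrides),
    class = "ser_environment"
  )
}

# The run's effective response regime: base parameters with the environment's
# contingent-feedback overrides applied. p_pos_admi > p_pos_riva is only
# required of the base regime; overrides may equalise them (e.g. uniformly
# positive feedback in the overvaluing environment).
resolve_response_params <- function(response, environment) {
  ov <- environment$response_overrides
  if (is.null(ov)) return(response)
  out <- modifyList(unclass(response), ov)
  stopifnot(out$p_pos_admi >= 0, out$p_pos_admi <= 1,
            out$p_pos_riva >= 0, out$p_pos_riva <= 1,
            out$mag_admi >= 0, out$mag_riva >= 0)
  structure(out, class = "ser_response_params")
}

#' Simulation configuration
#'
#' Bundles all model constants, world geometry, run length, burn-in, seeding,
#' initial state, and per-agent options into a single validated object.
#' Agent 1 is the focal ("narcissistic") agent whose trajectory the studies
#' analyse; `focal_overrides` replaces its thresholds.
#'
#' @param grid_rows,grid_cols Grid dimensions (default 10 x 10).
#' @param n_agents Number of agents (default 20, `>= 2`).
#' @param n_timesteps Number of simulated timesteps.
#' @param burn_in Number of initial timesteps flagged for exclusion from
#'   summaries; must be `< n_timesteps`.
#' @param seed Integer RNG seed of the run.
#' @param ts_intra,ts_admi,ts_riva Default behaviour-initiation thresholds for
#'   every agent. `ts_intra` must stay strictly below the learning floor so
#'   intra-individual regulation always has the lowest threshold.
#' @param init_se,init_nfa Initial self-esteem and need for admiration, in
#'   `[0, 1]`.
#' @param core,response,learning,environment Parameter blocks; see
#'   [core_params()], [response_params()], [learning_params()],
#'   [environment_profile()].
#' @param focal_overrides Optional named list with any of `ts_intra`,
#'   `ts_admi`, `ts_riva` applied to the focal agent.
#' @param learning_agents Integer ids of agents with the learning component
#'   enabled (empty = plain SER model).
#' @param record `"all"` keeps one record per agent per timestep; `"focal"`
#'   keeps only the focal agent's records (used by the experiment recipes to
#'   bound memory).
#' @return A list of class `ser_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_timesteps = 100, seed = 42)
#' cfg$environment$name
sim_config <- function(grid_rows = 10, grid_cols = 10, n_agents = 20,
                       n_timesteps = 200, burn_in = 50, seed = 1L,
                       ts_intra = 0.005, ts_admi = 0.08, ts_riva = 0.09,
                       init_se = 0.8, init_nfa = 0.8,
                       core = core_params(), response = response_params(),
                       learning = learning_params(),
                       environment = environment_profile("control"),
                       focal_overrides = NULL, learning_agents = integer(0),
                       record = c("all", "focal")) {
  record <- match.arg(record)
  cfg <- structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_agents = as.integer(n_agents),
         n_timesteps = as.integer(n_timesteps), burn_in = as.integer(burn_in),
         seed = as.integer(seed),
         ts_intra = ts_intra, ts_admi = ts_admi, ts_riva = ts_riva,
         init_se = init_se, init_nfa = init_nfa,
         core = core, response = response, learning = learning,
         environment = environment,
         focal_overrides = focal_overrides,
         learning_agents = as.integer(learning_agents),
         record = record),
    class = "ser_config"
  )
  validate_config(cfg)
}

#' @export
print.ser_config <- function(x, ...) {
  cat("<ser_config> ", x$grid_rows, "x", x$grid_cols, " grid, ",
      x$n_agents, " agents, ", x$n_timesteps, " timesteps (burn-in ",
      x$burn_in, "), environment '", x$environment$name, "', seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

validate_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) note("grid dimensions must be >= 1")
  if (cfg$grid_rows * cfg$grid_cols < 2) {
    note("the grid needs at least 2 cells (movement requires another cell)")
  }
  if (cfg$n_agents < 2) note("n_agents must be >= 2")
  if (cfg$n_timesteps < 1) note("n_timesteps must be >= 1")
  if (cfg$burn_in < 0) note("burn_in must be >= 0")
  if (cfg$burn_in >= cfg$n_timesteps) {
    note("burn_in must be strictly smaller than n_timesteps")
  }
  if (cfg$init_se < 0 || cfg$init_se > 1) note("init_se must be in [0, 1]")
  if (cfg$init_nfa < 0 || cfg$init_nfa > 1) note("init_nfa must be in [0, 1]")

  ts <- resolved_thresholds(cfg)
  fl <- cfg$learning$ts_floor
  ce <- cfg$learning$ts_ceiling
  for (who in names(ts)) {
    th <- ts[[who]]
    if (th$ts_intra >= fl) {
      note(sprintf("%s ts_intra (%g) must be strictly below ts_floor (%g)",
                   who, th$ts_intra, fl))
    }
    if (th$ts_admi < fl || th$ts_admi > ce) {
      note(sprintf("%s ts_admi (%g) must lie in [ts_floor, ts_ceiling]",
                   who, th$ts_admi))
    }
    if (th$ts_riva < fl || th$ts_riva > ce) {
      note(sprintf("%s ts_riva (%g) must lie in [ts_floor, ts_ceiling]",
                   who, th$ts_riva))
    }
  }
  if (length(cfg$learning_agents) > 0 &&
      (any(cfg$learning_agents < 1) || any(cfg$learning_agents > cfg$n_agents))) {
    note("learning_agents must be valid agent ids")
  }
  if (!is.null(cfg$focal_overrides)) {
    bad <- setdiff(names(cfg$focal_overrides),
                   c("ts_intra", "ts_admi", "ts_riva"))
    if (length(bad) > 0) {
      note(paste0("unknown focal_overrides field(s): ",
                  paste(bad, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(c("Invalid simulation configuration:", setNames(problems, rep("x", length(problems)))))
  }
  cfg
}

# Default and focal thresholds after applying focal_overrides.
resolved_thresholds <- function(cfg) {
  default <- list(ts_intra = cfg$ts_intra, ts_admi = cfg$ts_admi,
                  ts_riva = cfg$ts_riva)
  focal <- modifyList(default, cfg$focal_overrides %||% list())
  list(default = default, focal = focal)
}
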