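#' Load a simulation configuration from a YAML file
#'
#' Reads a structured key-value (YAML) file and resolves it against the
#' documented defaults of [sim_config()]. Parsing is strict: unknown keys are
#' an error, never silently absorbed -- simulation parameters are the
#' scientific content and a typo must not fall back to a default. An empty
#' file yields the default configuration.
#'
#' Top-level keys mirror the arguments of [sim_config()]; the nested blocks
#' `core`, `response`, `learning` and `environment` mirror [core_params()],
#' [response_params()], [learning_params()] and [environment_profile()]. The
#' `environment` key may also be a bare profile name.
#'
#' @param path Path to the YAML file.
#' @return A validated [sim_config()] object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines("n_timesteps: 100\nenvironment: overvaluing", f)
#' load_config(f)
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path))
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("Config file %s could not be parsed: %s", path,
                  conditionMessage(e)))
  })
  raw <- raw %||% list()
  if (!is.list(raw)) abort("The config file must contain a key-value mapping.")

  check_keys <- function(given, allowed, where) {
    bad <- setdiff(given, allowed)
    if (length(bad) > 0) {
      abort(sprintf("Unknown config key(s) in %s: %s", where,
                    paste(bad, collapse = ", ")))
    }
  }
  check_keys(names(raw), names(formals(sim_config)), "top level")

  args <- raw
  if (!is.null(raw[["core"]])) {
    check_keys(names(raw[["core"]]), names(formals(core_params)), "`core`")
    args$core <- do.call(core_params, raw[["core"]])
  }
  if (!is.null(raw[["response"]])) {
    check_keys(names(raw[["response"]]), names(formals(response_params)),
               "`response`")
    args$response <- do.call(response_params, raw[["response"]])
  }
  if (!is.null(raw[["learning"]])) {
    check_keys(names(raw[["learning"]]), names(formals(learning_params)),
               "`learning`")
    args$learning <- do.call(learning_params, raw[["learning"]])
  }
  if (!is.null(raw[["environment"]])) {
    env <- raw[["environment"]]
    if (is.character(env) && length(env) == 1) {
      args$environment <- environment_profile(env)
    } else {
      check_keys(names(env), names(formals(environment_profile)),
                 "`environment`")
      args$environment <- do.call(environment_profile, env)
    }
  }
  if (!is.null(raw[["focal_overrides"]])) {
    check_keys(names(raw[["focal_overrides"]]),
               c("ts_intra", "ts_admi", "ts_riva"), "`focal_overrides`")
  }
  do.call(sim_config, args)
}

trajectory_col_types <- function() {
  readr::cols(
    run = readr::col_integer(),
    t = readr::col_integer(),
    agent_id = readr::col_integer(),
    row = readr::col_integer(),
    col = readr::col_integer(),
    se = readr::col_double(),
    nfa = readr::col_double(),
    ts_intra = readr::col_double(),
    ts_admi = readr::col_double(),
    ts_riva = readr::col_double(),
    action = readr::col_character(),
    partner_id = readr::col_integer(),
    rsp = readr::col_double(),
    env_event = readr::col_character(),
    partner_available = readr::col_logical(),
    is_burnin = readr::col_logical()
  )
}

#' Write / read trajectory tables
#'
#' CSV with a fixed, documented column order (the [run_simulation()] record
#' schema), one header row, one row per agent-timestep, floats at full
#' (round-trippable) precision. `read_trajectories()` restores exactly what
#' [write_trajectories()] wrote.
#'
#' @param records A trajectory tibble.
#' @param path Output/input file path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns the trajectory tibble.
#' @export
write_trajectories <- function(records, path) {
  expected <- names(trajectory_col_types()$cols)
  missing <- setdiff(expected, names(records))
  if (length(missing) > 0) {
    abort(paste0("Trajectory table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(records[, expected], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, col_types = trajectory_col_types(),
                         progress = FALSE)
  class(out) <- c("ser_trajectory", class(out))
  out
}

#' Write a run manifest
#'
#' A manifest snapshots everything needed to reproduce a run bit-exactly:
#' the fully resolved configuration, the master seed and derived per-run
#' seeds, the package version and a timestamp. Stored as JSON.
#'
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @param master_seed,run_seeds Optional seeding information of a multi-run
#'   experiment.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, master_seed = NULL,
                               run_seeds = NULL) {
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  snap <- strip_classes(config)
  manifest <- list(
    config = snap,
    master_seed = master_seed,
    run_seeds = run_seeds,
    package = "sernarc",
    version = as.character(packageVersion("sernarc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run manifest back into a configuration
#'
#' @param path Path to a manifest written by [write_run_manifest()].
#' @return A list with `config` (a validated [sim_config()]), `master_seed`
#'   and `run_seeds`.
#' @export
read_run_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  args <- cfg[setdiff(names(cfg), c("core", "response", "learning",
                                    "environment", "focal_overrides"))]
  args$core <- do.call(core_params, as.list(cfg[["core"]]))
  args$response <- do.call(response_params, as.list(cfg[["response"]]))
  args$learning <- do.call(learning_params, as.list(cfg[["learning"]]))
  env <- as.list(cfg[["environment"]])
  args$environment <- environment_profile(
    env$name,
    p_overvaluation = env$p_overvaluation,
    p_devaluation = env$p_devaluation,
    response_overrides = if (length(env$response_overrides) > 0)
      as.list(env$response_overrides) else NULL
  )
  if (length(cfg[["focal_overrides"]]) > 0) {
    args$focal_overrides <- as.list(cfg[["focal_overrides"]])
  }
  if (length(args$learning_agents) == 0) args$learning_agents <- integer(0)
  list(config = do.call(sim_config, args),
       master_seed = m$master_seed, run_seeds = m$run_seeds)
}

#' Deterministic miniature test world
#'
#' A 1 x 2 grid with 2 agents and a short horizon: the Moore neighbourhood
#' covers the whole grid, so a partner is available at every timestep, and
#' every operation of the model can be exercised in milliseconds.
#'
#' @param seed RNG seed of the fixture run.
#' @param n_timesteps Horizon (default 50).
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `focal_overrides`).
#' @return A [sim_config()] object.
#' @export
#' @examples
#' traj <- run_simulation(make_fixture_world(seed = 1))
#' all(traj$partner_available)
make_fixture_world <- function(seed = 1L, n_timesteps = 50, ...) {
  sim_config(grid_rows = 1, grid_cols = 2, n_agents = 2,
             n_timesteps = n_timesteps, burn_in = min(10, n_timesteps - 1),
             seed = seed, ...)
}
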