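#' Study-1 threshold sweep conditions
#'
#' The baseline condition keeps both inter-individual thresholds at their
#' calibrated defaults (admiration 0.08, rivalry 0.09), under which the focal
#' agent shows only minor self-esteem oscillations and no inter-individual
#' regulation. The sweep conditions vary one threshold at a time over the
#' calibrated levels 0.0055 (low), 0.025 (medium) and 0.05 (high).
#'
#' @param values Threshold levels for the non-baseline conditions.
#' @return A tibble with columns `name`, `varied_threshold`, `value`.
#' @export
study1_conditions <- function(values = c(0.0055, 0.025, 0.05)) {
  tibble::tibble(
    name = c("baseline",
             paste0("admi_", values),
             paste0("riva_", values)),
    varied_threshold = c("none", rep("admiration", length(values)),
                         rep("rivalry", length(values))),
    value = c(NA_real_, values, values)
  )
}

focal_summary_row <- function(traj) {
  post <- traj[traj$agent_id == 1L & !traj$is_burnin, ]
  ext <- detect_extreme_changes(post$se)
  tibble::tibble(
    se_mean = mean(post$se),
    se_median = median(post$se),
    se_variance = var(post$se),
    n_admiration = sum(post$action == "admiration"),
    n_rivalry = sum(post$action == "rivalry"),
    n_intra = sum(post$action == "intra"),
    n_none = sum(post$action == "none"),
    n_solitude = sum(!post$partner_available),
    n_drops = ext$n_drops,
    n_spikes = ext$n_spikes,
    final_ts_admi = post$ts_admi[nrow(post)],
    final_ts_riva = post$ts_riva[nrow(post)]
  )
}

#' Study 1: inter-individual regulation thresholds and self-esteem
#'
#' Runs the plain SER model (learning disabled) with systematically varied
#' admiration or rivalry thresholds for the focal agent and averages the focal
#' agent's post-burn-in statistics across runs. All conditions share the same
#' per-run seeds (paired runs).
#'
#' @param conditions A tibble as produced by [study1_conditions()].
#' @param n_runs Runs per condition (default 50).
#' @param n_timesteps Timesteps per run (default 200).
#' @param burn_in Burn-in timesteps excluded from statistics (default 50).
#' @param master_seed Master seed; per-run seeds are derived from it.
#' @return A `ser_study1` object: list with `summary` (per-condition means),
#'   `per_run` (per-condition per-run focal statistics) and the design.
#' @export
run_study1 <- function(conditions = study1_conditions(), n_runs = 50,
                       n_timesteps = 200, burn_in = 50, master_seed = 1) {
  stopifnot(nrow(conditions) >= 1)
  run_seeds <- derive_run_seeds(master_seed, n_runs)

  per_run <- purrr::pmap(conditions, function(name, varied_threshold, value) {
    overrides <- switch(varied_threshold,
                        none = NULL,
                        admiration = list(ts_admi = value),
                        rivalry = list(ts_riva = value))
    purrr::map2_dfr(run_seeds, seq_len(n_runs), function(s, r) {
      cfg <- sim_config(n_timesteps = n_timesteps, burn_in = burn_in,
                        seed = s, focal_overrides = overrides,
                        record = "focal")
      dplyr::mutate(focal_summary_row(run_simulation(cfg, run = r)),
                    condition = name, run = r, .before = 1)
    })
  }) |> purrr::list_rbind()

  summary <- per_run |>
    dplyr::group_by(condition = factor(.data$condition,
                                       levels = conditions$name)) |>
    dplyr::summarise(dplyr::across(c("se_mean", "se_median", "se_variance",
                                     "n_admiration", "n_rivalry", "n_intra",
                                     "n_none", "n_drops", "n_spikes"),
                                   mean),
                     n_runs = dplyr::n(), .groups = "drop")

  structure(
    list(summary = summary, per_run = per_run, conditions = conditions,
         n_runs = n_runs, n_timesteps = n_timesteps, burn_in = burn_in,
         master_seed = master_seed),
    class = c("ser_study1", "ser_study")
  )
}

#' Study 2: threshold learning in different environments
#'
#' Runs the learning model (LSER) with exactly one learning agent per run in
#' the given environment and summarises the learning agent's *final*
#' admiration and rivalry thresholds across runs (mean and sample standard
#' deviation), keeping the full threshold time courses.
#'
#' @param environment An environment name (`"overvaluing"`, `"devaluing"`,
#'   `"control"`) or an [environment_profile()] object.
#' @param n_runs Number of runs (default 50).
#' @param n_timesteps Timesteps per run (default 1000).
#' @param master_seed Master seed.
#' @param burn_in Burn-in flag for the trajectory records (default 50).
#' @return A `ser_study2` object: list with `distribution` (the learned
#'   threshold distribution), `finals` (per-run final thresholds) and
#'   `time_course` (run x timestep thresholds of the learning agent).
#' @export
run_study2 <- function(environment = "overvaluing", n_runs = 50,
                       n_timesteps = 1000, master_seed = 1, burn_in = 50) {
  profile <- if (inherits(environment, "ser_environment")) environment
             else environment_profile(environment)
  run_seeds <- derive_run_seeds(master_seed, n_runs)

  time_course <- purrr::map2_dfr(run_seeds, seq_len(n_runs), function(s, r) {
    cfg <- sim_config(n_timesteps = n_timesteps, burn_in = burn_in, seed = s,
                      environment = profile, learning_agents = 1L,
                      record = "focal")
    traj <- run_simulation(cfg, run = r)
    traj[, c("run", "t", "se", "nfa", "ts_admi", "ts_riva", "action")]
  })

  finals <- time_course |>
    dplyr::filter(.data$t == n_timesteps) |>
    dplyr::select("run", "ts_admi", "ts_riva")

  distribution <- tibble::tibble(
    environment = profile$name,
    mean_ts_admi = mean(finals$ts_admi),
    sd_ts_admi = sd(finals$ts_admi),
    mean_ts_riva = mean(finals$ts_riva),
    sd_ts_riva = sd(finals$ts_riva)
  )

  structure(
    list(distribution = distribution, finals = finals,
         time_course = time_course, environment = profile,
         initial_ts_admi = sim_config()$ts_admi,
         initial_ts_riva = sim_config()$ts_riva,
         n_runs = n_runs, n_timesteps = n_timesteps,
         master_seed = master_seed),
    class = c("ser_study2", "ser_study")
  )
}

# Learned-threshold distributions used to initialise "adult" agents:
# normal means/sds of the admiration and rivalry thresholds acquired in each
# rearing environment.
study3_threshold_priors <- function() {
  tibble::tribble(
    ~origin,        ~mean_ts_admi, ~sd_ts_admi, ~mean_ts_riva, ~sd_ts_riva,
    "overvaluing",  0.0055,        0.0,         0.0576,        0.0037,
    "devaluing",    0.0833,        0.0029,      0.0072,        0.0007,
    "control",      0.0562,        0.0037,      0.1125,        0.0074
  )
}

#' Study 3: learned agents in a regular environment
#'
#' Runs the plain SER model (learning disabled) in the control environment
#' with the focal agent's thresholds drawn, per run, from the learned
#' threshold distribution of a rearing environment (truncated to the
#' calibrated `[ts_floor, ts_ceiling]` range).
#'
#' @param origin `"overvaluing"`, `"devaluing"` or `"control"`: the rearing
#'   environment whose learned-threshold distribution initialises the agents.
#' @param n_runs Number of runs / simulated adult agents (default 50).
#' @param n_timesteps Timesteps per run (default 1000).
#' @param master_seed Master seed.
#' @param burn_in Burn-in timesteps (default 50).
#' @param distribution Optional one-row data frame overriding the built-in
#'   distribution (columns `mean_ts_admi`, `sd_ts_admi`, `mean_ts_riva`,
#'   `sd_ts_riva`), e.g. the `distribution` of a [run_study2()] result.
#' @return A `ser_study3` object: list with `trajectories` (focal rows of all
#'   runs), `agent_summaries` (one row per run incl. behaviour counts and
#'   solitude timesteps) and the drawn `thresholds`.
#' @export
run_study3 <- function(origin = c("overvaluing", "devaluing", "control"),
                       n_runs = 50, n_timesteps = 1000, master_seed = 1,
                       burn_in = 50, distribution = NULL) {
  origin <- match.arg(origin)
  if (is.null(distribution)) {
    priors <- study3_threshold_priors()
    distribution <- priors[priors$origin == origin, ]
  }
  lp <- learning_params()
  set.seed(as.integer(master_seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  draw_admi <- pmin(lp$ts_ceiling,
                    pmax(lp$ts_floor,
                         rnorm(n_runs, distribution$mean_ts_admi,
                               distribution$sd_ts_admi)))
  draw_riva <- pmin(lp$ts_ceiling,
                    pmax(lp$ts_floor,
                         rnorm(n_runs, distribution$mean_ts_riva,
                               distribution$sd_ts_riva)))

  trajectories <- purrr::map_dfr(seq_len(n_runs), function(r) {
    cfg <- sim_config(n_timesteps = n_timesteps, burn_in = burn_in,
                      seed = run_seeds[r],
                      environment = environment_profile("control"),
                      focal_overrides = list(ts_admi = draw_admi[r],
                                             ts_riva = draw_riva[r]),
                      record = "focal")
    run_simulation(cfg, run = r)
  })

  agent_summaries <- trajectories |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(~ focal_summary_row(dplyr::mutate(.x, agent_id = 1L,
                                                          run = .y$run))) |>
    dplyr::ungroup() |>
    dplyr::mutate(origin = origin, .before = 1)

  structure(
    list(trajectories = trajectories, agent_summaries = agent_summaries,
         thresholds = tibble::tibble(run = seq_len(n_runs),
                                     ts_admi = draw_admi,
                                     ts_riva = draw_riva),
         origin = origin, distribution = distribution,
         n_runs = n_runs, n_timesteps = n_timesteps,
         master_seed = master_seed),
    class = c("ser_study3", "ser_study")
  )
}

#' Map an instrument trait score onto a behaviour threshold
#'
#' Linear *decreasing* map: the higher the trait expression, the lower the
#' behaviour-initiation threshold. The highest score of the instrument range
#' maps to the lowest threshold and vice versa.
#'
#' @param score Trait score within `[score_min, score_max]`.
#' @param score_min,score_max Instrument range, `score_min < score_max`.
#' @param ts_min,ts_max Threshold range, `ts_min < ts_max`.
#' @return The mapped threshold. Vectorised over `score`.
#' @export
#' @examples
#' map_trait_to_threshold(5, 1, 5, 0.0055, 0.08) # highest score -> floor
map_trait_to_threshold <- function(score, score_min, score_max, ts_min, ts_max) {
  stopifnot(score_min < score_max, ts_min < ts_max)
  if (any(score < score_min | score > score_max)) {
    abort("`score` must lie within [score_min, score_max].")
  }
  ts_max - (score - score_min) / (score_max - score_min) * (ts_max - ts_min)
}

#' Synthetic four-group trait fixture
#'
#' A synthetic stand-in for group-level trait scores of the four narcissism
#' groups (low/high grandiose x low/high vulnerable) on an arbitrary 1-5
#' instrument scale: "low" is the 25th percentile (2), "high" the 75th (4).
#' Grandiosity maps onto agency (admiration threshold), vulnerability onto
#' antagonism (rivalry threshold). Replace with real group means via the
#' `groups` argument of [run_study4()] for a faithful comparison.
#'
#' @return A tibble with columns `label`, `agency_score`, `antagonism_score`,
#'   `n_agents`.
#' @export
study4_default_groups <- function() {
  tibble::tribble(
    ~label,   ~agency_score, ~antagonism_score, ~n_agents,
    "LG_LV",  2,             2,                 50L,
    "HG_LV",  4,             2,                 50L,
    "LG_HV",  2,             4,                 50L,
    "HG_HV",  4,             4,                 50L
  )
}

#' Study 4: trait groups mapped to thresholds
#'
#' Maps group-level agency and antagonism scores onto admiration and rivalry
#' thresholds ([map_trait_to_threshold()]; agency -> admiration threshold,
#' antagonism -> rivalry threshold, inverted linear map over
#' `[ts_floor, default]`), simulates `n_agents` focal agents per group in the
#' control environment with learning disabled, and aggregates z-standardised
#' per-agent self-esteem medians/variances and inverted-threshold trait
#' proxies at the group level ([aggregate_groups()]).
#'
#' @param groups A tibble like [study4_default_groups()].
#' @param n_timesteps Timesteps per agent (default 1000).
#' @param master_seed Master seed.
#' @param burn_in Burn-in timesteps (default 50).
#' @param score_range Instrument range of the trait scores (default `c(1, 5)`).
#' @return A `ser_study4` object: list with `group_summary` (z-scored group
#'   means), `agent_summaries`, and the mapped `thresholds` per group.
#' @export
run_study4 <- function(groups = study4_default_groups(), n_timesteps = 1000,
                       master_seed = 1, burn_in = 50, score_range = c(1, 5)) {
  if (nrow(groups) < 2) {
    abort("At least 2 groups are required (z-scores are undefined otherwise).")
  }
  stopifnot(all(groups$n_agents > 0), all(is.finite(groups$agency_score)),
            all(is.finite(groups$antagonism_score)))
  defaults <- sim_config()
  lp <- learning_params()
  groups <- groups |>
    dplyr::mutate(
      ts_admi = map_trait_to_threshold(.data$agency_score, score_range[1],
                                       score_range[2], lp$ts_floor,
                                       defaults$ts_admi),
      ts_riva = map_trait_to_threshold(.data$antagonism_score, score_range[1],
                                       score_range[2], lp$ts_floor,
                                       defaults$ts_riva)
    )

  total <- sum(groups$n_agents)
  run_seeds <- derive_run_seeds(master_seed, total)
  seed_idx <- 0L

  agent_summaries <- purrr::pmap(groups, function(label, agency_score,
                                                  antagonism_score, n_agents,
                                                  ts_admi, ts_riva) {
    rows <- purrr::map_dfr(seq_len(n_agents), function(k) {
      seed_idx <<- seed_idx + 1L
      cfg <- sim_config(n_timesteps = n_timesteps, burn_in = burn_in,
                        seed = run_seeds[seed_idx],
                        environment = environment_profile("control"),
                        focal_overrides = list(ts_admi = ts_admi,
                                               ts_riva = ts_riva),
                        record = "focal")
      focal_summary_row(run_simulation(cfg, run = seed_idx))
    })
    dplyr::mutate(rows, group = label, agent = dplyr::row_number(),
                  .before = 1)
  }) |> purrr::list_rbind() |>
    dplyr::mutate(group = factor(.data$group, levels = groups$label))

  group_summary <- aggregate_groups(agent_summaries, group_col = "group") |>
    dplyr::arrange(.data$group)

  structure(
    list(group_summary = group_summary, agent_summaries = agent_summaries,
         thresholds = groups, n_timesteps = n_timesteps, burn_in = burn_in,
         master_seed = master_seed, score_range = score_range),
    class = c("ser_study4", "ser_study")
  )
}
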