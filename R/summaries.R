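#' Count extreme self-esteem changes (drops and spikes)
#'
#' A drop is a decrease of at least `drop_magnitude` within `window`
#' consecutive timesteps; a spike is the symmetric increase. Overlapping
#' flagged timesteps are merged so one continuous excursion counts once.
#' Defaults (`drop_magnitude = 0.05`, `window = 3`) are chosen so a single
#' failed rivalry attempt (response magnitude 0.12) registers.
#'
#' @param se Numeric self-esteem series in time order.
#' @param drop_magnitude Minimal absolute change, `> 0`.
#' @param window Number of consecutive timesteps the change may span, `>= 1`.
#' @return A named list with `n_drops` and `n_spikes`.
#' @export
#' @examples
#' detect_extreme_changes(c(0.8, 0.6, 0.6), drop_magnitude = 0.1, window = 1)
detect_extreme_changes <- function(se, drop_magnitude = 0.05, window = 3) {
  stopifnot(drop_magnitude > 0, window >= 1)
  len <- length(se)
  drop_flag <- logical(len)
  spike_flag <- logical(len)
  for (w in seq_len(min(window, len - 1))) {
    d <- se[(1 + w):len] - se[seq_len(len - w)]
    idx <- (1 + w):len
    drop_flag[idx] <- drop_flag[idx] | d <= -drop_magnitude
    spike_flag[idx] <- spike_flag[idx] | d >= drop_magnitude
  }
  count_runs <- function(flag) {
    r <- rle(flag)
    sum(r$values)
  }
  list(n_drops = count_runs(drop_flag), n_spikes = count_runs(spike_flag))
}

#' Z-standardise a vector
#'
#' Centres and scales by the sample standard deviation (n - 1 denominator),
#' so the output has mean 0 and sample standard deviation 1.
#'
#' @param values Numeric vector with at least 2 values, not all identical.
#' @return The standardised vector.
#' @export
#' @examples
#' zscore(c(1, 2, 3, 4))
zscore <- function(values) {
  if (length(values) < 2) {
    abort("`values` must contain at least 2 values.")
  }
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    abort("`values` are all identical; z-scores are undefined (sd = 0).")
  }
  (values - mean(values)) / s
}

#' Summarise one agent's trajectory
#'
#' Computes the post-burn-in self-esteem median and sample variance, action
#' counts, solitude timesteps (no partner available), extreme-change counts
#' and final thresholds for a single agent in a single run. Rows are sorted by
#' timestep first, so record order does not matter.
#'
#' @param trajectory Trajectory rows of one agent in one run (see
#'   [run_simulation()]).
#' @param burn_in Number of initial timesteps to exclude. Defaults to the
#'   trajectory's `is_burnin` flag.
#' @param drop_magnitude,window Passed to [detect_extreme_changes()].
#' @return A one-row tibble (agent summary).
#' @export
summarize_agent <- function(trajectory, burn_in = NULL,
                            drop_magnitude = 0.05, window = 3) {
  if (length(unique(trajectory$agent_id)) != 1 ||
      length(unique(trajectory$run)) != 1) {
    abort("`trajectory` must contain a single agent in a single run.")
  }
  trajectory <- dplyr::arrange(trajectory, .data$t)
  keep <- if (is.null(burn_in)) !trajectory$is_burnin else trajectory$t > burn_in
  post <- trajectory[keep, ]
  if (nrow(post) == 0) {
    abort("Empty post-burn-in window; nothing to summarise.")
  }
  ext <- detect_extreme_changes(post$se, drop_magnitude, window)
  tibble::tibble(
    agent_id = post$agent_id[1],
    run = post$run[1],
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

#' Summarise every agent of a (multi-run) trajectory table
#'
#' @param trajectories A trajectory tibble, possibly covering several runs.
#' @inheritParams summarize_agent
#' @return A tibble with one [summarize_agent()] row per agent x run.
#' @export
summarize_agents <- function(trajectories, burn_in = NULL,
                             drop_magnitude = 0.05, window = 3) {
  trajectories |>
    dplyr::group_by(.data$run, .data$agent_id) |>
    dplyr::group_modify(~ summarize_agent(dplyr::mutate(.x,
                                                        run = .y$run,
                                                        agent_id = .y$agent_id),
                                          burn_in = burn_in,
                                          drop_magnitude = drop_magnitude,
                                          window = window)[, -(1:2)]) |>
    dplyr::ungroup()
}

#' Aggregate agent summaries into group summaries
#'
#' Pools all agents across groups, z-standardises each metric over the pooled
#' sample (sample standard deviation), then averages within group. The agency
#' and antagonism proxies are the *negated* final admiration and rivalry
#' thresholds (a lower threshold means a stronger trait expression), negated
#' before z-scoring.
#'
#' @param agent_summaries A tibble of [summarize_agent()] rows with an
#'   additional grouping column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return A tibble with one row per group: `agency_proxy_z`,
#'   `antagonism_proxy_z`, `se_median_z`, `se_variance_z`, `n_agents`.
#' @export
aggregate_groups <- function(agent_summaries, group_col = "group") {
  groups <- agent_summaries[[group_col]]
  if (is.null(groups)) abort(sprintf("Column `%s` not found.", group_col))
  if (length(unique(groups)) < 2) {
    abort("At least 2 groups are required (pooled z-scores are undefined).")
  }
  scored <- agent_summaries |>
    dplyr::mutate(
      agency_proxy_z = zscore(-.data$final_ts_admi),
      antagonism_proxy_z = zscore(-.data$final_ts_riva),
      se_median_z = zscore(.data$se_median),
      se_variance_z = zscore(.data$se_variance)
    )
  scored |>
    dplyr::group_by(group = .data[[group_col]]) |>
    dplyr::summarise(
      agency_proxy_z = mean(.data$agency_proxy_z),
      antagonism_proxy_z = mean(.data$antagonism_proxy_z),
      se_median_z = mean(.data$se_median_z),
      se_variance_z = mean(.data$se_variance_z),
      n_agents = dplyr::n(),
      .groups = "drop"
    )
}
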