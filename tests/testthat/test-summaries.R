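make_traj <- function(se, action = "none", partner_available = TRUE,
                      burnin = 0) {
  n <- length(se)
  tibble::tibble(
    run = 1L, t = seq_len(n), agent_id = 1L, row = 0L, col = 0L,
    se = se, nfa = se, ts_intra = 0.005, ts_admi = 0.08, ts_riva = 0.09,
    action = rep_len(action, n), partner_id = NA_integer_, rsp = 0,
    env_event = "none", partner_available = rep_len(partner_available, n),
    is_burnin = seq_len(n) <= burnin
  )
}

test_that("agent summaries compute medians, variances and counts", {
  s <- summarize_agent(make_traj(rep(0.7, 100)))
  expect_equal(s$se_median, 0.7)
  expect_equal(s$se_variance, 0)
  expect_equal(s$n_none, 100)

  s2 <- summarize_agent(make_traj(c(0.2, 0.4, 0.9)))
  expect_equal(s2$se_median, 0.4)
  # even-length median = mean of the two central values
  s3 <- summarize_agent(make_traj(c(0.2, 0.4, 0.6, 0.9)))
  expect_equal(s3$se_median, 0.5)

  expect_error(summarize_agent(make_traj(c(0.5, 0.5), burnin = 2)),
               "post-burn-in")
})

test_that("agent summaries count what the record stream contains", {
  cfg <- make_fixture_world(seed = 2, n_timesteps = 60,
                            focal_overrides = list(ts_admi = 0.0055))
  traj <- run_simulation(cfg)
  focal <- traj[traj$agent_id == 1, ]
  s <- summarize_agent(focal)
  post <- focal[!focal$is_burnin, ]
  expect_equal(s$n_admiration, sum(post$action == "admiration"))
  expect_equal(s$n_rivalry, sum(post$action == "rivalry"))
  expect_equal(s$n_admiration + s$n_rivalry + s$n_intra + s$n_none,
               nrow(post))
  expect_equal(s$n_solitude, sum(!post$partner_available))
  expect_equal(s$final_ts_admi, post$ts_admi[nrow(post)])
})

test_that("agent summaries are invariant to record order", {
  cfg <- make_fixture_world(seed = 6, n_timesteps = 40)
  focal <- run_simulation(cfg) |> dplyr::filter(agent_id == 1)
  shuffled <- focal[sample.int(nrow(focal)), ]
  expect_equal(summarize_agent(focal), summarize_agent(shuffled))
})

test_that("extreme-change detection counts merged excursions", {
  expect_equal(detect_extreme_changes(rep(0.5, 50), 0.1, 3),
               list(n_drops = 0, n_spikes = 0))
  expect_equal(detect_extreme_changes(c(0.8, 0.6, 0.6), 0.1, 1),
               list(n_drops = 1, n_spikes = 0))

  # sawtooth: alternating +/-0.15 steps; brute-force oracle over lag-1 diffs
  saw <- c(0.5, rep(c(0.65, 0.5), 5))
  d <- diff(saw)
  expect_equal(detect_extreme_changes(saw, 0.1, 1),
               list(n_drops = sum(d <= -0.1), n_spikes = sum(d >= 0.1)))
  expect_equal(detect_extreme_changes(saw, 0.1, 1)$n_drops, 5)

  # a monotone slide spread over several steps counts once via the window
  slide <- c(0.8, 0.77, 0.74, 0.71, 0.71, 0.71)
  expect_equal(detect_extreme_changes(slide, 0.08, 3)$n_drops, 1)

  # unreachable magnitude finds nothing in any bounded series
  expect_equal(detect_extreme_changes(runif(100), 10, 5),
               list(n_drops = 0, n_spikes = 0))
})

test_that("z-scores use the sample standard deviation", {
  expect_equal(zscore(c(0, 2)), c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(zscore(c(1, 2, 3, 4)),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  x <- rnorm(50)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(zscore(z), z, tolerance = 1e-10)
  expect_error(zscore(rep(1, 5)), "identical")
  expect_error(zscore(1), "at least 2")
})

test_that("group aggregation pools z-scores and negates trait thresholds", {
  base <- tibble::tibble(
    agent_id = 1:6, run = 1:6,
    se_median = c(0.8, 0.81, 0.79, 0.5, 0.52, 0.48),
    se_variance = c(1, 1, 1, 3, 3, 3),
    n_admiration = 0L, n_rivalry = 0L, n_intra = 0L, n_none = 0L,
    n_solitude = 0L, n_drops = 0L, n_spikes = 0L,
    final_ts_admi = c(0.08, 0.081, 0.079, 0.02, 0.021, 0.019),
    final_ts_riva = c(0.09, 0.09, 0.091, 0.03, 0.031, 0.029),
    group = rep(c("A", "B"), each = 3)
  )
  g <- aggregate_groups(base)
  # closed-form pooled z of the variances (1,1,1,3,3,3): sd = sqrt(6/5)
  expect_equal(g$se_variance_z[g$group == "A"], -1 / sqrt(6 / 5))
  expect_lt(g$se_variance_z[g$group == "A"], g$se_variance_z[g$group == "B"])
  # the group with the LOWER thresholds carries the HIGHER trait proxies
  expect_gt(g$agency_proxy_z[g$group == "B"], g$agency_proxy_z[g$group == "A"])
  expect_gt(g$antagonism_proxy_z[g$group == "B"],
            g$antagonism_proxy_z[g$group == "A"])
  expect_error(aggregate_groups(dplyr::mutate(base, group = "A")),
               "2 groups")
})
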