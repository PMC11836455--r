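lp <- learning_params(cl_step = 5e-4, ncl_step = 5e-4)

test_that("contingent learning follows the satisfaction sign rule", {
  # response exceeded the need: positive reinforcement, threshold drops
  expect_equal(contingent_update(0.08, "admiration", 0.08, 0.05, lp), 0.0795)
  # response failed the need: negative reinforcement, threshold rises
  expect_equal(contingent_update(0.09, "rivalry", -0.12, 0.05, lp), 0.0905)
  # the calibrated floor is the lower limit of learning
  expect_equal(contingent_update(0.0055, "admiration", 0.08, 0.01, lp), 0.0055)
  expect_error(contingent_update(0.08, "intra", 0.02, 0.01, lp),
               "inter-individual")
})

test_that("a successful regulation never increases a threshold", {
  set.seed(5)
  for (k in 1:100) {
    ts <- runif(1, lp$ts_floor, lp$ts_ceiling)
    diff <- runif(1, 0, 0.2)
    rsp <- runif(1, -0.15, 0.2)
    out <- contingent_update(ts, "admiration", rsp, diff, lp)
    if (rsp > diff) expect_lte(out, ts) else expect_gte(out, ts)
    expect_gte(out, lp$ts_floor)
    expect_lte(out, lp$ts_ceiling)
  }
})

test_that("non-contingent events lower the matching threshold to the floor", {
  expect_equal(noncontingent_update(0.08, 0.09, "none", lp),
               list(ts_admi = 0.08, ts_riva = 0.09))
  expect_equal(noncontingent_update(0.08, 0.09, "overvaluation", lp),
               list(ts_admi = 0.0795, ts_riva = 0.09))
  expect_equal(noncontingent_update(0.08, 0.09, "devaluation", lp),
               list(ts_admi = 0.08, ts_riva = 0.0895))
  expect_equal(noncontingent_update(0.0055, 0.09, "overvaluation", lp)$ts_admi,
               0.0055)
  expect_error(noncontingent_update(0.08, 0.09, "praise", lp), "event")
})

test_that("thresholds never leave their bounds under any event sequence", {
  set.seed(8)
  ts_admi <- 0.007
  ts_riva <- 0.149
  events <- sample(c("overvaluation", "devaluation", "none"), 500,
                   replace = TRUE)
  for (e in events) {
    out <- noncontingent_update(ts_admi, ts_riva, e, lp)
    ts_admi <- out$ts_admi
    ts_riva <- out$ts_riva
    expect_gte(ts_admi, lp$ts_floor)
    expect_lte(ts_riva, lp$ts_ceiling)
  }
  expect_equal(ts_admi, lp$ts_floor)
})

test_that("environment events are sampled with the configured probabilities", {
  none <- environment_profile("custom", p_overvaluation = 0,
                              p_devaluation = 0)
  expect_true(all(sample_environment_event(none, n = 100) == "none"))

  always <- environment_profile("custom", p_overvaluation = 1)
  expect_true(all(sample_environment_event(always, n = 100) ==
                    "overvaluation"))

  half <- environment_profile("custom", p_overvaluation = 0.5)
  set.seed(21)
  draws <- sample_environment_event(half, n = 1e5)
  expect_lt(abs(mean(draws == "overvaluation") - 0.5), 0.005)
  expect_error(environment_profile("custom", p_overvaluation = 0.7,
                                   p_devaluation = 0.5), "exceed 1")
})

test_that("zero learning steps freeze thresholds (LSER degenerates to SER)", {
  cfg <- make_fixture_world(seed = 4, n_timesteps = 80,
                            learning_agents = 1L,
                            learning = learning_params(cl_step = 0,
                                                       ncl_step = 0),
                            environment = environment_profile("custom"),
                            focal_overrides = list(ts_admi = 0.0055))
  traj <- run_simulation(cfg)
  focal <- traj[traj$agent_id == 1, ]
  expect_gt(sum(focal$action %in% c("admiration", "rivalry")), 0)
  expect_true(all(focal$ts_admi == 0.0055))
  expect_true(all(focal$ts_riva == 0.09))
})
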