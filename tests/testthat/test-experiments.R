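# Scaled-down study recipes: the full-scale runs live in the acceptance suite.

test_that("the baseline agent shows no inter-individual regulation", {
  s1 <- run_study1(conditions = study1_conditions()[1, ], n_runs = 5,
                   n_timesteps = 120, burn_in = 30, master_seed = 7)
  expect_equal(s1$summary$n_admiration, 0)
  expect_equal(s1$summary$n_rivalry, 0)
  expect_equal(s1$summary$se_variance, 0)
  expect_equal(s1$summary$se_mean, 0.8)
})

test_that("study recipes are bit-reproducible in the master seed", {
  cond <- study1_conditions(values = 0.0055)[2, ]
  a <- run_study1(cond, n_runs = 3, n_timesteps = 80, burn_in = 20,
                  master_seed = 42)
  b <- run_study1(cond, n_runs = 3, n_timesteps = 80, burn_in = 20,
                  master_seed = 42)
  expect_identical(a$per_run, b$per_run)
  c <- run_study1(cond, n_runs = 3, n_timesteps = 80, burn_in = 20,
                  master_seed = 43)
  expect_false(identical(a$per_run, c$per_run))
})

test_that("threshold learning responds to the environment direction", {
  ov <- run_study2("overvaluing", n_runs = 4, n_timesteps = 400,
                   master_seed = 2)
  expect_lt(ov$distribution$mean_ts_admi, 0.08)
  # quiet custom environment with no learning signal leaves thresholds alone
  quiet <- run_study2(environment_profile("custom"), n_runs = 3,
                      n_timesteps = 150, master_seed = 2)
  expect_true(all(quiet$finals$ts_admi == 0.08))
  expect_true(all(quiet$finals$ts_riva == 0.09))
})

test_that("learned-threshold origins produce distinct behavioural regimes", {
  ov <- run_study3("overvaluing", n_runs = 6, n_timesteps = 400,
                   master_seed = 3)
  dv <- run_study3("devaluing", n_runs = 6, n_timesteps = 400,
                   master_seed = 3)
  expect_gt(sum(ov$agent_summaries$n_admiration),
            sum(ov$agent_summaries$n_rivalry))
  expect_gt(sum(dv$agent_summaries$n_rivalry),
            sum(dv$agent_summaries$n_admiration))
  expect_gt(mean(ov$agent_summaries$se_median),
            mean(dv$agent_summaries$se_median))
  expect_error(run_study3("praising"), "arg")
})

test_that("study-3 thresholds are drawn from the origin distribution", {
  s3 <- run_study3("overvaluing", n_runs = 10, n_timesteps = 60,
                   master_seed = 5)
  expect_true(all(s3$thresholds$ts_admi == 0.0055))
  expect_true(all(s3$thresholds$ts_riva >= learning_params()$ts_floor))
  custom <- tibble::tibble(mean_ts_admi = 0.01, sd_ts_admi = 0,
                           mean_ts_riva = 0.12, sd_ts_riva = 0)
  s3b <- run_study3("control", n_runs = 3, n_timesteps = 60, master_seed = 5,
                    distribution = custom)
  expect_true(all(s3b$thresholds$ts_admi == 0.01))
  expect_true(all(s3b$thresholds$ts_riva == 0.12))
})

test_that("trait scores map linearly and inversely onto thresholds", {
  expect_equal(map_trait_to_threshold(5, 1, 5, 0.0055, 0.08), 0.0055)
  expect_equal(map_trait_to_threshold(1, 1, 5, 0.0055, 0.08), 0.08)
  expect_equal(map_trait_to_threshold(3, 1, 5, 0.0055, 0.08),
               (0.0055 + 0.08) / 2)
  expect_error(map_trait_to_threshold(6, 1, 5, 0.0055, 0.08), "within")
})

test_that("trait groups get pooled z-scored group summaries", {
  groups <- study4_default_groups()
  groups$n_agents <- c(4L, 4L, 4L, 4L)
  s4 <- run_study4(groups, n_timesteps = 250, master_seed = 9)
  expect_equal(nrow(s4$group_summary), 4)
  expect_equal(levels(s4$group_summary$group), groups$label)
  # pooled z-scores are centred across all agents
  expect_lt(abs(sum(s4$group_summary$agency_proxy_z * s4$group_summary$n_agents)),
            1e-8)
  expect_lt(abs(sum(s4$group_summary$se_median_z * s4$group_summary$n_agents)),
            1e-8)
  # grandiose groups carry the higher agency proxy by construction
  hg <- s4$group_summary$agency_proxy_z[s4$group_summary$group %in%
                                          c("HG_LV", "HG_HV")]
  lg <- s4$group_summary$agency_proxy_z[s4$group_summary$group %in%
                                          c("LG_LV", "LG_HV")]
  expect_true(min(hg) > max(lg))
  expect_error(run_study4(groups[1, ]), "2 groups")
})
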