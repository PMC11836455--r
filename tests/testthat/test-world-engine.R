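test_that("movement redraws uniformly among all other cells", {
  # a 1 x 2 grid leaves exactly one other cell
  a <- tibble::tibble(agent_id = 1L, row = 0L, col = 0L)
  set.seed(1)
  moved <- move_agents(a, 1, 2)
  expect_equal(c(moved$row, moved$col), c(0, 1))

  # 99,000 simultaneous moves from (5,5) on a 10 x 10 grid
  many <- tibble::tibble(agent_id = seq_len(99000), row = 5L, col = 5L)
  set.seed(2)
  moved <- move_agents(many, 10, 10)
  cellidx <- moved$row * 10 + moved$col
  expect_false(any(cellidx == 55))
  counts <- tabulate(cellidx + 1L, 100)[-56]
  expect_true(all(abs(counts / 99000 - 1 / 99) < 0.003))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("movement is deterministic under a fixed seed", {
  a <- tibble::tibble(agent_id = 1:2, row = c(3L, 7L), col = c(3L, 7L))
  set.seed(10)
  m1 <- move_agents(a, 10, 10)
  set.seed(10)
  m2 <- move_agents(a, 10, 10)
  expect_identical(m1, m2)
})

test_that("frozen dynamics leave self-esteem unchanged", {
  cfg <- sim_config(n_timesteps = 30, burn_in = 5, seed = 3,
                    core = core_params(leak_rate = 0, intra_boost = 0.01),
                    ts_admi = 0.15, ts_riva = 0.15)
  traj <- run_simulation(cfg)
  expect_true(all(traj$se == 0.8))
  expect_true(all(traj$action == "none"))
})

test_that("the record stream is complete, flagged, and within bounds", {
  cfg <- sim_config(n_timesteps = 60, burn_in = 20, seed = 5,
                    learning_agents = 1L,
                    environment = environment_profile("overvaluing"),
                    focal_overrides = list(ts_admi = 0.03))
  traj <- run_simulation(cfg)
  expect_equal(nrow(traj), 60 * 20)
  expect_equal(sum(!traj$is_burnin), 40 * 20)
  expect_false(any(duplicated(traj[, c("t", "agent_id")])))
  expect_true(all(traj$se >= 0 & traj$se <= 1))
  expect_true(all(traj$nfa >= 0 & traj$nfa <= 1))
  lp <- cfg$learning
  expect_true(all(traj$ts_admi >= lp$ts_floor & traj$ts_admi <= lp$ts_ceiling))
  expect_true(all(traj$ts_riva >= lp$ts_floor & traj$ts_riva <= lp$ts_ceiling))
  expect_true(all(traj$ts_intra < lp$ts_floor))
  expect_true(all(traj$row >= 0 & traj$row <= 9 & traj$col >= 0 &
                    traj$col <= 9))
})

test_that("identical configurations reproduce bit-identical trajectories", {
  cfg <- sim_config(n_timesteps = 80, seed = 123, learning_agents = 1L,
                    environment = environment_profile("control"),
                    focal_overrides = list(ts_admi = 0.0055))
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  t3 <- run_simulation(sim_config(n_timesteps = 80, seed = 124,
                                  learning_agents = 1L,
                                  environment = environment_profile("control"),
                                  focal_overrides = list(ts_admi = 0.0055)))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("step_world agrees with run_simulation step by step", {
  cfg <- make_fixture_world(seed = 9, n_timesteps = 25)
  full <- run_simulation(cfg)
  w <- make_world(cfg)
  for (t in 1:25) {
    st <- step_world(w)
    w <- st$world
    ref <- full[full$t == t, ]
    expect_equal(st$records$se, ref$se)
    expect_equal(st$records$action, ref$action)
  }
})

test_that("the fixture world always offers a partner", {
  traj <- run_simulation(make_fixture_world(seed = 1))
  expect_true(all(traj$partner_available))
})

test_that("invalid configurations are rejected before stepping", {
  expect_error(sim_config(burn_in = 300, n_timesteps = 200), "burn_in")
  expect_error(sim_config(n_agents = 1), "n_agents")
  expect_error(sim_config(ts_intra = 0.01), "ts_intra")
  expect_error(sim_config(ts_admi = 0.2), "ts_admi")
  expect_error(sim_config(focal_overrides = list(ts_admy = 0.01)),
               "focal_overrides")
})
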