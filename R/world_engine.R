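#' Random movement on the grid
#'
#' Every agent teleports to a cell drawn uniformly at random among all cells
#' *except* its current one ("moves to another cell"); several agents may share
#' a cell. Uses the current RNG state.
#'
#' @param agents A data frame with 0-based `row` and `col` columns.
#' @param grid_rows,grid_cols Grid dimensions.
#' @return `agents` with updated positions.
#' @export
#' @examples
#' set.seed(1)
#' move_agents(tibble::tibble(agent_id = 1, row = 0, col = 0), 1, 2)
move_agents <- function(agents, grid_rows, grid_cols) {
  ncell <- grid_rows * grid_cols
  if (ncell < 2) abort("Movement requires a grid with at least 2 cells.")
  cell <- agents$row * grid_cols + agents$col
  if (any(cell < 0 | cell >= ncell)) abort("Agent positions are off the grid.")
  cell <- (cell + sample.int(ncell - 1L, nrow(agents), replace = TRUE)) %% ncell
  agents$row <- cell %/% grid_cols
  agents$col <- cell %% grid_cols
  agents
}

# World state as flat vectors for speed. Seeds the run's RNG stream.
init_world <- function(cfg) {
  cfg <- validate_config(cfg)
  n <- cfg$n_agents
  ths <- resolved_thresholds(cfg)
  set.seed(cfg$seed)
  w <- list(
    cfg = cfg,
    resp = resolve_response_params(cfg$response, cfg$environment),
    t = 0L,
    cell = sample.int(cfg$grid_rows * cfg$grid_cols, n, replace = TRUE) - 1L,
    se = rep(cfg$init_se, n),
    nfa = rep(cfg$init_nfa, n),
    tsi = rep(ths$default$ts_intra, n),
    tsa = rep(ths$default$ts_admi, n),
    tsr = rep(ths$default$ts_riva, n),
    learn = seq_len(n) %in% cfg$learning_agents
  )
  w$tsi[1] <- ths$focal$ts_intra
  w$tsa[1] <- ths$focal$ts_admi
  w$tsr[1] <- ths$focal$ts_riva
  w
}

# One timestep: (1) move everyone; (2) agents act in freshly shuffled order
# (leakage -> regulation need -> partner check -> hierarchical behaviour
# selection -> execution -> contingent + non-contingent learning for learning
# agents); (3) need-for-admiration habituation from post-action self-esteem.
# Returns the updated world plus flat per-agent step results.
step_world_impl <- function(w) {
  cfg <- w$cfg
  n <- cfg$n_agents
  ncell <- cfg$grid_rows * cfg$grid_cols
  gcols <- cfg$grid_cols
  leak <- cfg$core$leak_rate
  boost <- cfg$core$intra_boost
  adapt_up <- cfg$core$nfa_adapt_up
  adapt_down <- cfg$core$nfa_adapt_down
  p_admi <- w$resp$p_pos_admi
  p_riva <- w$resp$p_pos_riva
  coup <- w$resp$status_coupling
  mag_admi <- w$resp$mag_admi
  mag_riva <- w$resp$mag_riva
  cl <- cfg$learning$cl_step
  ncl <- cfg$learning$ncl_step
  fl <- cfg$learning$ts_floor
  ce <- cfg$learning$ts_ceiling
  p_over <- cfg$environment$p_overvaluation
  p_deval <- cfg$environment$p_devaluation

  se <- w$se
  nfa <- w$nfa
  tsi <- w$tsi
  tsa <- w$tsa
  tsr <- w$tsr
  learn <- w$learn

  cell <- (w$cell + sample.int(ncell - 1L, n, replace = TRUE)) %% ncell
  row <- cell %/% gcols
  col <- cell %% gcols
  near <- abs(outer(row, row, "-")) <= 1L & abs(outer(col, col, "-")) <= 1L
  diag(near) <- FALSE

  act <- integer(n)
  part <- rep(NA_integer_, n)
  rsp <- numeric(n)
  ev <- integer(n)
  pav <- logical(n)

  for (i in sample.int(n)) {
    s <- se[i] * (1 - leak)
    d <- nfa[i] - s
    near_i <- near[i, ]
    has_p <- any(near_i)
    pav[i] <- has_p
    a <- 0L
    if (d > tsi[i]) {
      exc_a <- d > tsa[i]
      exc_r <- d > tsr[i]
      if ((exc_a || exc_r) && has_p) {
        a <- if (exc_a && exc_r) {
          if (tsr[i] > tsa[i]) 3L else 2L
        } else if (exc_r) 3L else 2L
        cand <- which(near_i)
        j <- cand[sample.int(length(cand), 1L)]
        part[i] <- j
        if (a == 2L) {
          base <- p_admi
          mag <- mag_admi
        } else {
          base <- p_riva
          mag <- mag_riva
        }
        p <- base + coup * (s - se[j])
        if (p < 0) p <- 0 else if (p > 1) p <- 1
        r <- if (runif(1) < p) mag else -mag
        s <- s + r
        if (s > 1) s <- 1 else if (s < 0) s <- 0
        rsp[i] <- r
        # a zero-magnitude (indifferent) response carries no reinforcement
        # signal, so contingent learning only fires on a real response
        if (learn[i] && r != 0) {
          if (a == 2L) {
            v <- if (r > d) tsa[i] - cl else tsa[i] + cl
            tsa[i] <- min(ce, max(fl, v))
          } else {
            v <- if (r > d) tsr[i] - cl else tsr[i] + cl
            tsr[i] <- min(ce, max(fl, v))
          }
        }
      } else {
        a <- 1L
        s <- s + boost
        if (s > 1) s <- 1
      }
    }
    se[i] <- s
    act[i] <- a
    if (learn[i]) {
      u <- runif(1)
      if (u < p_over) {
        ev[i] <- 1L
        tsa[i] <- max(fl, tsa[i] - ncl)
      } else if (u < p_over + p_deval) {
        ev[i] <- 2L
        tsr[i] <- max(fl, tsr[i] - ncl)
      }
    }
  }

  nfa <- clamp01(nfa + ifelse(se > nfa, adapt_up, adapt_down) * (se - nfa))

  w$t <- w$t + 1L
  w$cell <- cell
  w$se <- se
  w$nfa <- nfa
  w$tsa <- tsa
  w$tsr <- tsr
  list(world = w, row = row, col = col, act = act, part = part, rsp = rsp,
       ev = ev, pav = pav)
}

action_levels <- c("none", "intra", "admiration", "rivalry")
event_levels <- c("none", "overvaluation", "devaluation")

#' Advance a simulated world by one timestep
#'
#' Executes, in order: movement of all agents; for each agent in a freshly
#' shuffled order, leakage, regulation-need computation, partner check,
#' hierarchical behaviour selection and execution (with contingent and
#' non-contingent threshold learning for learning agents); then the
#' need-for-admiration habituation of every agent from its post-action
#' self-esteem.
#'
#' @param world A world state from [make_world()] or a previous `step_world()`
#'   call.
#' @return A list with `world` (the advanced state) and `records` (a tibble
#'   with one row per agent for the executed timestep).
#' @export
#' @examples
#' w <- make_world(sim_config(n_timesteps = 10, seed = 1))
#' step_world(w)$records
step_world <- function(world) {
  st <- step_world_impl(world)
  w <- st$world
  n <- w$cfg$n_agents
  records <- tibble::tibble(
    run = 1L,
    t = w$t,
    agent_id = seq_len(n),
    row = st$row,
    col = st$col,
    se = w$se,
    nfa = w$nfa,
    ts_intra = w$tsi,
    ts_admi = w$tsa,
    ts_riva = w$tsr,
    action = action_levels[st$act + 1L],
    partner_id = st$part,
    rsp = st$rsp,
    env_event = event_levels[st$ev + 1L],
    partner_available = st$pav,
    is_burnin = w$t <= w$cfg$burn_in
  )
  list(world = w, records = records)
}

#' Initialise a world from a configuration
#'
#' Seeds the run's RNG stream from `config$seed` and places all agents at the
#' configured initial self-esteem/need-for-admiration with random grid
#' positions.
#'
#' @param config A [sim_config()] object.
#' @return An opaque world state for [step_world()].
#' @export
make_world <- function(config) {
  init_world(config)
}

#' Run a full simulation
#'
#' Runs `config$n_timesteps` timesteps from the standard initial state and
#' returns the trajectory table: one row per recorded agent per timestep, with
#' the first `config$burn_in` timesteps flagged by `is_burnin` (kept, never
#' dropped). The output is bit-reproducible for identical `(config, seed)`.
#'
#' @param config A [sim_config()] object.
#' @param run Run index embedded in the output (default 1).
#' @return A `ser_trajectory` tibble with columns `run`, `t`, `agent_id`,
#'   `row`, `col`, `se`, `nfa`, `ts_intra`, `ts_admi`, `ts_riva`, `action`,
#'   `partner_id`, `rsp`, `env_event`, `partner_available`, `is_burnin`.
#'   The configuration and seed are attached as attributes `config` and
#'   `seed`.
#' @export
#' @examples
#' traj <- run_simulation(sim_config(n_timesteps = 60, seed = 7))
#' dplyr::count(traj, action)
run_simulation <- function(config, run = 1L) {
  w <- init_world(config)
  cfg <- w$cfg
  tmax <- cfg$n_timesteps
  rec_ids <- if (cfg$record == "focal") 1L else seq_len(cfg$n_agents)
  nr <- length(rec_ids)
  nout <- nr * tmax

  o_row <- integer(nout); o_col <- integer(nout)
  o_se <- numeric(nout); o_nfa <- numeric(nout)
  o_tsa <- numeric(nout); o_tsr <- numeric(nout)
  o_act <- integer(nout); o_part <- rep(NA_integer_, nout)
  o_rsp <- numeric(nout); o_ev <- integer(nout); o_pav <- logical(nout)

  for (t in seq_len(tmax)) {
    st <- step_world_impl(w)
    w <- st$world
    idx <- (t - 1L) * nr + seq_len(nr)
    o_row[idx] <- st$row[rec_ids]
    o_col[idx] <- st$col[rec_ids]
    o_se[idx] <- w$se[rec_ids]
    o_nfa[idx] <- w$nfa[rec_ids]
    o_tsa[idx] <- w$tsa[rec_ids]
    o_tsr[idx] <- w$tsr[rec_ids]
    o_act[idx] <- st$act[rec_ids]
    o_part[idx] <- st$part[rec_ids]
    o_rsp[idx] <- st$rsp[rec_ids]
    o_ev[idx] <- st$ev[rec_ids]
    o_pav[idx] <- st$pav[rec_ids]
  }

  tvec <- rep(seq_len(tmax), each = nr)
  out <- tibble::tibble(
    run = as.integer(run),
    t = tvec,
    agent_id = rep(rec_ids, times = tmax),
    row = o_row,
    col = o_col,
    se = o_se,
    nfa = o_nfa,
    ts_intra = rep(w$tsi[rec_ids], times = tmax),
    ts_admi = o_tsa,
    ts_riva = o_tsr,
    action = action_levels[o_act + 1L],
    partner_id = o_part,
    rsp = o_rsp,
    env_event = event_levels[o_ev + 1L],
    partner_available = o_pav,
    is_burnin = tvec <= cfg$burn_in
  )
  attr(out, "config") <- cfg
  attr(out, "seed") <- cfg$seed
  class(out) <- c("ser_trajectory", class(out))
  out
}

# Derive per-run seeds from a master seed: one deterministic stream,
# independent of how many runs are later consumed.
derive_run_seeds <- function(master_seed, n_runs) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n_runs)
}
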