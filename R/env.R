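# Agent-facing environment: reset/step loop binding the musculoskeletal
# dynamics, the reward system and the target-velocity task.
#
# Two interface modes:
#  * "compat-22": the published interface -- 22 muscle excitations, a 97-dim
#    body observation and a 242-dim target velocity map.  The frontal-plane
#    muscles HAB/HAD have no mechanical action in the sagittal-plane core;
#    their activations still follow the excitation dynamics and enter the
#    effort cost and the observation.
#  * "planar-18": the native sagittal interface -- 18 excitations and an
#    81-dim body observation.
#
# 97-dim body layout (compat-22): pelvis block of 9 (height, pitch, roll,
# forward/vertical/lateral velocity, pitch/roll/yaw rate; frontal-plane
# entries are exact zeros), then per leg (right first) 44 = 3 ground-reaction
# components normalised by body weight (forward, lateral, vertical) + 4
# joint angles (hip flexion, hip abduction, knee, ankle) + 4 joint speeds +
# 11 muscles x (force / f_max, CE length / l_opt, CE velocity / v_max).
# 81-dim layout (planar-18): same pelvis block, then per leg 36 =
# (GRF forward, GRF vertical, contact flag) + 3 angles + 3 speeds +
# 9 muscles x 3.

#' Episode configuration
#'
#' @param mode Interface mode, `"compat-22"` or `"planar-18"`.
#' @param seed Integer seed controlling target sampling.
#' @param max_steps Episode cap in control steps.
#' @param forward_speed Initial forward pelvis speed (m/s).
#' @param target_annulus Radial bounds (m) for target sampling ahead of the
#'   pelvis.
#' @return A list of class `episode_config`.
#' @export
episode_config <- function(mode = c("compat-22", "planar-18"), seed = 1L,
                           max_steps = 2500L, forward_speed = 0,
                           target_annulus = c(2, 6)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1, max_steps >= 1,
            target_annulus[1] > 0, target_annulus[2] >= target_annulus[1])
  structure(list(mode = mode, seed = as.integer(seed),
                 max_steps = as.integer(max_steps),
                 forward_speed = forward_speed,
                 target_annulus = target_annulus),
            class = "episode_config")
}

#' Create a walker environment
#'
#' Builds the environment object binding the planar musculoskeletal model,
#' the footstep-segmented reward and the target-velocity task.  Call
#' [env_reset()] before stepping.
#'
#' @param model A `walker_config` (default [default_walker_config()]).
#' @param reward A [reward_config()].
#' @param episode An [episode_config()].
#' @return An object of class `walker_env` (a stateful environment).
#' @export
walker_env <- function(model = default_walker_config(),
                       reward = reward_config(),
                       episode = episode_config()) {
  e <- new.env(parent = emptyenv())
  e$model <- model
  e$reward <- reward
  e$episode <- episode
  e$core <- build_core_params(model)
  e$weight <- sum(e$core$mass) * model$gravity
  e$muscles_all <- muscle_order(model, planar = episode$mode == "planar-18")
  e$muscles_mech <- e$core$mus_names
  e$active <- FALSE
  class(e) <- "walker_env"
  e
}

#' @export
print.walker_env <- function(x, ...) {
  cat("walker_env (", x$episode$mode, ", ",
      if (x$active) sprintf("active, step %d", x$step_count) else "inactive",
      ")\n", sep = "")
  invisible(x)
}

#' Dimensions of the environment interface
#'
#' @param env A `walker_env`.
#' @return List with `n_action`, `n_body`, `n_map`.
#' @export
env_dims <- function(env) {
  if (env$episode$mode == "compat-22") {
    list(n_action = 22L, n_body = 97L, n_map = 242L)
  } else {
    list(n_action = 18L, n_body = 81L, n_map = 242L)
  }
}

#' Reset the environment
#'
#' Places the model in the static standing pose at the origin, seeds the
#' RNG, samples the first target and returns the initial observation.
#' Deterministic per seed.
#'
#' @param env A `walker_env`.
#' @return Observation: list with `body` (97- or 81-vector) and `vtgt_map`
#'   (242-vector).
#' @export
env_reset <- function(env) {
  stopifnot(inherits(env, "walker_env"))
  ep <- env$episode
  # seed a private RNG stream so environment sampling never disturbs the
  # caller's RNG state
  env$rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(ep$seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  env$state <- initial_state(env$model, forward_speed = ep$forward_speed)
  n_extra <- length(env$muscles_all) - length(env$muscles_mech)
  env$act_frontal <- rep(0, n_extra)      # HAB/HAD activations (compat mode)
  env$step_count <- 0L
  env$done <- FALSE
  env$active <- TRUE
  env$fallen <- FALSE
  env$ledger <- new_footstep_ledger(0)
  env$r_alive <- 0; env$r_step <- 0; env$r_target <- 0
  env$trace <- numeric(0)
  env$targets_reached <- 0L
  env$target <- .with_env_rng(env, sample_target(c(env$state$q[1], 0), 1L,
                                                 env$reward,
                                                 annulus = ep$target_annulus))
  env$airborne <- c(r = 0, l = 0)
  env$prev_contact <- c(TRUE, TRUE)
  env$log_rows <- vector("list", ep$max_steps)
  # evaluate muscles/contact at the initial state for the first observation
  env$last_info <- .eval_state_info(env)
  build_observation(env)
}

# evaluate expr under the environment's private RNG stream, then put the
# caller's stream back
.with_env_rng <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", env$rng, envir = globalenv())
  on.exit({
    env$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

.eval_state_info <- function(env) {
  s <- env$state
  g <- .pt_muscle_geometry(s$q, s$qd, env$core)
  g <- lapply(g, as.numeric)
  cf <- .pt_contact_forces(s$q, s$qd, env$core)
  # forces at current activation, composed from the scalar curves
  f <- env$core$mus_fmax *
    (s$act * force_length_active(g$lce_norm) *
       vapply(seq_along(s$act),
              function(i) force_velocity(g$vce_norm[i],
                                         env$core$mus_fvplateau[i]),
              numeric(1)) +
       force_passive(g$lce_norm))
  f[g$lce_norm <= 0] <- 0
  list(mus_force = pmax(f, 0), mus_lce_norm = g$lce_norm,
       mus_vce_norm = g$vce_norm, contact = cf)
}

#' Assemble the observation
#'
#' Builds the documented body vector and the 242-dim local target-velocity
#' map from the current environment state (see the layout notes in
#' `?walker_env`).  Ground-reaction components are normalised by body
#' weight; muscle entries by `f_max`, `l_opt` and `v_max`.
#'
#' @param env A `walker_env` that has been reset.
#' @return List with `body` and `vtgt_map`.
#' @export
build_observation <- function(env) {
  stopifnot(isTRUE(env$active))
  s <- env$state
  info <- env$last_info
  mode <- env$episode$mode
  q <- s$q; qd <- s$qd
  pelvis <- c(q[2], q[3], 0, qd[1], qd[2], 0, qd[3], 0, 0)

  cf <- info$contact
  grf <- function(rows) colSums(cf[rows, 1:2, drop = FALSE]) / env$weight
  leg_block <- function(side) {
    rows <- if (side == "r") 1:3 else 4:6
    jix <- if (side == "r") 4:6 else 7:9
    g <- grf(rows)
    contact <- any(cf[rows, 3] > 0)
    mech_ix <- grep(paste0("_", toupper(side), "$"), env$muscles_mech)
    mus <- as.vector(rbind(info$mus_force[mech_ix] / env$core$mus_fmax[mech_ix],
                           info$mus_lce_norm[mech_ix],
                           info$mus_vce_norm[mech_ix]))
    if (mode == "compat-22") {
      # HAB/HAD: no mechanical path; force entry mirrors activation,
      # length/velocity sit at their neutral values
      fr_ix <- if (side == "r") 1:2 else 3:4
      fr <- env$act_frontal[fr_ix]
      frontal <- as.vector(rbind(fr, c(1, 1), c(0, 0)))
      c(g[1], 0, g[2],                       # GRF fwd, lat, vert
        q[jix[1]], 0, q[jix[2]], q[jix[3]],  # hip flex, hip abd, knee, ankle
        qd[jix[1]], 0, qd[jix[2]], qd[jix[3]],
        frontal, mus)
    } else {
      c(g[1], g[2], as.numeric(contact),
        q[jix], qd[jix], mus)
    }
  }
  body <- c(pelvis, leg_block("r"), leg_block("l"))
  field <- velocity_field(target = env$target$location,
                          speed = env$reward$speed,
                          proximity_radius = env$reward$proximity_radius)
  map <- local_velocity_map(field, c(q[1], 0), heading = 0)
  stopifnot(all(is.finite(body)), all(is.finite(map)))
  list(body = body, vtgt_map = map)
}

#' Advance the environment by one control step
#'
#' Applies the excitation action for one 0.01 s control step, advances the
#' musculoskeletal dynamics, updates the footstep ledger and the target
#' bookkeeping, and returns the new observation, the step reward (alive
#' increment plus any footstep-closure reward and target bonus), the
#' termination flag and an info record with the running reward
#' decomposition.  Stepping a finished episode is a hard failure; so are
#' non-finite action entries.
#'
#' @param env A `walker_env` that has been reset.
#' @param action Excitation vector (length 22 in compat-22 mode, 18 in
#'   planar-18); values outside `[0, 1]` are clamped.
#' @return List with `observation`, `reward`, `done`, `info`.
#' @export
env_step <- function(env, action) {
  stopifnot(inherits(env, "walker_env"), isTRUE(env$active))
  if (env$done) stop("env_step() called on a finished episode", call. = FALSE)
  dims <- env_dims(env)
  if (length(action) != dims$n_action) {
    stop("action must have length ", dims$n_action, call. = FALSE)
  }
  if (any(!is.finite(action))) {
    stop("non-finite action entry at index ", which(!is.finite(action))[1],
         call. = FALSE)
  }
  rw <- env$reward
  dt <- rw$dt
  compat <- env$episode$mode == "compat-22"

  # split the action into mechanical and frontal-plane channels
  if (compat) {
    all_n <- env$muscles_all
    frontal_ix <- grep("^(HAB|HAD)_", all_n)
    mech_exc <- action[match(env$muscles_mech, all_n)]
    fr_exc <- pmin(pmax(action[frontal_ix], 0), 1)
    tau_a <- 0.015; tau_d <- 0.05
    env$act_frontal <- ifelse(
      fr_exc >= env$act_frontal,
      fr_exc + (env$act_frontal - fr_exc) * exp(-dt / tau_a),
      fr_exc + (env$act_frontal - fr_exc) * exp(-dt / tau_d))
  } else {
    mech_exc <- action
  }

  env$state <- integrate_step(env$state, mech_exc, env$core, dt = dt,
                              substeps = env$model$simulation$substeps)
  info_raw <- attr(env$state, "info")
  env$last_info <- list(mus_force = info_raw$mus_force,
                        mus_lce_norm = info_raw$mus_lce_norm,
                        mus_vce_norm = info_raw$mus_vce_norm,
                        contact = info_raw$contact)
  env$step_count <- env$step_count + 1L
  s <- env$state
  reward_t <- 0

  # footstep segmentation
  cf <- info_raw$contact
  contact_now <- c(any(cf[1:3, 3] > 0), any(cf[4:6, 3] > 0))
  ev <- detect_footstep_event(env$prev_contact, contact_now, env$airborne,
                              env$ledger$open$duration, rw)
  if (ev == "new_step") {
    cl <- close_footstep(env$ledger, rw, time = s$time)
    env$r_step <- env$r_step + cl$reward
    reward_t <- reward_t + cl$reward
    env$ledger <- cl$ledger
  }
  env$airborne <- ifelse(contact_now, 0, env$airborne + dt)
  env$prev_contact <- contact_now

  # accumulate this step (current target defines v_tgt0)
  pel <- c(s$q[1], 0)
  field <- velocity_field(target = env$target$location, speed = rw$speed,
                          proximity_radius = rw$proximity_radius)
  v_tgt0 <- field_at(field, pel)
  acts <- if (compat) {
    full <- numeric(length(env$muscles_all))
    full[match(env$muscles_mech, env$muscles_all)] <- s$act
    full[grep("^(HAB|HAD)_", env$muscles_all)] <- env$act_frontal
    full
  } else s$act
  env$ledger <- accumulate_step(env$ledger, c(s$qd[1], 0), v_tgt0, acts, dt)

  # alive bonus / fall
  if (s$q[2] < rw$fall_height) {
    env$fallen <- TRUE
  } else {
    env$r_alive <- env$r_alive + rw$b_alive
    reward_t <- reward_t + rw$b_alive
  }

  # target bookkeeping (log the pre-update target for this row)
  row_target <- env$target
  if (!env$target$awarded) {
    up <- update_target(env$target, pel, dt, rw)
    env$target <- up$spec
    if (up$bonus > 0) {
      env$r_target <- env$r_target + up$bonus
      reward_t <- reward_t + up$bonus
      env$targets_reached <- env$targets_reached + 1L
      if (env$targets_reached < rw$n_targets) {
        env$target <- .with_env_rng(
          env, sample_target(pel, env$targets_reached + 1L, rw,
                             annulus = env$episode$target_annulus))
      }
    }
  }

  env$done <- env$fallen || env$step_count >= env$episode$max_steps
  if (env$done && env$ledger$open$duration > 0) {
    cl <- close_footstep(env$ledger, rw)
    env$r_step <- env$r_step + cl$reward
    reward_t <- reward_t + cl$reward
    env$ledger <- cl$ledger
  }
  env$trace <- c(env$trace, reward_t)
  env$log_rows[[env$step_count]] <- .log_row(env, s, contact_now, acts,
                                             row_target)

  obs <- build_observation(env)
  list(observation = obs, reward = reward_t, done = env$done,
       info = list(step = env$step_count, time = s$time,
                   fallen = env$fallen,
                   R_alive = env$r_alive, R_step = env$r_step,
                   R_target = env$r_target,
                   J = env$r_alive + env$r_step + env$r_target,
                   open_step = env$ledger$open,
                   contact = contact_now,
                   excitation_clamped = isTRUE(info_raw$excitation_clamped)))
}

.log_row <- function(env, s, contact_now, acts, target) {
  row <- c(time = s$time - env$reward$dt,
           pel_x = s$q[1], pel_lat = 0, pel_height = s$q[2],
           pel_pitch = s$q[3], v_x = s$qd[1], v_lat = 0,
           hip_r = s$q[4], knee_r = s$q[5], ankle_r = s$q[6],
           hip_l = s$q[7], knee_l = s$q[8], ankle_l = s$q[9],
           dhip_r = s$qd[4], dknee_r = s$qd[5], dankle_r = s$qd[6],
           dhip_l = s$qd[7], dknee_l = s$qd[8], dankle_l = s$qd[9],
           contact_r = as.numeric(contact_now[1]),
           contact_l = as.numeric(contact_now[2]))
  names(acts) <- paste0("act_", env$muscles_all)
  c(row, acts,
    tgt_x = target$location[1], tgt_lat = target$location[2],
    tgt_index = target$index, tgt_dwell = target$required_dwell)
}

#' Termination check
#'
#' An episode terminates when the pelvis drops below the fall threshold or
#' when the step cap is reached.
#'
#' @param state A `body_state`.
#' @param step_count Steps taken so far.
#' @param reward A [reward_config()] (for the fall threshold).
#' @param max_steps Episode cap.
#' @return Logical.
#' @export
check_termination <- function(state, step_count, reward = reward_config(),
                              max_steps = 2500) {
  state$q[2] < reward$fall_height || step_count >= max_steps
}

#' Episode result of a finished (or running) environment
#'
#' @param env A `walker_env`.
#' @return An [episode_result()] with the running decomposition.
#' @export
env_result <- function(env) {
  stopifnot(inherits(env, "walker_env"), isTRUE(env$active))
  episode_result(env$r_alive, env$r_step, env$r_target,
                 reward_trace = env$trace,
                 footsteps = footstep_table(env$ledger),
                 n_steps = env$step_count,
                 targets_reached = env$targets_reached,
                 fallen = env$fallen)
}

#' Trajectory log of the episode so far
#'
#' One row per control step in the [trajectory_columns()] schema, suitable
#' for [write_trajectory()] and exactly re-scorable with
#' [score_trajectory()].
#'
#' @param env A `walker_env`.
#' @return A tibble.
#' @export
env_trajectory <- function(env) {
  stopifnot(inherits(env, "walker_env"), isTRUE(env$active),
            env$step_count > 0)
  rows <- env$log_rows[seq_len(env$step_count)]
  df <- tibble::as_tibble(do.call(rbind, rows))
  df$tgt_index <- as.integer(df$tgt_index)
  df
}
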