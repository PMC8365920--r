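# Footstep-segmented reward system: alive bonus, per-footstep step reward
# (step-duration bonus minus velocity and effort costs) and target bonuses.
#
# Total episode reward decomposes exactly as
#   J = R_alive + R_step + R_target
#     = sum_i_sim b_alive
#       + sum_i_step (w_s * b_s - w_v * c_v - w_e * c_e)
#       + sum_i_target b_target
# where, within each footstep,
#   b_s = sum dt                       (step duration),
#   c_v = || sum (v_pel - v_tgt0) dt ||_2   (deviation of *average* velocity),
#   c_e = sum_m sum A_m^2 dt           (activation-squared effort).
# Because c_v depends only on the time-integral of the velocity error, the
# instantaneous velocity may fluctuate freely within a footstep, and because
# b_s is proportional to the step duration the total reward does not favour
# many small footsteps over fewer large ones.

#' Reward configuration
#'
#' The constants of the reward system.  Defaults are the competition-mode
#' values: alive bonus 0.1 per 0.01 s simulation step, step-bonus weight 10,
#' velocity-cost weight 3, effort-cost weight 1, target bonus 500 for each of
#' two targets held within 0.3 m for a required dwell drawn from 2-4 s, and a
#' 2500-step episode, giving a hypothetical maximum total reward of
#' 250 + 250 + 1000 = 1500.
#'
#' @param b_alive Alive bonus per simulation step.
#' @param w_s,w_v,w_e Weights of the step bonus, velocity cost, effort cost.
#' @param b_target Bonus per reached-and-held target.
#' @param dt Simulation/control time step (s).
#' @param max_sim_steps Episode cap in simulation steps.
#' @param n_targets Number of targets per episode.
#' @param proximity_radius Distance (m) within which target dwell accrues.
#' @param dwell_range Range (s) the required dwell is drawn from.
#' @param min_swing_time Minimum airborne time (s) for a touchdown to count
#'   as a new footstep (debounces contact chatter).
#' @param forced_closure Horizon (s) after which an open footstep is closed
#'   even without a touchdown, so standing phases are still scored.
#' @param fall_height Pelvis height (m) below which the model counts as
#'   fallen.
#' @param speed Commanded walking speed of the target velocity field (m/s).
#' @return A list of class `reward_config`.
#' @export
reward_config <- function(b_alive = 0.1, w_s = 10, w_v = 3, w_e = 1,
                          b_target = 500, dt = 0.01, max_sim_steps = 2500,
                          n_targets = 2, proximity_radius = 0.3,
                          dwell_range = c(2, 4), min_swing_time = 0.05,
                          forced_closure = 5, fall_height = 0.6,
                          speed = 1.4) {
  stopifnot(b_alive > 0, w_s > 0, w_v > 0, w_e > 0, b_target > 0, dt > 0,
            max_sim_steps > 0, n_targets >= 1, proximity_radius > 0,
            length(dwell_range) == 2, dwell_range[1] > 0,
            dwell_range[2] >= dwell_range[1], min_swing_time >= 0,
            forced_closure > 0, speed >= 0)
  structure(as.list(environment()), class = "reward_config")
}

#' Alive-bonus increment
#'
#' The per-simulation-step reward for not having fallen.
#'
#' @param config A [reward_config()].
#' @return `b_alive`.
#' @export
alive_increment <- function(config = reward_config()) config$b_alive

#' Create an empty footstep ledger
#'
#' The ledger accumulates, per footstep, the step duration, the integral of
#' the pelvis-velocity error and the effort integral, and keeps an immutable
#' record of closed footsteps.
#'
#' @param start_time Episode time (s) at which the first footstep opens.
#' @return A list of class `footstep_ledger`.
#' @export
new_footstep_ledger <- function(start_time = 0) {
  structure(list(
    i_step = 1L,
    open = list(duration = 0, v_int = c(0, 0), effort = 0,
                start_time = start_time),
    closed = list()),
    class = "footstep_ledger")
}

#' Detect a footstep event from contact transitions
#'
#' A new footstep begins when a foot that has been airborne for at least
#' `min_swing_time` regains ground contact, or when the open footstep has
#' lasted at least `forced_closure` seconds without such a touchdown (the
#' standing case), so that velocity and effort costs are never left
#' unscored in degenerate gaits.
#'
#' @param prev_contact,contact Logical vectors of per-foot contact flags
#'   (previous and current control step).
#' @param airborne_time Numeric vector: time (s) each foot has been airborne
#'   as of the previous step.
#' @param open_duration Duration (s) of the currently open footstep.
#' @param config A [reward_config()].
#' @return `"new_step"` or `"none"`.
#' @export
detect_footstep_event <- function(prev_contact, contact, airborne_time,
                                  open_duration, config = reward_config()) {
  touchdown <- any(!prev_contact & contact &
                     airborne_time >= config$min_swing_time)
  if (touchdown) return("new_step")
  if (open_duration >= config$forced_closure) return("new_step")
  "none"
}

#' Accumulate one control step into the open footstep
#'
#' Adds `dt` to the step duration, `(v_pel - v_tgt0) dt` to the velocity
#' error integral (a 2-vector, so only the average velocity over the step is
#' penalised) and `dt * sum(A_m^2)` to the effort integral.
#'
#' @param ledger A `footstep_ledger`.
#' @param v_pel Pelvis velocity in the ground plane (m/s, 2-vector).
#' @param v_tgt0 Commanded velocity at the pelvis position (m/s, 2-vector).
#' @param activations Muscle activations in `[0, 1]`.
#' @param dt Time step (s).
#' @return The updated ledger.
#' @export
accumulate_step <- function(ledger, v_pel, v_tgt0, activations, dt) {
  stopifnot(inherits(ledger, "footstep_ledger"), length(v_pel) == 2,
            length(v_tgt0) == 2, dt > 0)
  ledger$open$duration <- ledger$open$duration + dt
  ledger$open$v_int <- ledger$open$v_int + (v_pel - v_tgt0) * dt
  ledger$open$effort <- ledger$open$effort + effort_increment(activations, dt)
  ledger
}

#' Close the open footstep and score it
#'
#' Step reward `w_s * b_s - w_v * c_v - w_e * c_e` where `b_s` is the step
#' duration, `c_v` the Euclidean norm of the accumulated velocity-error
#' integral and `c_e` the accumulated effort integral.  The closed step is
#' appended to the immutable record and a new footstep opens.
#'
#' @param ledger A `footstep_ledger`.
#' @param config A [reward_config()].
#' @param time Episode time (s) at closure, used as the start of the next
#'   open step.
#' @return List with `reward` (the step reward; 0 with a warning flag for a
#'   zero-duration step) and `ledger` (the updated ledger).
#' @export
close_footstep <- function(ledger, config = reward_config(),
                           time = ledger$open$start_time + ledger$open$duration) {
  stopifnot(inherits(ledger, "footstep_ledger"))
  o <- ledger$open
  zero_duration <- o$duration <= 0
  b_s <- o$duration
  c_v <- sqrt(sum(o$v_int^2))
  c_e <- o$effort
  reward <- if (zero_duration) 0 else
    config$w_s * b_s - config$w_v * c_v - config$w_e * c_e
  ledger$closed[[length(ledger$closed) + 1L]] <- list(
    i_step = ledger$i_step, b_s = b_s, c_v = c_v, c_e = c_e,
    reward = reward, start_time = o$start_time, zero_duration = zero_duration)
  ledger$i_step <- ledger$i_step + 1L
  ledger$open <- list(duration = 0, v_int = c(0, 0), effort = 0,
                      start_time = time)
  list(reward = reward, ledger = ledger, zero_duration = zero_duration)
}

#' Per-footstep record of a ledger
#'
#' @param ledger A `footstep_ledger`.
#' @return Tibble with one row per closed footstep: `i_step`, `b_s`, `c_v`,
#'   `c_e`, `reward`, `start_time`.
#' @export
footstep_table <- function(ledger) {
  stopifnot(inherits(ledger, "footstep_ledger"))
  if (length(ledger$closed) == 0) {
    return(tibble::tibble(i_step = integer(), b_s = numeric(),
                          c_v = numeric(), c_e = numeric(), reward = numeric(),
                          start_time = numeric()))
  }
  purrr::map_dfr(ledger$closed, function(s) {
    tibble::tibble(i_step = s$i_step, b_s = s$b_s, c_v = s$c_v, c_e = s$c_e,
                   reward = s$reward, start_time = s$start_time)
  })
}

#' Assemble an episode result
#'
#' Exact three-term decomposition of the total reward with the per-step
#' reward trace; the invariant `J = R_alive + R_step + R_target` holds to
#' machine precision by construction.
#'
#' @param r_alive,r_step,r_target Component sums.
#' @param reward_trace Per-control-step reward vector.
#' @param footsteps Per-footstep tibble (see [footstep_table()]).
#' @param n_steps Number of simulation steps scored.
#' @param targets_reached Number of targets awarded.
#' @param fallen Did the episode end in a fall?
#' @return A list of class `episode_result`.
#' @export
episode_result <- function(r_alive, r_step, r_target, reward_trace = numeric(),
                           footsteps = NULL, n_steps = length(reward_trace),
                           targets_reached = NA_integer_, fallen = FALSE) {
  structure(list(J = r_alive + r_step + r_target,
                 R_alive = r_alive, R_step = r_step, R_target = r_target,
                 reward_trace = reward_trace, footsteps = footsteps,
                 n_steps = n_steps, targets_reached = targets_reached,
                 fallen = fallen),
            class = "episode_result")
}

#' @export
print.episode_result <- function(x, ...) {
  cat("Episode result (", x$n_steps, " simulation steps",
      if (isTRUE(x$fallen)) ", ended in fall" else "", ")\n", sep = "")
  cat(sprintf("  J        = %.6f\n", x$J))
  cat(sprintf("  R_alive  = %.6f\n", x$R_alive))
  cat(sprintf("  R_step   = %.6f\n", x$R_step))
  cat(sprintf("  R_target = %.6f\n", x$R_target))
  if (!is.null(x$footsteps) && nrow(x$footsteps) > 0) {
    cat("  footsteps:", nrow(x$footsteps),
        sprintf(" (total duration %.2f s)\n", sum(x$footsteps$b_s)))
  }
  invisible(x)
}

#' Tidy an episode result
#'
#' @param x An `episode_result`.
#' @param ... Unused.
#' @return One row per reward component (`term`, `reward`).
#' @export
tidy.episode_result <- function(x, ...) {
  tibble::tibble(term = c("R_alive", "R_step", "R_target"),
                 reward = c(x$R_alive, x$R_step, x$R_target))
}

#' Glance at an episode result
#'
#' @param x An `episode_result`.
#' @param ... Unused.
#' @return One-row tibble with `J`, the three components, `n_steps`,
#'   `n_footsteps`, `targets_reached` and `fallen`.
#' @export
glance.episode_result <- function(x, ...) {
  tibble::tibble(J = x$J, R_alive = x$R_alive, R_step = x$R_step,
                 R_target = x$R_target, n_steps = x$n_steps,
                 n_footsteps = if (is.null(x$footsteps)) NA_integer_
                               else nrow(x$footsteps),
                 targets_reached = x$targets_reached, fallen = x$fallen)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
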