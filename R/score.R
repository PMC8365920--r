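# Offline scoring of a trajectory log: replays the footstep ledger, target
# bookkeeping and alive bonus over the logged rows and returns the exact
# three-term reward decomposition.

#' Score a logged trajectory
#'
#' Replays the reward system over a trajectory data frame (one row per
#' control step, see [trajectory_columns()]): the alive bonus accrues for
#' every non-fallen step; footsteps are segmented from the per-foot contact
#' flags (touchdown after at least the minimum swing time, with forced
#' closure of over-long steps) and scored as
#' `w_s b_s - w_v c_v - w_e c_e` on closure; target bonuses are awarded from
#' the pelvis position, the logged target location and required dwell.
#' Scoring stops at the first fall; the trailing partial footstep is closed
#' and scored at termination.
#'
#' @param log Trajectory data frame or path to a trajectory CSV.
#' @param config A [reward_config()]; its `speed` is the commanded speed of
#'   the target velocity field used to reconstruct `v_tgt0`.
#' @return An [episode_result()] with the per-footstep table attached.
#' @export
score_trajectory <- function(log, config = reward_config()) {
  if (is.character(log)) log <- read_trajectory(log)
  validate_trajectory(log)
  act_cols <- activation_columns(log)
  actm <- as.matrix(log[, act_cols])
  n <- nrow(log)
  dt <- config$dt
  col <- function(nm) as.numeric(log[[nm]])
  pel_x <- col("pel_x"); pel_lat <- col("pel_lat")
  pel_height <- col("pel_height"); v_x <- col("v_x"); v_lat <- col("v_lat")
  contact_r <- col("contact_r") > 0; contact_l <- col("contact_l") > 0
  tgt_x <- col("tgt_x"); tgt_lat <- col("tgt_lat")
  tgt_index <- as.integer(log$tgt_index); tgt_dwell <- col("tgt_dwell")
  times <- col("time")

  ledger <- new_footstep_ledger(start_time = times[1])
  r_alive <- 0; r_step <- 0; r_target <- 0
  trace <- numeric(n)
  airborne <- c(r = 0, l = 0)
  prev_contact <- c(contact_r[1], contact_l[1])
  awarded_idx <- integer(0)
  cur_idx <- NA_integer_
  dwell <- 0
  fallen <- FALSE
  last <- n

  for (i in seq_len(n)) {
    row_contact <- c(contact_r[i], contact_l[i])
    pel <- c(pel_x[i], pel_lat[i])
    tgt <- c(tgt_x[i], tgt_lat[i])

    # footstep segmentation (touchdown events need one step of history)
    if (i > 1) {
      ev <- detect_footstep_event(prev_contact, row_contact, airborne,
                                  ledger$open$duration, config)
      if (ev == "new_step") {
        cl <- close_footstep(ledger, config, time = times[i])
        r_step <- r_step + cl$reward
        trace[i] <- trace[i] + cl$reward
        ledger <- cl$ledger
      }
    }
    airborne <- ifelse(row_contact, 0, airborne + dt)
    prev_contact <- row_contact

    # accumulate this control step into the open footstep
    field <- velocity_field(target = tgt, speed = config$speed,
                            proximity_radius = config$proximity_radius)
    v_tgt0 <- field_at(field, pel)
    ledger <- accumulate_step(ledger, c(v_x[i], v_lat[i]), v_tgt0,
                              actm[i, ], dt)

    # alive bonus and fall detection
    if (pel_height[i] < config$fall_height) {
      fallen <- TRUE
      last <- i
    } else {
      r_alive <- r_alive + config$b_alive
      trace[i] <- trace[i] + config$b_alive
    }

    # target dwell bookkeeping
    idx <- tgt_index[i]
    if (!identical(idx, cur_idx)) { cur_idx <- idx; dwell <- 0 }
    if (!idx %in% awarded_idx && length(awarded_idx) < config$n_targets) {
      d <- sqrt(sum((pel - tgt)^2))
      dwell <- if (d <= config$proximity_radius) dwell + dt else 0
      if (dwell >= tgt_dwell[i]) {
        awarded_idx <- c(awarded_idx, idx)
        r_target <- r_target + config$b_target
        trace[i] <- trace[i] + config$b_target
      }
    }
    if (fallen) break
  }

  # close the trailing partial footstep
  if (ledger$open$duration > 0) {
    cl <- close_footstep(ledger, config)
    r_step <- r_step + cl$reward
    trace[last] <- trace[last] + cl$reward
    ledger <- cl$ledger
  }

  episode_result(r_alive, r_step, r_target, reward_trace = trace[seq_len(last)],
                 footsteps = footstep_table(ledger), n_steps = last,
                 targets_reached = length(awarded_idx), fallen = fallen)
}

#' Total reward from components
#'
#' Recombines component sums into an [episode_result()]; the decomposition
#' identity `J = R_alive + R_step + R_target` holds by construction.
#'
#' @param r_alive,r_step,r_target Component sums.
#' @param ... Passed to [episode_result()].
#' @return An `episode_result`.
#' @export
total_reward <- function(r_alive, r_step, r_target, ...) {
  episode_result(r_alive, r_step, r_target, ...)
}
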