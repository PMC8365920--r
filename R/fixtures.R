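# Synthetic trajectory fixtures with closed-form expected rewards.
#
# The generator realises a FixtureSpec (episode duration, footstep schedule,
# pelvis velocity profile, activation profile, target scenario) as a
# trajectory log, and computes the expected reward decomposition with a
# direct transcription of the reward formula over the spec's piecewise
# segments -- deliberately independent of the incremental ledger/event
# implementation that the scorer uses, so the two paths check each other.

#' Fixture specification
#'
#' Describes a synthetic episode.  Two pelvis-velocity modes are supported:
#'
#' * `"follow_field"`: the pelvis follows the commanded-velocity field
#'   exactly (the velocity cost is identically zero) through the target
#'   scenario in `targets`; each target is placed `distance` metres ahead of
#'   the pelvis position at the moment it becomes current and must be held
#'   for `dwell` seconds.
#' * `"piecewise"`: piecewise-constant forward velocity, one value per
#'   scheduled footstep (recycled), with an optional zero-mean within-step
#'   oscillation of amplitude `oscillation` that alternates sign every
#'   control step (padded to an exactly zero sum); the target is parked far
#'   ahead so the commanded velocity is the constant `(speed, 0)`.
#'
#' @param duration Episode duration (s).
#' @param footsteps Vector of footstep durations (s), each >= 0.2 and below
#'   the forced-closure horizon; recycled to cover the episode, with any
#'   remainder forming a trailing partial step.
#' @param velocity_mode `"follow_field"` or `"piecewise"`.
#' @param speeds Forward speeds (m/s) per footstep for `"piecewise"`.
#' @param oscillation Zero-mean within-step speed oscillation amplitude
#'   (m/s) for `"piecewise"`.
#' @param activations Named vector of constant activation levels in
#'   `[0, 1]`; names are side-suffixed muscle names, unnamed muscles are 0.
#' @param targets List of `list(distance = , dwell = )` records for
#'   `"follow_field"`.
#' @param planar Use the 18-muscle activation set.
#' @param config A [reward_config()].
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(duration = 25, footsteps = 0.8,
                         velocity_mode = c("follow_field", "piecewise"),
                         speeds = NULL, oscillation = 0,
                         activations = NULL,
                         targets = list(list(distance = 3.5, dwell = 2.5),
                                        list(distance = 3.0, dwell = 2.0)),
                         planar = FALSE, config = reward_config()) {
  velocity_mode <- match.arg(velocity_mode)
  stopifnot(duration > 0, all(footsteps >= 0.2),
            all(footsteps < config$forced_closure), oscillation >= 0)
  if (length(targets) > config$n_targets) {
    stop("more targets than config$n_targets", call. = FALSE)
  }
  mus <- muscle_order(planar = planar)
  act <- stats::setNames(rep(0, length(mus)), mus)
  if (!is.null(activations)) {
    bad <- setdiff(names(activations), mus)
    if (length(bad) > 0) stop("unknown muscles: ", paste(bad, collapse = ", "),
                              call. = FALSE)
    act[names(activations)] <- activations
    stopifnot(all(act >= 0), all(act <= 1))
  }
  structure(list(duration = duration, footsteps = footsteps,
                 velocity_mode = velocity_mode, speeds = speeds,
                 oscillation = oscillation, activations = act,
                 targets = targets, planar = planar, config = config),
            class = "fixture_spec")
}

# expand the footstep schedule over the episode: durations of every step,
# the last possibly partial
expand_schedule <- function(spec) {
  dt <- spec$config$dt
  n <- round(spec$duration / dt)
  steps_rows <- integer(0)
  remaining <- n
  i <- 1
  while (remaining > 0) {
    rows <- min(round(spec$footsteps[(i - 1) %% length(spec$footsteps) + 1] / dt),
                remaining)
    steps_rows <- c(steps_rows, rows)
    remaining <- remaining - rows
    i <- i + 1
  }
  steps_rows
}

# per-row forward speed sequence for "piecewise" mode; the oscillation
# alternates +A, -A within each footstep and is zeroed on a trailing odd row
# so each step's added sum is exactly zero
piecewise_speeds <- function(spec, steps_rows) {
  speeds <- spec$speeds %||% spec$config$speed
  v <- numeric(0)
  for (k in seq_along(steps_rows)) {
    rows <- steps_rows[k]
    base <- rep(speeds[(k - 1) %% length(speeds) + 1], rows)
    if (spec$oscillation > 0 && rows >= 2) {
      osc <- rep(c(spec$oscillation, -spec$oscillation), length.out = rows)
      if (rows %% 2 == 1) osc[rows] <- 0
      base <- base + osc
    }
    v <- c(v, base)
  }
  v
}

#' Generate a fixture trajectory and its expected rewards
#'
#' Realises a [fixture_spec()] as a trajectory log (a tibble in the
#' [trajectory_columns()] schema) together with the expected
#' [episode_result()] computed by the closed-form evaluator.  Contact flags
#' encode the footstep schedule (the stepping foot alternates and is
#' airborne for 0.1 s before each scheduled touchdown); the model never
#' falls; time, velocities and target bookkeeping are exact realisations of
#' the spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `log` (tibble) and `expected` (an `episode_result`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  cfg <- spec$config
  dt <- cfg$dt
  n <- round(spec$duration / dt)
  steps_rows <- expand_schedule(spec)
  mus <- names(spec$activations)

  # contact flags realising the schedule: the stepping foot (alternating,
  # right first) is airborne for the swing_rows rows before each boundary
  swing_rows <- round(0.1 / dt)
  contact_r <- rep(1, n); contact_l <- rep(1, n)
  boundaries <- cumsum(steps_rows)
  for (k in seq_along(boundaries)) {
    b <- boundaries[k]
    if (b >= n) break                      # no touchdown needed at episode end
    lift <- max(1, b - swing_rows + 1)
    if (k %% 2 == 1) contact_r[lift:b] <- 0 else contact_l[lift:b] <- 0
  }
  # touchdown happens on the row after the airborne block
  # (detect_footstep_event sees prev=air, current=contact)

  pel <- matrix(0, n, 2); vel <- matrix(0, n, 2)
  tgt <- matrix(0, n, 2); tgt_idx <- integer(n); tgt_dwell <- numeric(n)

  if (spec$velocity_mode == "follow_field") {
    pos <- c(0, 0)
    ti <- 1
    cur <- if (length(spec$targets) >= 1) {
      list(loc = pos + c(spec$targets[[1]]$distance, 0),
           dwell = spec$targets[[1]]$dwell)
    } else list(loc = pos + c(1e6, 0), dwell = 1e6)
    dwell_clock <- 0
    for (i in seq_len(n)) {
      fld <- velocity_field(target = cur$loc, speed = cfg$speed,
                            proximity_radius = cfg$proximity_radius)
      v <- field_at(fld, pos)
      pel[i, ] <- pos; vel[i, ] <- v
      tgt[i, ] <- cur$loc; tgt_idx[i] <- ti; tgt_dwell[i] <- cur$dwell
      d <- sqrt(sum((pos - cur$loc)^2))
      dwell_clock <- if (d <= cfg$proximity_radius) dwell_clock + dt else 0
      if (dwell_clock >= cur$dwell && ti < length(spec$targets)) {
        ti <- ti + 1
        cur <- list(loc = pos + c(spec$targets[[ti]]$distance, 0),
                    dwell = spec$targets[[ti]]$dwell)
        dwell_clock <- 0
      }
      pos <- pos + v * dt
    }
  } else {
    vseq <- piecewise_speeds(spec, steps_rows)
    far <- c(1e6, 0)
    x <- 0
    for (i in seq_len(n)) {
      pel[i, ] <- c(x, 0); vel[i, ] <- c(vseq[i], 0)
      tgt[i, ] <- far; tgt_idx[i] <- 1L; tgt_dwell[i] <- 1e6
      x <- x + vseq[i] * dt
    }
  }

  log <- tibble::tibble(
    time = (seq_len(n) - 1) * dt,
    pel_x = pel[, 1], pel_lat = pel[, 2],
    pel_height = 0.94, pel_pitch = 0,
    v_x = vel[, 1], v_lat = vel[, 2],
    hip_r = 0, knee_r = 0, ankle_r = 0, hip_l = 0, knee_l = 0, ankle_l = 0,
    dhip_r = 0, dknee_r = 0, dankle_r = 0,
    dhip_l = 0, dknee_l = 0, dankle_l = 0,
    contact_r = contact_r, contact_l = contact_l)
  for (m in mus) log[[paste0("act_", m)]] <- spec$activations[[m]]
  log$tgt_x <- tgt[, 1]; log$tgt_lat <- tgt[, 2]
  log$tgt_index <- tgt_idx; log$tgt_dwell <- tgt_dwell

  list(log = log, expected = fixture_expected(spec, steps_rows, log))
}

# Closed-form expected rewards: literal transcription of
#   J = sum b_alive + sum_steps (w_s b_s - w_v c_v - w_e c_e) + sum b_target
# over the spec's piecewise segments.  Independent of the ledger/event code.
fixture_expected <- function(spec, steps_rows, log) {
  cfg <- spec$config
  dt <- cfg$dt
  n <- sum(steps_rows)
  r_alive <- cfg$b_alive * n

  effort_rate <- sum(spec$activations^2)     # per second
  if (spec$velocity_mode == "follow_field") {
    cv <- rep(0, length(steps_rows))         # exact field following
  } else {
    vseq <- piecewise_speeds(spec, steps_rows)
    ends <- cumsum(steps_rows)
    starts <- c(1, utils::head(ends, -1) + 1)
    cv <- vapply(seq_along(steps_rows), function(k) {
      err <- sum(vseq[starts[k]:ends[k]] - cfg$speed) * dt
      abs(err)                               # lateral error is identically 0
    }, numeric(1))
  }
  b_s <- steps_rows * dt
  step_rewards <- cfg$w_s * b_s - cfg$w_v * cv - cfg$w_e * effort_rate * b_s
  r_step <- sum(step_rewards)

  n_awarded <- if (spec$velocity_mode == "follow_field") {
    sum(target_award_rows(spec) <= n)
  } else 0
  r_target <- cfg$b_target * n_awarded

  episode_result(r_alive, r_step, r_target,
                 reward_trace = numeric(0), n_steps = n,
                 targets_reached = n_awarded, fallen = FALSE)
}

# Row index at which each target of a follow-field scenario is awarded:
# the pelvis closes on the target at full speed until within the proximity
# radius (discrete rows), then dwells; replicates the discrete-time
# construction, not the scorer.
target_award_rows <- function(spec) {
  cfg <- spec$config
  dt <- cfg$dt
  rows <- integer(0)
  row <- 0
  for (t in spec$targets) {
    d <- t$distance
    # rows spent approaching until distance <= proximity radius
    approach <- ceiling(max(0, d - cfg$proximity_radius) / (cfg$speed * dt) - 1e-9)
    dwell_rows <- ceiling(t$dwell / dt - 1e-9)
    row <- row + approach + dwell_rows
    rows <- c(rows, row)
  }
  rows
}
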