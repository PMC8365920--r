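# Target bookkeeping and the commanded-velocity field.
#
# The field points from the query position toward the current target with the
# commanded walking speed, tapering linearly to zero inside the proximity
# radius so that stopping and standing at the target is optimal.  An 11 x 11
# body-frame grid sample of the field (242 numbers: all forward components,
# then all lateral components) is part of the observation.

#' Target specification
#'
#' @param index Target index within the episode (1-based).
#' @param location Target position in the ground plane (m, 2-vector).
#' @param required_dwell Time (s) the pelvis must stay within the proximity
#'   radius for the bonus to be awarded.
#' @return A list of class `target_spec` with an `awarded` flag and a dwell
#'   clock (`dwell`).
#' @export
target_spec <- function(index, location, required_dwell) {
  stopifnot(length(location) == 2, required_dwell > 0)
  structure(list(index = as.integer(index), location = as.numeric(location),
                 required_dwell = required_dwell, dwell = 0, awarded = FALSE),
            class = "target_spec")
}

#' Sample a new target
#'
#' Targets are drawn uniformly from an annulus around the current pelvis
#' position with the required dwell drawn uniformly from the configured
#' dwell range; deterministic under a fixed RNG state.
#'
#' @param pelvis_position Current pelvis ground-plane position (m, 2-vector).
#' @param index Index of the new target.
#' @param config A [reward_config()].
#' @param annulus Radial bounds (m) of the sampling annulus.
#' @param angle_range Angular bounds (rad) of the sampling sector; the
#'   default samples only straight ahead (+x), matching the sagittal-plane
#'   walker which cannot turn.
#' @return A `target_spec`.
#' @export
sample_target <- function(pelvis_position, index, config = reward_config(),
                          annulus = c(2, 6), angle_range = c(0, 0)) {
  stopifnot(annulus[1] > 0, annulus[2] >= annulus[1])
  r <- stats::runif(1, annulus[1], annulus[2])
  ang <- stats::runif(1, angle_range[1], angle_range[2])
  dwell <- stats::runif(1, config$dwell_range[1], config$dwell_range[2])
  target_spec(index, pelvis_position + r * c(cos(ang), sin(ang)), dwell)
}

#' Update a target's dwell clock and award its bonus
#'
#' The dwell clock accrues while the pelvis stays within the proximity
#' radius of the target and resets when it leaves.  Once the accrued dwell
#' reaches the required dwell, the target bonus is awarded exactly once and
#' the episode should advance to the next target.
#'
#' @param spec A `target_spec` (not yet awarded).
#' @param pelvis_position Pelvis ground-plane position (m, 2-vector).
#' @param dt Time step (s).
#' @param config A [reward_config()].
#' @return List with `bonus` (0 or `b_target`), `spec` (updated) and
#'   `advance` (should the episode move to the next target?).
#' @export
update_target <- function(spec, pelvis_position, dt, config = reward_config()) {
  stopifnot(inherits(spec, "target_spec"))
  if (spec$awarded) stop("target already awarded", call. = FALSE)
  d <- sqrt(sum((pelvis_position - spec$location)^2))
  if (d <= config$proximity_radius) {
    spec$dwell <- spec$dwell + dt
  } else {
    spec$dwell <- 0
  }
  if (spec$dwell >= spec$required_dwell) {
    spec$awarded <- TRUE
    return(list(bonus = config$b_target, spec = spec, advance = TRUE))
  }
  list(bonus = 0, spec = spec, advance = FALSE)
}

#' Commanded-velocity field
#'
#' Either a target-seeking field (vectors point from the query position
#' toward `target`, magnitude equal to the commanded speed outside the
#' proximity radius and tapering linearly to zero inside it) or a uniform
#' field with a constant vector (useful for fixtures and tests).
#'
#' @param target Target ground-plane position (2-vector), or `NULL` for a
#'   uniform field.
#' @param speed Commanded speed (m/s).
#' @param uniform Constant field vector when `target` is `NULL`.
#' @param proximity_radius Taper radius (m).
#' @param grid_n Grid points per side of the local map (default 11).
#' @param grid_spacing Local-map grid spacing (m, default 0.5).
#' @return A list of class `velocity_field`.
#' @export
velocity_field <- function(target = NULL, speed = 1.4, uniform = c(0, 0),
                           proximity_radius = 0.3, grid_n = 11,
                           grid_spacing = 0.5) {
  stopifnot(speed >= 0, proximity_radius > 0, grid_n >= 1, grid_spacing > 0)
  structure(list(target = target, speed = speed, uniform = uniform,
                 proximity_radius = proximity_radius, grid_n = grid_n,
                 grid_spacing = grid_spacing),
            class = "velocity_field")
}

#' Evaluate the commanded-velocity field at a point
#'
#' @param field A [velocity_field()].
#' @param position Ground-plane query position (m, 2-vector).
#' @return Commanded velocity (m/s, 2-vector).
#' @export
field_at <- function(field, position) {
  stopifnot(inherits(field, "velocity_field"), length(position) == 2)
  if (is.null(field$target)) return(as.numeric(field$uniform))
  v <- field$target - position
  d <- sqrt(sum(v^2))
  if (d == 0) return(c(0, 0))
  mag <- if (d >= field$proximity_radius) field$speed else
    field$speed * d / field$proximity_radius
  v / d * mag
}

#' Local target-velocity map
#'
#' Samples the commanded-velocity field on an 11 x 11 grid centred on the
#' pelvis in the body-heading frame and flattens it to a 242-vector: the 121
#' forward components first, then the 121 lateral components, each block
#' ordered row-major (lateral offset varying slowest, forward offset
#' fastest).  The centre cell equals the commanded velocity `v_tgt0` used by
#' the reward.
#'
#' @param field A [velocity_field()].
#' @param pelvis_position Pelvis ground-plane position (m, 2-vector).
#' @param heading Body heading (rad); 0 for the sagittal-plane walker.
#' @return Numeric vector of length `2 * grid_n^2` (242 for the default
#'   grid).
#' @export
local_velocity_map <- function(field, pelvis_position, heading = 0) {
  stopifnot(inherits(field, "velocity_field"))
  n <- field$grid_n
  half <- (n - 1) / 2
  offs <- (seq_len(n) - 1 - half) * field$grid_spacing
  ch <- cos(heading); sh <- sin(heading)
  # grid points, row-major: lateral offset (rows) slowest, forward fastest
  fo <- rep(offs, times = n)          # forward offset per point
  lo <- rep(offs, each = n)           # lateral offset per point
  wx <- pelvis_position[1] + ch * fo - sh * lo
  wy <- pelvis_position[2] + sh * fo + ch * lo
  if (is.null(field$target)) {
    vx <- rep(field$uniform[1], n * n)
    vy <- rep(field$uniform[2], n * n)
  } else {
    dx <- field$target[1] - wx
    dy <- field$target[2] - wy
    d <- sqrt(dx^2 + dy^2)
    mag <- ifelse(d >= field$proximity_radius, field$speed,
                  field$speed * d / field$proximity_radius)
    scl <- ifelse(d == 0, 0, mag / pmax(d, .Machine$double.xmin))
    vx <- dx * scl
    vy <- dy * scl
  }
  # rotate into the body-heading frame
  c(ch * vx + sh * vy, -sh * vx + ch * vy)
}
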