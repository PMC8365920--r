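# Model configuration: segments, joints, contact spheres and muscle paths of
# the planar 7-segment walker, plus the translation into the parameter list
# consumed by the compiled dynamics core.
#
# Body order: pelvis+trunk (floating base), right thigh/shank/foot, left
# thigh/shank/foot.  Generalized coordinates:
#   q = (pelvis_x, pelvis_y, pelvis_pitch,
#        hip_r, knee_r, ankle_r, hip_l, knee_l, ankle_l)
# with hip flexion positive, knee flexion negative (0 = straight) and ankle
# dorsiflexion positive (0 = foot flat).  All angles are relative to the
# parent segment; the neutral standing pose is q = 0.

#' Default walker model configuration
#'
#' Anthropometry for a ~75 kg, ~1.80 m adult from standard segment-parameter
#' tables: a combined head-arms-trunk-pelvis segment and thigh, shank and
#' foot segments per leg, three ground-contact spheres per foot, soft joint
#' limits, and the 22 side-suffixed Hill muscles with constant moment arms
#' (affine path model) calibrated so that every MTU sits at its optimal CE
#' length in the neutral standing pose.
#'
#' @return A nested list of class `walker_config` (segments, joints, contact,
#'   muscles, simulation defaults).  Serialisable to YAML with
#'   [write_model_config()].
#' @export
default_walker_config <- function() {
  # Moment arms are constant (affine path model); optimal CE lengths are
  # chosen so normalized CE excursions over the walking range of each joint
  # stay moderate under the rigid tendon.
  leg_muscles <- list(
    #       f_max l_opt v_max l_slack   r_hip  r_knee r_ankle
    HAB  = c(3000, 0.09, 12, 0.13,  0.00,  0.00,  0.00),
    HAD  = c(4500, 0.10, 12, 0.17,  0.00,  0.00,  0.00),
    HFL  = c(2000, 0.12, 12, 0.10,  0.05,  0.00,  0.00),
    GLU  = c(1500, 0.12, 12, 0.13, -0.05,  0.00,  0.00),
    HAM  = c(3000, 0.12, 12, 0.31, -0.06, -0.03,  0.00),
    RF   = c(1200, 0.12, 12, 0.35,  0.05,  0.03,  0.00),
    VAS  = c(6000, 0.10, 12, 0.23,  0.00,  0.03,  0.00),
    BFSH = c( 350, 0.10, 12, 0.10,  0.00, -0.03,  0.00),
    GAS  = c(1500, 0.08, 12, 0.40,  0.00, -0.02, -0.05),
    SOL  = c(4000, 0.06,  6, 0.26,  0.00,  0.00, -0.05),
    TA   = c( 800, 0.06, 12, 0.24,  0.00,  0.00,  0.04))
  muscles <- list()
  for (side in c("R", "L")) {
    for (nm in names(leg_muscles)) {
      v <- leg_muscles[[nm]]
      muscles[[paste0(nm, "_", side)]] <- list(
        f_max = v[1], l_opt = v[2], v_max = v[3], l_slack = v[4],
        tau_act = 0.015, tau_deact = 0.05, fv_ecc_plateau = 1.5,
        moment_arm = list(hip = v[5], knee = v[6], ankle = v[7]))
    }
  }
  structure(list(
    schema = "gaitenv-model-1",
    gravity = 9.80665,
    segments = list(
      pelvis = list(mass = 50.8, inertia = 3.0, com = c(0.0, 0.30)),
      thigh  = list(mass = 7.5, inertia = 0.135, length = 0.44,
                    com = c(0.0, -0.19)),
      shank  = list(mass = 3.5, inertia = 0.058, length = 0.43,
                    com = c(0.0, -0.19)),
      foot   = list(mass = 1.2, inertia = 0.007, com = c(0.06, -0.04))),
    joints = list(
      hip   = list(limits = c(-0.87, 2.09), stiffness = 300, damping = 30),
      knee  = list(limits = c(-2.40, 0.02), stiffness = 300, damping = 30),
      ankle = list(limits = c(-0.90, 0.70), stiffness = 300, damping = 30)),
    contact = list(
      stiffness = 1.2e6, exponent = 1.5, damping = 1.0,
      friction_mu = 0.8, friction_vsmooth = 0.05,
      spheres = list(
        heel = list(pos = c(-0.070, -0.05), radius = 0.025),
        mid  = list(pos = c( 0.055, -0.05), radius = 0.025),
        toe  = list(pos = c( 0.180, -0.05), radius = 0.025))),
    muscles = muscles,
    simulation = list(dt = 0.01, substeps = 10, init_height = 0.9428)),
    class = "walker_config")
}

#' Read / write a model configuration file
#'
#' The model configuration is stored as YAML: one `segments`/`joints`/
#' `contact` block and one muscle record per side-suffixed muscle name.
#'
#' @param path File path.
#' @return `read_model_config()` returns a `walker_config` list;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || !identical(cfg$schema, "gaitenv-model-1")) {
    stop("not a gaitenv model config (missing schema 'gaitenv-model-1'): ",
         path, call. = FALSE)
  }
  for (k in c("segments", "joints", "contact", "muscles")) {
    if (is.null(cfg[[k]])) stop("model config missing block: ", k, call. = FALSE)
  }
  class(cfg) <- "walker_config"
  cfg
}

#' @rdname read_model_config
#' @param config A `walker_config` list.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' Canonical muscle order of a configuration
#'
#' @param config A `walker_config` list.
#' @param planar Drop HAB/HAD (the frontal-plane muscles)?
#' @return Character vector of side-suffixed muscle names, right leg first.
#' @export
muscle_order <- function(config = default_walker_config(), planar = FALSE) {
  nm <- names(config$muscles)
  if (planar) nm <- nm[!grepl("^(HAB|HAD)_", nm)]
  nm
}

# Build the flat parameter list consumed by the compiled planar-tree core.
# Muscles are restricted to those with non-zero moment arms (the frontal
# plane muscles HAB/HAD have none and are handled outside the dynamics).
build_core_params <- function(config) {
  seg <- config$segments
  lth <- seg$thigh$length; lsh <- seg$shank$length
  parent <- c(-1L, 0L, 1L, 2L, 0L, 4L, 5L)
  jpos <- rbind(c(0, 0),                 # pelvis (unused)
                c(0, 0), c(0, -lth), c(0, -lsh),   # right hip/knee/ankle
                c(0, 0), c(0, -lth), c(0, -lsh))   # left hip/knee/ankle
  com <- rbind(seg$pelvis$com,
               seg$thigh$com, seg$shank$com, seg$foot$com,
               seg$thigh$com, seg$shank$com, seg$foot$com)
  mass <- c(seg$pelvis$mass, seg$thigh$mass, seg$shank$mass, seg$foot$mass,
            seg$thigh$mass, seg$shank$mass, seg$foot$mass)
  inertia <- c(seg$pelvis$inertia, seg$thigh$inertia, seg$shank$inertia,
               seg$foot$inertia, seg$thigh$inertia, seg$shank$inertia,
               seg$foot$inertia)
  stopifnot(length(mass) == 7, all(mass > 0), all(inertia > 0))

  sph <- config$contact$spheres
  stopifnot(length(sph) == 3)
  cpos <- do.call(rbind, lapply(sph, function(s) s$pos))
  crad <- vapply(sph, function(s) s$radius, numeric(1))
  contact_body <- c(rep(3L, 3), rep(6L, 3))        # right foot, left foot
  contact_pos <- rbind(cpos, cpos)
  contact_radius <- c(crad, crad)

  jl <- function(j) c(config$joints[[j]]$limits, config$joints[[j]]$stiffness,
                      config$joints[[j]]$damping)
  joint_limits <- rbind(jl("hip"), jl("knee"), jl("ankle"),
                        jl("hip"), jl("knee"), jl("ankle"))

  mech <- muscle_order(config, planar = TRUE)
  nm <- length(mech)
  marm <- matrix(0, nm, 6)
  get <- function(x, f) unname(vapply(config$muscles[x],
                                      function(m) m[[f]], numeric(1)))
  for (i in seq_along(mech)) {
    m <- config$muscles[[mech[i]]]
    right <- grepl("_R$", mech[i])
    cols <- if (right) 1:3 else 4:6
    marm[i, cols] <- c(m$moment_arm$hip, m$moment_arm$knee, m$moment_arm$ankle)
  }
  l_opt <- get(mech, "l_opt"); l_slack <- get(mech, "l_slack")

  list(parent = parent, jpos = jpos, com = com, mass = mass, inertia = inertia,
       gravity = config$gravity, base_fixed = FALSE,
       contact_body = contact_body, contact_pos = contact_pos,
       contact_radius = contact_radius,
       contact_stiffness = config$contact$stiffness,
       contact_exponent = config$contact$exponent,
       contact_damping = config$contact$damping,
       friction_mu = config$contact$friction_mu,
       friction_vsmooth = config$contact$friction_vsmooth,
       joint_limits = joint_limits,
       mus_fmax = get(mech, "f_max"), mus_lopt = l_opt,
       mus_vmax = get(mech, "v_max"), mus_lslack = l_slack,
       mus_tact = get(mech, "tau_act"), mus_tdeact = get(mech, "tau_deact"),
       mus_fvplateau = get(mech, "fv_ecc_plateau"),
       mus_L0 = l_slack + l_opt,          # neutral-pose calibration
       mus_moment_arm = marm, q_neutral = rep(0, 6),
       mus_names = mech)
}

#' Initial standing body state
#'
#' Static standing at the origin: neutral joint angles, zero velocities, feet
#' flat on the ground with a sub-millimetre static contact penetration so the
#' model starts in (approximate) load-bearing equilibrium.
#'
#' @param config A `walker_config` list.
#' @param forward_speed Optional initial forward pelvis speed (m/s); useful
#'   for gait initiation with the reflex baseline.
#' @return List of class `body_state` with `q`, `qd`, `act` (one per
#'   sagittal-plane muscle), `time`.
#' @export
initial_state <- function(config = default_walker_config(), forward_speed = 0) {
  core <- build_core_params(config)
  q <- c(0, config$simulation$init_height, 0, rep(0, 6))
  qd <- c(forward_speed, rep(0, 8))
  structure(list(q = q, qd = qd, act = rep(0, length(core$mus_fmax)), time = 0),
            class = "body_state")
}
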