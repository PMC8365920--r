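# Planar articulated rigid-body dynamics: R surface over the compiled core.
# The same generic kinematic-tree engine drives both the walker and the small
# closed-form oracle systems used in the tests (pendula, projectiles).

#' Generic planar kinematic-tree parameters
#'
#' Low-level constructor for the parameter list consumed by the dynamics
#' core: a floating (or fixed) planar base plus a chain/tree of revolute
#' joints, optional ground-contact spheres and optional Hill muscles.  The
#' walker model is one instance of this structure (see
#' [build_core_params()] via [default_walker_config()]); simple systems such
#' as pendula can be built directly for verification against closed forms.
#'
#' @param parent Integer vector of parent body indices (0-based, -1 for the
#'   base); bodies must be topologically ordered.
#' @param jpos n x 2 matrix: joint position in the parent frame.
#' @param com n x 2 matrix: centre of mass in the body frame.
#' @param mass,inertia Per-body mass (kg) and rotational inertia about the
#'   COM (kg m^2).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param base_fixed If `TRUE` the base is welded to the world (its three
#'   coordinates are held at their initial values).
#' @param ... Further entries merged into the parameter list (contact and
#'   muscle blocks following the naming used by [build_core_params()]).
#' @return A parameter list for the compiled core.
#' @export
planar_tree_params <- function(parent, jpos, com, mass, inertia,
                               gravity = 9.80665, base_fixed = FALSE, ...) {
  stopifnot(length(mass) == length(parent), length(inertia) == length(parent),
            nrow(jpos) == length(parent), nrow(com) == length(parent),
            all(mass > 0), all(inertia > 0))
  c(list(parent = as.integer(parent), jpos = jpos, com = com,
         mass = mass, inertia = inertia, gravity = gravity,
         base_fixed = base_fixed),
    list(...))
}

#' Joint-space mass matrix
#'
#' Assembles `M(q)` from point Jacobians: symmetric positive-definite for
#' valid inertial parameters.
#'
#' @param q Generalized coordinates.
#' @param params Core parameter list (from [planar_tree_params()] or
#'   [build_core_params()]).
#' @return ndof x ndof matrix.
#' @export
mass_matrix <- function(q, params) .pt_mass_matrix(q, params)

#' Forward dynamics
#'
#' Solves `M(q) qddot = Q(q, qdot, tau, forces)` where `Q` collects gravity,
#' velocity-product terms, joint torques and external point forces.  A
#' numerically singular mass matrix raises a hard failure (invalid inertial
#' parameters).
#'
#' @param q,qd Generalized coordinates and velocities.
#' @param tau_joint Torque per revolute joint (N m); defaults to zeros.
#' @param ext_forces Matrix with rows `(body, px_local, py_local, fx, fy)`
#'   of world-frame point forces, or `NULL`.
#' @param params Core parameter list.
#' @param with_contact,with_limits Include ground-contact forces / soft
#'   joint-limit torques.
#' @return Vector of generalized accelerations.
#' @export
forward_dynamics <- function(q, qd, tau_joint = NULL, ext_forces = NULL,
                             params, with_contact = FALSE, with_limits = FALSE) {
  njoint <- length(params$parent) - 1
  if (is.null(tau_joint)) tau_joint <- rep(0, njoint)
  if (is.null(ext_forces)) ext_forces <- matrix(0, 0, 5)
  stopifnot(all(is.finite(q)), all(is.finite(qd)), all(is.finite(tau_joint)))
  as.numeric(.pt_forward_dynamics(q, qd, tau_joint, ext_forces, params,
                                  with_contact, with_limits))
}

#' Ground-contact forces
#'
#' Nonlinear spring-damper normal law (Hunt-Crossley style,
#' `N = k d^p (1 + b ddot)`, floored at zero so there is no adhesion) with
#' smoothed Coulomb friction `Ft = -mu N tanh(v / v_smooth)`.
#'
#' @param q,qd Generalized coordinates and velocities.
#' @param params Core parameter list with a contact block.
#' @return Tibble with one row per sphere: `fx`, `fy` (world frame, N),
#'   `penetration` (m) and `in_contact`.
#' @export
contact_forces <- function(q, qd, params) {
  cf <- .pt_contact_forces(q, qd, params)
  tibble::tibble(sphere = seq_len(nrow(cf)),
                 body = params$contact_body[seq_len(nrow(cf))],
                 fx = cf[, 1], fy = cf[, 2], penetration = cf[, 3],
                 in_contact = cf[, 3] > 0)
}

#' Muscle path geometry
#'
#' Affine muscle path model: MTU length
#' `L_m = L0_m - sum_j r_mj (q_j - q_neutral_j)` with constant moment arms
#' `r_mj`, so MTU velocity is the exact time derivative
#' `-sum_j r_mj qdot_j`.  Biarticular muscles (HAM, RF, GAS) span two joints.
#'
#' @param q,qd Generalized coordinates and velocities.
#' @param params Core parameter list with a muscle block.
#' @return Tibble with one row per muscle: `muscle`, `length` (m),
#'   `velocity` (m/s), `lce_norm`, `vce_norm`.
#' @export
muscle_geometry <- function(q, qd, params) {
  g <- .pt_muscle_geometry(q, qd, params)
  tibble::tibble(muscle = params$mus_names %||% as.character(seq_along(g$length)),
                 length = as.numeric(g$length),
                 velocity = as.numeric(g$velocity),
                 lce_norm = as.numeric(g$lce_norm),
                 vce_norm = as.numeric(g$vce_norm))
}

#' Mechanical energy of the tree
#'
#' Kinetic plus gravitational potential energy; used by the conservation
#' oracles in the tests.
#'
#' @inheritParams mass_matrix
#' @param qd Generalized velocities.
#' @return List with `kinetic`, `potential`, `total` (J).
#' @export
tree_energy <- function(q, qd, params) .pt_energy(q, qd, params)

#' Body kinematics
#'
#' Per-body orientation, angular velocity, joint and COM positions and
#' velocities in the world frame.
#'
#' @inheritParams tree_energy
#' @return List of matrices/vectors (`phi`, `omega`, `p_ref`, `v_ref`,
#'   `p_com`, `v_com`).
#' @export
tree_kinematics <- function(q, qd, params) .pt_kinematics(q, qd, params)

#' Advance the neuromusculoskeletal state by one control step
#'
#' Semi-implicit Euler sub-stepping: each sub-step advances the first-order
#' activation dynamics (exact exponential update), evaluates Hill muscle
#' forces, maps them to joint moments through the constant moment arms, adds
#' ground contact and joint-limit torques, solves the forward dynamics and
#' integrates.  Deterministic given identical inputs.
#'
#' @param state A `body_state` list (`q`, `qd`, `act`, `time`).
#' @param excitations Muscle excitation vector in `[0, 1]` (values outside
#'   are clamped; non-finite entries are a hard failure).
#' @param params Core parameter list with muscle and contact blocks.
#' @param dt Control time step (s), default 0.01.
#' @param substeps Integration sub-steps per control step, >= 1.
#' @return Updated `body_state` with an `info` attribute carrying muscle
#'   forces/lengths/velocities, per-sphere contact forces and flags.
#' @export
integrate_step <- function(state, excitations, params, dt = 0.01, substeps = 10) {
  stopifnot(substeps >= 1, dt > 0)
  out <- .pt_step(state, params, excitations, dt, as.integer(substeps))
  new_state <- structure(list(q = as.numeric(out$q), qd = as.numeric(out$qd),
                              act = as.numeric(out$act), time = out$time),
                         class = "body_state")
  info <- out[setdiff(names(out), c("q", "qd", "act", "time"))]
  for (nm in c("mus_force", "mus_length", "mus_velocity", "mus_lce_norm",
               "mus_vce_norm")) info[[nm]] <- as.numeric(info[[nm]])
  attr(new_state, "info") <- info
  new_state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
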