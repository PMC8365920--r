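# Hill-type muscle-tendon unit: excitation -> activation dynamics, active and
# passive force generation, and the activation-squared effort integrand.

# Curve constants shared with the compiled fast path (src/dynamics.cpp).
.fl_width <- 0.30   # Gaussian width of the active force-length bell
.fv_curv <- 0.25    # concentric curvature constant of the force-velocity hyperbola
.fp_scale <- 1.00   # passive force reaches 1 at l_ce_norm = 1 + .fp_scale

#' Muscle-tendon unit parameters
#'
#' Builds a validated parameter record for one Hill-type muscle-tendon unit
#' (MTU).  The model is the classic three-element arrangement: an active
#' contractile element (CE) whose force scales with activation and with
#' length- and velocity-dependent factors, a parallel elastic element, and a
#' series elastic element treated as rigid at its slack length by default.
#'
#' @param name Muscle name, one of the eleven per-leg muscles
#'   (HAB, HAD, HFL, GLU, HAM, RF, VAS, BFSH, GAS, SOL, TA) with an `_R` or
#'   `_L` side suffix, e.g. `"SOL_R"`.
#' @param f_max Maximum isometric force (N), > 0.
#' @param l_opt Optimal CE length (m), > 0.
#' @param v_max Maximum shortening velocity in optimal lengths per second, > 0.
#' @param l_slack Series-element slack length (m), >= 0.
#' @param tau_act Activation time constant (s).
#' @param tau_deact Deactivation time constant (s), >= `tau_act`.
#' @param fv_ecc_plateau Eccentric force plateau (dimensionless), >= 1.
#' @return A list of class `muscle_params`.
#' @export
muscle_params <- function(name, f_max, l_opt, v_max, l_slack,
                          tau_act = 0.015, tau_deact = 0.05,
                          fv_ecc_plateau = 1.5) {
  stopifnot(is.character(name), length(name) == 1)
  base <- sub("_[RL]$", "", name)
  if (!base %in% muscle_names_per_leg()) {
    stop("unknown muscle name: ", name, call. = FALSE)
  }
  if (f_max <= 0 || l_opt <= 0 || v_max <= 0 || l_slack < 0) {
    stop("f_max, l_opt, v_max must be > 0 and l_slack >= 0", call. = FALSE)
  }
  if (tau_act <= 0 || tau_deact < tau_act) {
    stop("need 0 < tau_act <= tau_deact", call. = FALSE)
  }
  if (fv_ecc_plateau < 1) stop("fv_ecc_plateau must be >= 1", call. = FALSE)
  structure(
    list(name = name, f_max = f_max, l_opt = l_opt, v_max = v_max,
         l_slack = l_slack, tau_act = tau_act, tau_deact = tau_deact,
         fv_ecc_plateau = fv_ecc_plateau),
    class = "muscle_params")
}

#' Per-leg muscle names
#'
#' The eleven muscles actuating each leg, in the canonical action/observation
#' order: hip abductor (HAB), hip adductor (HAD), hip flexor (HFL), glutei
#' (GLU), hamstrings (HAM, biarticular), rectus femoris (RF, biarticular),
#' vastii (VAS), short head of biceps femoris (BFSH), gastrocnemius (GAS,
#' biarticular), soleus (SOL) and tibialis anterior (TA).
#'
#' @param planar If `TRUE`, drop the two frontal-plane muscles (HAB, HAD)
#'   that have no mechanical action in the sagittal-plane core.
#' @return Character vector of muscle names.
#' @export
muscle_names_per_leg <- function(planar = FALSE) {
  nm <- c("HAB", "HAD", "HFL", "GLU", "HAM", "RF", "VAS", "BFSH",
          "GAS", "SOL", "TA")
  if (planar) setdiff(nm, c("HAB", "HAD")) else nm
}

#' Advance muscle activation by one time step
#'
#' First-order excitation-to-activation dynamics, integrated exactly over the
#' step: `a' = u + (a - u) exp(-dt / tau)` with `tau = tau_act` when the
#' excitation exceeds the activation and `tau_deact` otherwise.  Excitations
#' outside `[0, 1]` are clamped (RL agents emit unconstrained outputs); the
#' clamping is reported through the `clamped` attribute.
#'
#' @param excitation Neural excitation in `[0, 1]` (values outside are clamped).
#' @param activation Current activation in `[0, 1]`.
#' @param dt Time step (s), > 0.
#' @param params A [muscle_params()] record.
#' @return New activation in `[0, 1]`, with attribute `clamped`.
#' @export
activation_step <- function(excitation, activation, dt, params) {
  stopifnot(dt > 0)
  clamped <- excitation < 0 || excitation > 1
  u <- min(max(excitation, 0), 1)
  a <- min(max(activation, 0), 1)
  tau <- if (u >= a) params$tau_act else params$tau_deact
  out <- u + (a - u) * exp(-dt / tau)
  structure(min(max(out, 0), 1), clamped = clamped)
}

#' Active force-length factor
#'
#' Gaussian bell centred on the optimal CE length:
#' `exp(-((l - 1) / w)^2)` with width `w = 0.30`.
#'
#' @param l_ce_norm CE length normalised by `l_opt`, > 0.
#' @return Factor in `[0, 1]`, maximal at `l_ce_norm = 1`.
#' @export
force_length_active <- function(l_ce_norm) {
  exp(-((l_ce_norm - 1) / .fl_width)^2)
}

#' Force-velocity factor
#'
#' Hyperbolic Hill curve for shortening (`v < 0`), saturating eccentric branch
#' for lengthening (`v > 0`), C1-continuous at the isometric point.  Equals 0
#' at the maximum shortening velocity (`v = -1`), 1 at `v = 0`, and approaches
#' `fv_ecc_plateau` for fast lengthening.
#'
#' @param v_ce_norm CE velocity normalised by the maximum shortening velocity
#'   (shortening negative).
#' @param fv_ecc_plateau Eccentric plateau, >= 1.
#' @return Dimensionless factor, monotone non-decreasing in `v_ce_norm`.
#' @export
force_velocity <- function(v_ce_norm, fv_ecc_plateau = 1.5) {
  vapply(v_ce_norm, function(v) {
    if (v <= -1) return(0)
    if (v < 0) return((1 + v) / (1 - v / .fv_curv))
    slope0 <- 1 + 1 / .fv_curv
    ke <- (fv_ecc_plateau - 1) / slope0
    if (ke == 0) return(1)
    fv_ecc_plateau - (fv_ecc_plateau - 1) / (1 + v / ke)
  }, numeric(1))
}

#' Passive force-length factor
#'
#' Quadratic parallel-elastic curve engaging at the optimal CE length:
#' zero at or below `l_ce_norm = 1`, then `((l - 1) / w)^2` with `w = 1`.
#'
#' @param l_ce_norm CE length normalised by `l_opt`, > 0.
#' @return Non-negative factor, strictly increasing above engagement.
#' @export
force_passive <- function(l_ce_norm) {
  ifelse(l_ce_norm <= 1, 0, ((l_ce_norm - 1) / .fp_scale)^2)
}

#' Muscle-tendon unit force (rigid tendon)
#'
#' Composes the scalar Hill curves under the rigid-tendon simplification
#' (CE length = MTU length minus the series-element slack length):
#' `F = f_max * (a * fl(l) * fv(v) + fp(l))`, floored at zero.
#'
#' @param state List with elements `activation` (in `[0, 1]`).
#' @param mtu_length MTU length (m), > 0.
#' @param mtu_velocity MTU lengthening velocity (m/s).
#' @param params A [muscle_params()] record.
#' @return List of class `muscle_state` with `activation`, `l_ce_norm`,
#'   `v_ce_norm`, `force` (N) and a `degenerate` flag set when the CE length
#'   is non-positive (geometry misconfiguration; passive-only floor of zero).
#' @export
mtu_force <- function(state, mtu_length, mtu_velocity, params) {
  stopifnot(mtu_length > 0)
  a <- min(max(state$activation, 0), 1)
  l_ce <- (mtu_length - params$l_slack) / params$l_opt
  v_ce <- (mtu_velocity / params$l_opt) / params$v_max
  if (l_ce <= 0) {
    return(structure(list(activation = a, l_ce_norm = l_ce, v_ce_norm = v_ce,
                          force = 0, degenerate = TRUE),
                     class = "muscle_state"))
  }
  f <- params$f_max *
    (a * force_length_active(l_ce) * force_velocity(v_ce, params$fv_ecc_plateau) +
       force_passive(l_ce))
  structure(list(activation = a, l_ce_norm = l_ce, v_ce_norm = v_ce,
                 force = max(f, 0), degenerate = FALSE),
            class = "muscle_state")
}

#' Effort-cost increment
#'
#' One time-step increment of the effort cost: the time integral of summed
#' squared activations, `dt * sum(A_m^2)`.  Squared activation integrated
#' over time is a standard proxy for muscle fatigue.
#'
#' @param activations Vector of muscle activations in `[0, 1]`.
#' @param dt Time step (s), > 0.
#' @return Non-negative scalar increment (activation^2 * s).
#' @export
effort_increment <- function(activations, dt) {
  stopifnot(dt > 0, all(activations >= 0), all(activations <= 1))
  dt * sum(activations^2)
}
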