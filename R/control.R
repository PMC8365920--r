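# Non-learned baseline policies: a standing controller and a parameterized
# reflex-style gait controller (stance/swing finite-state machine per leg,
# force-/length-/contact-triggered feedback laws), plus a derivative-free
# search hook for tuning the reflex parameters.
#
# The reflex laws are a compact member of the classic reflex-control family:
# stance is dominated by positive force feedback of the extensors and a
# trunk-balance contribution through the hip muscles; swing combines
# constant flexion drive, knee control and late-swing deceleration by the
# hamstrings.  They read only observation entries.

# --- observation decoding (planar-18 layout; see R/env.R) ----------------
.leg_names18 <- c("HFL", "GLU", "HAM", "RF", "VAS", "BFSH", "GAS", "SOL", "TA")

decode_obs18 <- function(body) {
  stopifnot(length(body) == 81)
  leg <- function(off) {
    mus <- matrix(body[off + 10:36], nrow = 3)   # rows: force, length, vel
    colnames(mus) <- .leg_names18
    list(grf_fwd = body[off + 1], grf_vert = body[off + 2],
         contact = body[off + 3] > 0.5,
         hip = body[off + 4], knee = body[off + 5], ankle = body[off + 6],
         dhip = body[off + 7], dknee = body[off + 8], dankle = body[off + 9],
         f = mus[1, ], l = mus[2, ], v = mus[3, ])
  }
  list(height = body[1], pitch = body[2], v_fwd = body[4], v_up = body[5],
       w_pitch = body[7], r = leg(9), l = leg(45))
}

#' Standing policy
#'
#' Constant low-level co-activation of the anti-gravity muscles plus a
#' postural reflex: an ankle servo around a slightly dorsiflexed set-point
#' (the quiet-standing equilibrium keeps the centre of mass a little ahead
#' of the ankle, held by soleus) with a forward-velocity term, a knee servo
#' through the vastii, and a combined trunk-pitch / hip-angle servo through
#' the hip muscles.  Standing is statically unstable, so pure constant
#' co-activation cannot hold it; these low-gain joint servos are the
#' minimal stabilising addition.  A pure function of the observation:
#' identical observations give identical actions.
#'
#' @param observation Observation list from [env_reset()] / [env_step()].
#' @param mode Interface mode the action is built for.
#' @param tone Base co-activation level.
#' @param gains Named vector of postural feedback gains: `ankle_kp`,
#'   `ankle_kd`, `ankle_ref` (set-point, rad), `vel` (forward-velocity
#'   gain), `knee_kp`, `knee_kd`, `trunk_kp`, `trunk_kd`, `hip_kp`,
#'   `hip_kd`.
#' @return Excitation vector (length 22 for compat-22, 18 for planar-18).
#' @export
stand_policy <- function(observation, mode = c("compat-22", "planar-18"),
                         tone = 0.005,
                         gains = c(ankle_kp = 5.70, ankle_kd = 0,
                                   ankle_ref = 0.042, vel = 3.81,
                                   knee_kp = 4.53, knee_kd = 0.63,
                                   trunk_kp = 5.51, trunk_kd = 1.33,
                                   hip_kp = 1.51, hip_kd = 0.62)) {
  mode <- match.arg(mode)
  body <- observation$body
  d <- if (length(body) == 81) decode_obs18(body) else decode_obs18(.compat_to18(body))
  a <- stats::setNames(rep(tone, 18),
                       c(paste0(.leg_names18, "_R"), paste0(.leg_names18, "_L")))
  for (side in c("R", "L")) {
    lg <- if (side == "R") d$r else d$l
    # ankle strategy: forward sway (dorsiflexion past the set-point, or
    # forward pelvis velocity) recruits SOL, the reverse TA
    u_sol <- gains[["ankle_kp"]] * (lg$ankle - gains[["ankle_ref"]]) +
      gains[["ankle_kd"]] * lg$dankle + gains[["vel"]] * d$v_fwd
    a[paste0("SOL_", side)] <- a[paste0("SOL_", side)] + max(u_sol, 0)
    a[paste0("TA_", side)] <- a[paste0("TA_", side)] + max(-u_sol, 0)
    # knee servo: flexion (negative knee angle) recruits the vastii
    u_vas <- -gains[["knee_kp"]] * lg$knee - gains[["knee_kd"]] * lg$dknee
    a[paste0("VAS_", side)] <- a[paste0("VAS_", side)] + max(u_vas, 0)
    # trunk/hip: backward pitch or hip extension recruits the flexors,
    # forward pitch or hip flexion the extensors
    u_hip <- gains[["trunk_kp"]] * d$pitch + gains[["trunk_kd"]] * d$w_pitch -
      gains[["hip_kp"]] * lg$hip - gains[["hip_kd"]] * lg$dhip
    a[paste0("HFL_", side)] <- a[paste0("HFL_", side)] + max(u_hip, 0)
    a[paste0("GLU_", side)] <- a[paste0("GLU_", side)] + max(-u_hip, 0)
  }
  a <- pmin(pmax(a, 0), 1)
  if (mode == "planar-18") unname(a) else .expand_to22(a)
}

.expand_to22 <- function(a18) {
  full <- stats::setNames(rep(0, 22), muscle_order())
  full[names(a18)] <- a18
  unname(full)
}

# compat-22 (97-dim) body vector -> planar-18 (81-dim) layout
.compat_to18 <- function(body) {
  stopifnot(length(body) == 97)
  leg <- function(off) {
    grf <- body[off + c(1, 3)]
    ang <- body[off + c(4, 6, 7)]
    spd <- body[off + c(8, 10, 11)]
    mus <- body[off + 11 + 1:33]           # 11 muscles x (force, length, vel)
    c(grf, as.numeric(grf[2] > 1e-3), ang, spd, mus[7:33])  # drop HAB, HAD
  }
  c(body[1:9], leg(9), leg(53))
}

#' Reflex parameter vector
#'
#' Named parameter vector of the reflex gait controller with box bounds.
#' Round-trips losslessly through [write_reflex_params()] /
#' [read_reflex_params()].
#'
#' @param values Optional named numeric vector overriding the defaults.
#' @return Named numeric vector of class `reflex_params` with a `bounds`
#'   attribute (2 x n matrix).
#' @export
reflex_params <- function(values = NULL) {
  def <- c(
    # stance: postural joint servos (ankle/knee/trunk+hip, initialised from
    # the tuned standing reflex) + extensor force feedback + push-off
    ank_kp = 5.70, ank_kd = 0, ank_ref = 0.042, vel_g = 3.81,
    kne_kp = 4.53, kne_kd = 0.63,
    bal_kp = 5.51, bal_kd = 1.33, hip_kp = 1.51, hip_kd = 0.62,
    sol_gf = 0.8,                      # soleus positive force feedback
    gas_gf = 0.4,                      # gastrocnemius force feedback
    vas_gf = 0.5,                      # vastii force feedback
    glu_c = 0.03, ham_share = 0.4,
    po_sol = 0.25,                     # push-off boost in single support
    ds_t = 0.25,                       # double support before swing starts (s)
    # swing
    hfl_sw = 0.4, hfl_gl = 0.5,        # hip flexion drive + HAM-stretch fb
    bfsh_sw = 0.3,                     # early-swing knee flexion
    ham_sw = 0.3, glu_sw = 0.1,        # late-swing deceleration
    vas_sw = 0.15, ta_sw = 0.5,        # landing preparation, foot clearance
    t_sw = 0.25,                       # early/late swing split (s)
    min_st = 0.15)                     # minimum stance dwell (s)
  lo <- c(ank_kp = 0, ank_kd = 0, ank_ref = -0.05, vel_g = 0,
          kne_kp = 0, kne_kd = 0, bal_kp = 0, bal_kd = 0, hip_kp = 0,
          hip_kd = 0, sol_gf = 0, gas_gf = 0, vas_gf = 0, glu_c = 0,
          ham_share = 0, po_sol = 0, ds_t = 0.05, hfl_sw = 0, hfl_gl = 0,
          bfsh_sw = 0, ham_sw = 0, glu_sw = 0, vas_sw = 0, ta_sw = 0,
          t_sw = 0.05, min_st = 0.05)
  hi <- c(ank_kp = 10, ank_kd = 2, ank_ref = 0.15, vel_g = 6,
          kne_kp = 8, kne_kd = 2, bal_kp = 10, bal_kd = 3, hip_kp = 4,
          hip_kd = 2, sol_gf = 5, gas_gf = 5, vas_gf = 5, glu_c = 0.5,
          ham_share = 1, po_sol = 1, ds_t = 1, hfl_sw = 1, hfl_gl = 3,
          bfsh_sw = 1, ham_sw = 1, glu_sw = 0.5, vas_sw = 0.5, ta_sw = 1,
          t_sw = 0.6, min_st = 0.4)
  p <- def
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(def))
    if (length(bad) > 0) stop("unknown reflex parameters: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    p[names(values)] <- values
  }
  p <- pmin(pmax(p, lo[names(p)]), hi[names(p)])
  structure(p, bounds = rbind(lo = lo, hi = hi), class = "reflex_params")
}

#' Read / write reflex parameters
#'
#' Plain YAML serialisation of the named parameter vector.
#'
#' @param params A `reflex_params` vector.
#' @param path File path.
#' @return `read_reflex_params()` returns a `reflex_params` vector.
#' @export
write_reflex_params <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)), path, precision = 17)
  invisible(path)
}

#' @rdname write_reflex_params
#' @export
read_reflex_params <- function(path) {
  v <- unlist(yaml::read_yaml(path))
  reflex_params(v)
}

#' Initial controller state for the reflex policy
#'
#' @return List with per-leg phase (`"stance"`/`"swing"`) and phase timers.
#' @export
reflex_state <- function() {
  list(r = list(phase = "stance", t = 0), l = list(phase = "stance", t = 0))
}

#' Reflex gait policy
#'
#' Stance/swing finite-state machine per leg with muscle excitations formed
#' as clamped sums of constant offsets and gains on sensed muscle force,
#' muscle length and contact terms taken from the observation.  Pure
#' function of `(observation, params, state)`.
#'
#' @param observation Observation list (planar-18 mode).
#' @param params A [reflex_params()] vector.
#' @param state Controller state from [reflex_state()] (or a previous call).
#' @param dt Control time step (s).
#' @return List with `action` (18-vector) and `state` (updated).
#' @export
reflex_policy <- function(observation, params, state = reflex_state(),
                          dt = 0.01) {
  p <- as.list(unclass(params))
  d <- decode_obs18(observation$body)
  act <- stats::setNames(rep(0, 18),
                         c(paste0(.leg_names18, "_R"), paste0(.leg_names18, "_L")))

  for (side in c("r", "l")) {
    lg <- if (side == "r") d$r else d$l
    other_side <- if (side == "r") "l" else "r"
    other <- if (side == "r") d$l else d$r
    st <- state[[side]]
    ot <- state[[other_side]]
    # phase transitions: losing contact starts swing; so does a long double
    # support (the leg that has been in stance longer lifts -- this breaks
    # the both-legs-standing deadlock and alternates stepping); touchdown
    # starts stance
    if (st$phase == "stance" && st$t >= p$min_st) {
      older <- st$t > ot$t || (st$t == ot$t && side == "r")
      start_swing <- !lg$contact ||
        (other$contact && ot$phase == "stance" && st$t >= p$ds_t && older)
      if (start_swing) st <- list(phase = "swing", t = 0)
    } else if (st$phase == "swing" && lg$contact && st$t >= 0.1) {
      st <- list(phase = "stance", t = 0)
    }
    u <- stats::setNames(rep(0, 9), .leg_names18)
    if (st$phase == "stance") {
      # ankle servo (forward sway or forward speed recruits SOL, else TA)
      ua <- p$ank_kp * (lg$ankle - p$ank_ref) + p$ank_kd * lg$dankle +
        p$vel_g * d$v_fwd
      u["SOL"] <- max(ua, 0) + p$sol_gf * lg$f[["SOL"]]
      u["TA"] <- max(-ua, 0)
      u["GAS"] <- p$gas_gf * lg$f[["GAS"]]
      # knee servo + vastii force feedback
      uk <- -p$kne_kp * lg$knee - p$kne_kd * lg$dknee
      u["VAS"] <- max(uk, 0) + p$vas_gf * lg$f[["VAS"]]
      # trunk/hip balance: forward lean (negative pitch) or hip flexion
      # drives the hip extensors
      uh <- p$bal_kp * d$pitch + p$bal_kd * d$w_pitch -
        p$hip_kp * lg$hip - p$hip_kd * lg$dhip
      u["HFL"] <- max(uh, 0)
      u["GLU"] <- p$glu_c + max(-uh, 0)
      u["HAM"] <- p$ham_share * u["GLU"]
      if (!other$contact) {           # single support: push off
        u["SOL"] <- u["SOL"] + p$po_sol
        u["GAS"] <- u["GAS"] + 0.5 * p$po_sol
      }
    } else {
      early <- st$t < p$t_sw
      if (early) {
        u["HFL"] <- p$hfl_sw + p$hfl_gl * max(lg$l[["HAM"]] - 1, 0)
        u["BFSH"] <- p$bfsh_sw
      } else {
        u["HFL"] <- 0.5 * p$hfl_sw
        u["HAM"] <- p$ham_sw
        u["GLU"] <- p$glu_sw
        u["VAS"] <- p$vas_sw
      }
      u["TA"] <- p$ta_sw
    }
    st$t <- st$t + dt
    state[[side]] <- st
    act[paste0(.leg_names18, "_", toupper(side))] <- u
  }
  list(action = unname(pmin(pmax(act, 0), 1)), state = state)
}

#' Derivative-free parameter search
#'
#' A seeded (mu, lambda) rank-based evolution strategy with per-coordinate
#' step-size decay: each generation samples `lambda` offspring around the
#' incumbent mean, keeps the `mu` best by objective value and recombines
#' them; the step size decays geometrically.  Candidates whose objective is
#' non-finite are assigned the worst fitness and the run continues.
#'
#' @param objective Function mapping a parameter vector to a scalar score
#'   (maximised).
#' @param bounds 2 x n matrix (rows `lo`, `hi`) of box bounds.
#' @param budget Total objective evaluations, >= `lambda`.
#' @param seed Integer seed; identical seeds give identical results.
#' @param x0 Optional start vector (defaults to the box midpoint).
#' @param lambda Offspring per generation.
#' @param mu Parents kept per generation.
#' @param sigma0 Initial step size as a fraction of the box width.
#' @param decay Per-generation step-size decay factor.
#' @param verbose Print the best-so-far trace?
#' @return List with `par` (best parameters), `value` (best score) and
#'   `trace` (tibble of per-generation best-so-far values, monotone
#'   non-decreasing).
#' @export
search_params <- function(objective, bounds, budget, seed = 1, x0 = NULL,
                          lambda = 16, mu = 4, sigma0 = 0.15, decay = 0.97,
                          verbose = FALSE) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2)
  if (budget < lambda) stop("budget must be at least lambda", call. = FALSE)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  n <- length(lo)
  set.seed(as.integer(seed))
  mean_x <- if (is.null(x0)) (lo + hi) / 2 else pmin(pmax(x0, lo), hi)
  sigma <- sigma0 * (hi - lo)
  best_x <- mean_x; best_v <- -Inf
  gens <- floor(budget / lambda)
  trace <- numeric(gens)
  for (g in seq_len(gens)) {
    pop <- t(vapply(seq_len(lambda), function(i) {
      pmin(pmax(mean_x + stats::rnorm(n) * sigma, lo), hi)
    }, numeric(n)))
    vals <- apply(pop, 1, function(x) {
      v <- objective(x)
      if (!is.finite(v)) -Inf else v
    })
    ord <- order(vals, decreasing = TRUE)
    elite <- pop[ord[seq_len(mu)], , drop = FALSE]
    mean_x <- colMeans(elite)
    if (vals[ord[1]] > best_v) { best_v <- vals[ord[1]]; best_x <- pop[ord[1], ] }
    sigma <- sigma * decay
    trace[g] <- best_v
    if (verbose) message(sprintf("gen %3d  best %.4f", g, best_v))
  }
  list(par = stats::setNames(best_x, colnames(bounds)), value = best_v,
       trace = tibble::tibble(generation = seq_len(gens), best = trace))
}

#' Roll out a policy in the environment
#'
#' Convenience driver: resets the environment and applies a policy until
#' the episode ends or `steps` control steps have elapsed.
#'
#' @param env A `walker_env`.
#' @param policy `"stand"`, `"reflex"`, or a function
#'   `(observation, state) -> list(action, state)`.
#' @param params [reflex_params()] for the reflex policy.
#' @param steps Maximum control steps.
#' @return List with `result` (an `episode_result`), `log` (trajectory
#'   tibble) and `env`.
#' @export
rollout <- function(env, policy = "stand", params = reflex_params(),
                    steps = env$episode$max_steps) {
  obs <- env_reset(env)
  mode <- env$episode$mode
  pol_state <- reflex_state()
  for (i in seq_len(steps)) {
    if (identical(policy, "stand")) {
      action <- stand_policy(obs, mode = mode)
    } else if (identical(policy, "reflex")) {
      stopifnot(mode == "planar-18")
      out <- reflex_policy(obs, params, pol_state, dt = env$reward$dt)
      action <- out$action
      pol_state <- out$state
    } else {
      out <- policy(obs, pol_state)
      action <- out$action
      pol_state <- out$state
    }
    step <- env_step(env, action)
    obs <- step$observation
    if (step$done) break
  }
  list(result = env_result(env), log = env_trajectory(env), env = env)
}
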