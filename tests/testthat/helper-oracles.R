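# Shared oracle systems and fixture helpers, built in code at test time.

# single rod pivoting about a fixed base at the origin
pendulum_params <- function(mass = 2, length = 1, g = 9.80665) {
  planar_tree_params(
    parent = c(-1L, 0L),
    jpos = rbind(c(0, 0), c(0, 0)),
    com = rbind(c(0, 0), c(0, -length / 2)),
    mass = c(1e-6, mass), inertia = c(1e-9, mass * length^2 / 12),
    gravity = g, base_fixed = TRUE)
}

# two equal rods, fixed base
double_pendulum_params <- function(mass = 1, length = 1, g = 9.80665) {
  planar_tree_params(
    parent = c(-1L, 0L, 1L),
    jpos = rbind(c(0, 0), c(0, 0), c(0, -length)),
    com = rbind(c(0, 0), c(0, -length / 2), c(0, -length / 2)),
    mass = c(1e-6, mass, mass),
    inertia = c(1e-9, mass * length^2 / 12, mass * length^2 / 12),
    gravity = g, base_fixed = TRUE)
}

# free rigid body, no contact
free_body_params <- function(mass = 3, inertia = 0.2, com = c(0, 0)) {
  planar_tree_params(parent = -1L, jpos = rbind(c(0, 0)), com = rbind(com),
                     mass = mass, inertia = inertia)
}

walker_core <- function(config = default_walker_config()) {
  gaitenv:::build_core_params(config)
}

ref_muscle <- function(...) {
  muscle_params(name = "SOL_R", f_max = 4000, l_opt = 0.04, v_max = 6,
                l_slack = 0.26, ...)
}

# random fixture specs for the generator-vs-scorer agreement property
random_fixture_spec <- function(config = reward_config()) {
  mode <- sample(c("piecewise", "follow_field"), 1, prob = c(0.7, 0.3))
  mus <- sample(muscle_order(), sample(1:4, 1))
  acts <- stats::setNames(round(runif(length(mus), 0, 0.8), 3), mus)
  footsteps <- round(runif(sample(1:3, 1), 0.3, 2.5), 2)
  if (mode == "piecewise") {
    fixture_spec(duration = round(runif(1, 3, 8), 1), footsteps = footsteps,
                 velocity_mode = "piecewise",
                 speeds = round(runif(3, 0.8, 1.8), 2),
                 oscillation = round(runif(1, 0, 0.3), 2),
                 activations = acts, config = config)
  } else {
    # keep the target scenario comfortably inside the episode
    fixture_spec(duration = 14, footsteps = footsteps,
                 velocity_mode = "follow_field",
                 activations = acts,
                 targets = list(list(distance = round(runif(1, 2, 4), 2),
                                     dwell = round(runif(1, 2, 3), 2))),
                 config = config)
  }
}
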