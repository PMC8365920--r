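# Planar rigid-body dynamics: closed-form oracles, contact, muscle paths.

test_that("unactuated pendulum matches the closed-form angular acceleration", {
  m <- 2; L <- 1; g <- 9.80665
  p <- pendulum_params(m, L, g)
  for (th in c(-1.2, -0.3, 0.001, 0.3, 1.2)) {
    qdd <- forward_dynamics(c(0, 1, 0, th), rep(0, 4), params = p)
    I_piv <- m * L^2 / 12 + m * (L / 2)^2
    expect_equal(qdd[4], -(m * g * (L / 2) / I_piv) * sin(th),
                 tolerance = 1e-12)
  }
})

test_that("zero gravity, zero forces, zero velocity gives zero acceleration", {
  p <- double_pendulum_params(g = 0)
  qdd <- forward_dynamics(c(0, 0, 0, 0.7, -0.4), rep(0, 5), params = p)
  expect_equal(max(abs(qdd)), 0, tolerance = 1e-12)
})

test_that("mass matrix is symmetric positive-definite at random configurations", {
  set.seed(1)
  core <- walker_core()
  for (i in 1:100) {
    q <- c(runif(2, -1, 1), runif(1, -0.5, 0.5), runif(6, -1, 1))
    M <- mass_matrix(q, core)
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("ballistic flight follows the projectile closed form", {
  p <- free_body_params(mass = 3, inertia = 0.2, com = c(0, 0))
  st <- list(q = c(0, 2, 0.1), qd = c(1.5, 3, 0.4), act = numeric(0), time = 0)
  out <- integrate_step(st, numeric(0), p, dt = 0.5, substeps = 5000)
  g <- 9.80665; t <- 0.5
  expect_equal(out$q[1], 0 + 1.5 * t, tolerance = 1e-6)
  expect_equal(out$q[2], 2 + 3 * t - 0.5 * g * t^2, tolerance = 1e-3)
  expect_equal(out$qd[2], 3 - g * t, tolerance = 1e-9)
  expect_equal(out$q[3], 0.1 + 0.4 * t, tolerance = 1e-9)
})

test_that("passive double pendulum conserves energy to < 0.1% over 5 s", {
  p <- double_pendulum_params()
  q0 <- c(0, 0, 0, 1.2, 0.5)
  st <- list(q = q0, qd = rep(0, 5), act = numeric(0), time = 0)
  e0 <- tree_energy(q0, rep(0, 5), p)$total
  out <- integrate_step(st, numeric(0), p, dt = 5, substeps = 5e5)
  e1 <- tree_energy(out$q, out$qd, p)$total
  expect_lt(abs(e1 - e0) / abs(e0), 0.001)
})

test_that("horizontal momentum is conserved in contact-free passive flight", {
  # symplectic-Euler momentum drift is O(h^2) per integration step; at a
  # 1e-5 s step the per-step relative drift must be below 1e-9
  core <- walker_core()
  q <- c(0, 3, 0.1, 0.4, -0.6, 0.2, -0.3, -0.8, 0.1)  # airborne, legs bent
  qd <- c(1.2, 0.5, 0.3, rep(0.4, 6))
  st <- list(q = q, qd = qd, act = rep(0, length(core$mus_fmax)), time = 0)
  px <- function(q, qd) {
    k <- tree_kinematics(q, qd, core)
    sum(core$mass * k$v_com[, 1])
  }
  p0 <- px(q, qd)
  nsub <- 5000                      # 0.05 s at h = 1e-5
  st1 <- integrate_step(st, rep(0, length(core$mus_fmax)), core,
                        dt = 0.05, substeps = nsub)
  drift_per_step <- abs(px(st1$q, st1$qd) - p0) / abs(p0) / nsub
  expect_lt(drift_per_step, 1e-9)
  # and the drift order is quadratic: 10x the step, ~100x the drift
  st2 <- integrate_step(st, rep(0, length(core$mus_fmax)), core,
                        dt = 0.05, substeps = nsub / 10)
  drift10 <- abs(px(st2$q, st2$qd) - p0) / abs(p0) / (nsub / 10)
  expect_gt(drift10 / (drift_per_step * 100), 0.2)
  expect_lt(drift10 / (drift_per_step * 100), 5)
})

test_that("contact forces: no adhesion, spring law, Coulomb saturation", {
  core <- walker_core()
  s <- initial_state()
  # airborne: all forces zero
  qa <- s$q; qa[2] <- qa[2] + 1
  cf <- contact_forces(qa, s$qd, core)
  expect_true(all(cf$fx == 0 & cf$fy == 0))
  expect_true(all(!cf$in_contact))
  # static penetration: normal force equals the stiffness law k d^1.5
  cf <- contact_forces(s$q, rep(0, 9), core)
  d <- cf$penetration[1]
  expect_gt(d, 0)
  expect_equal(cf$fy[1], core$contact_stiffness * d^core$contact_exponent,
               tolerance = 1e-9)
  expect_equal(cf$fx[1], 0)
  # sliding: tangential force opposes slip and saturates at mu N
  qd <- rep(0, 9); qd[1] <- 2      # fast forward slide
  cf <- contact_forces(s$q, qd, core)
  expect_true(all(cf$fx < 0))
  expect_true(all(abs(cf$fx) <= core$friction_mu * cf$fy + 1e-9))
  expect_equal(abs(cf$fx[1]), core$friction_mu * cf$fy[1], tolerance = 1e-3)
})

test_that("joint-limit torques act only outside the limits", {
  core <- walker_core()
  q_in <- c(0, 2, 0, 0.3, -0.5, 0.1, 0.3, -0.5, 0.1)   # inside all limits
  qd <- rep(0.2, 9)
  a1 <- forward_dynamics(q_in, qd, params = core, with_limits = TRUE)
  a2 <- forward_dynamics(q_in, qd, params = core, with_limits = FALSE)
  expect_equal(a1, a2, tolerance = 1e-12)
  # knee pushed past extension limit: limit torque opposes the violation
  q_out <- q_in; q_out[5] <- 0.4    # beyond the 0.02 rad extension stop
  a1 <- forward_dynamics(q_out, rep(0, 9), params = core, with_limits = TRUE)
  a2 <- forward_dynamics(q_out, rep(0, 9), params = core, with_limits = FALSE)
  expect_lt(a1[5], a2[5])
})

test_that("muscle path geometry: neutral calibration, moment arms, velocity", {
  core <- walker_core()
  s <- initial_state()
  g0 <- muscle_geometry(s$q, rep(0, 9), core)
  expect_equal(g0$length, core$mus_L0, tolerance = 1e-12)
  expect_true(all(g0$length > 0))
  # knee flexion by delta lengthens VAS by |moment arm x delta|, velocity 0
  delta <- -0.3
  q1 <- s$q; q1[5] <- delta
  g1 <- muscle_geometry(q1, rep(0, 9), core)
  ivas <- which(core$mus_names == "VAS_R")
  r_vas <- core$mus_moment_arm[ivas, 2]
  expect_equal(g1$length[ivas] - g0$length[ivas], abs(r_vas * delta),
               tolerance = 1e-12)
  expect_equal(g1$velocity[ivas], 0)
  # biarticular muscles span two joints
  iham <- which(core$mus_names == "HAM_R")
  expect_equal(sum(core$mus_moment_arm[iham, ] != 0), 2)
  # finite-difference check: velocity is the exact derivative of length
  set.seed(5)
  qd <- c(0, 0, 0, runif(6, -1, 1))
  eps <- 1e-7
  gq <- muscle_geometry(s$q, qd, core)
  gq2 <- muscle_geometry(s$q + eps * qd, qd, core)
  expect_equal((gq2$length - gq$length) / eps, gq$velocity, tolerance = 1e-5)
})

test_that("integrate_step is deterministic and rejects non-finite actions", {
  core <- walker_core()
  s <- initial_state()
  exc <- runif(length(core$mus_fmax))
  a <- integrate_step(s, exc, core)
  b <- integrate_step(s, exc, core)
  expect_identical(a$q, b$q)
  expect_identical(a$qd, b$qd)
  expect_identical(a$act, b$act)
  expect_error(integrate_step(s, replace(exc, 3, NaN), core), "index 3")
})

test_that("zero gravity, zero excitation, zero velocity leaves state unchanged", {
  cfg <- default_walker_config()
  cfg$gravity <- 0
  core <- gaitenv:::build_core_params(cfg)
  q <- c(0, 2, 0, rep(0, 6))     # airborne so no contact either
  st <- list(q = q, qd = rep(0, 9), act = rep(0, length(core$mus_fmax)),
             time = 0)
  out <- integrate_step(st, rep(0, length(core$mus_fmax)), core)
  expect_equal(out$q, q, tolerance = 1e-14)
  expect_equal(out$qd, rep(0, 9), tolerance = 1e-14)
})
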