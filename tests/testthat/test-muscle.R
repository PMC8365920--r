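# Hill muscle-tendon unit: activation dynamics, force curves, effort.

test_that("activation dynamics fix point, saturation and exact exponential", {
  p <- ref_muscle()
  # fixed point
  expect_equal(as.numeric(activation_step(0.5, 0.5, 0.01, p)), 0.5)
  # saturation under repeated steps, monotone
  a <- 0
  prev <- 0
  for (i in 1:2000) {
    a <- as.numeric(activation_step(1, a, 0.01, p))
    expect_gte(a, prev)
    prev <- a
  }
  expect_equal(a, 1, tolerance = 1e-6)
  # closed-form exponential of da/dt = (u - a)/tau_act
  a1 <- as.numeric(activation_step(1, 0, 0.01, p))
  expect_equal(a1, 1 - exp(-0.01 / 0.015), tolerance = 1e-3)
  # full trajectory at 1 ms steps matches the closed form to 1e-6
  a <- 0.2
  tt <- 0
  for (i in 1:300) {
    a <- as.numeric(activation_step(0.9, a, 0.001, p))
    tt <- tt + 0.001
    expect_equal(a, 0.9 + (0.2 - 0.9) * exp(-tt / 0.015), tolerance = 1e-6)
  }
})

test_that("out-of-range excitation is clamped and flagged", {
  p <- ref_muscle()
  a <- activation_step(1.7, 0.5, 0.01, p)
  expect_true(attr(a, "clamped"))
  expect_lte(as.numeric(a), 1)
  a2 <- activation_step(-0.3, 0.5, 0.01, p)
  expect_true(attr(a2, "clamped"))
  expect_gte(as.numeric(a2), 0)
  expect_false(attr(activation_step(0.7, 0.5, 0.01, p), "clamped"))
})

test_that("active force-length is a unimodal bell with maximum at optimum", {
  expect_equal(force_length_active(1), 1)
  expect_lt(force_length_active(0.4), 0.05)
  for (d in c(0.05, 0.1, 0.2, 0.4)) {
    expect_lt(force_length_active(1 + d), 1)
    expect_lt(force_length_active(1 - d), 1)
  }
  l <- seq(0.3, 1.7, by = 0.01)
  f <- force_length_active(l)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("force-velocity endpoints, eccentric plateau and monotonicity", {
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  expect_equal(force_velocity(-1.4), 0)
  # eccentric value from the independent scalar form of the chosen curve:
  # plateau - (plateau-1) / (1 + v/ke), ke = (plateau-1)/(1 + 1/0.25)
  plateau <- 1.5
  ke <- (plateau - 1) / (1 + 1 / 0.25)
  expect_equal(force_velocity(1, plateau), plateau - (plateau - 1) / (1 + 1 / ke))
  expect_gt(force_velocity(1), 1)
  expect_lte(force_velocity(1e3), plateau)
  v <- seq(-1.5, 3, by = 0.01)
  f <- force_velocity(v)
  expect_true(all(diff(f) >= -1e-12))
})

test_that("passive force engages above optimum and grows superlinearly", {
  expect_equal(force_passive(1), 0)
  expect_equal(force_passive(0.7), 0)
  expect_gt(force_passive(1.5), 0)
  # doubling the stretch beyond engagement more than doubles the force
  expect_gt(force_passive(1.4), 2 * force_passive(1.2))
  l <- seq(1.01, 2, by = 0.01)
  expect_true(all(diff(force_passive(l)) > 0))
})

test_that("mtu_force composes the scalar curves under the rigid tendon", {
  p <- ref_muscle()
  neutral <- p$l_slack + p$l_opt
  # no activation, optimal length, isometric: zero force
  s <- mtu_force(list(activation = 0), neutral, 0, p)
  expect_equal(s$force, 0)
  expect_equal(s$l_ce_norm, 1)
  # maximal isometric
  s <- mtu_force(list(activation = 1), neutral, 0, p)
  expect_equal(s$force, p$f_max)
  # mixed case cross-checked by composing the scalar operations
  l <- p$l_slack + 1.2 * p$l_opt
  s <- mtu_force(list(activation = 0.5), l, 0, p)
  expect_equal(s$force,
               p$f_max * (0.5 * force_length_active(1.2) * force_velocity(0) +
                            force_passive(1.2)),
               tolerance = 1e-12)
  # degenerate geometry: passive-only floor and flag
  s <- mtu_force(list(activation = 1), p$l_slack / 2, 0, p)
  expect_true(s$degenerate)
  expect_equal(s$force, 0)
})

test_that("mtu_force equals f_max (a fl fv + fp) over random draws", {
  set.seed(42)
  p <- ref_muscle()
  for (i in 1:1000) {
    a <- runif(1)
    lce <- runif(1, 0.5, 1.6)
    vce <- runif(1, -1.2, 1.5)
    s <- mtu_force(list(activation = a), p$l_slack + lce * p$l_opt,
                   vce * p$v_max * p$l_opt, p)
    expected <- p$f_max * (a * force_length_active(lce) *
                             force_velocity(vce, p$fv_ecc_plateau) +
                             force_passive(lce))
    expect_equal(s$force, max(expected, 0), tolerance = 1e-9)
    expect_gte(s$force, 0)
  }
})

test_that("effort increment is dt * sum of squared activations", {
  expect_equal(effort_increment(rep(0, 22), 0.01), 0)
  expect_equal(effort_increment(c(0.5, rep(0, 21)), 0.01), 0.0025)
  expect_equal(effort_increment(rep(1, 22), 0.01), 0.22)
  # order invariance over an episode
  set.seed(7)
  acts <- matrix(runif(22 * 50), 50, 22)
  perm <- sample(22)
  total <- sum(apply(acts, 1, effort_increment, dt = 0.01))
  total_perm <- sum(apply(acts[, perm], 1, effort_increment, dt = 0.01))
  expect_equal(total, total_perm, tolerance = 1e-12)
})

test_that("muscle parameter validation enforces the invariants", {
  expect_error(muscle_params("XXX_R", 100, 0.1, 10, 0.2), "unknown muscle")
  expect_error(ref_muscle(tau_act = 0.06, tau_deact = 0.05), "tau_act")
  expect_error(ref_muscle(fv_ecc_plateau = 0.9), "fv_ecc_plateau")
  expect_error(muscle_params("SOL_R", -1, 0.1, 10, 0.2), "f_max")
})
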