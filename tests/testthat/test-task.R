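# Reward system: footstep ledger, targets, velocity field, decomposition.

test_that("alive increment and its episode sums", {
  cfg <- reward_config()
  expect_equal(alive_increment(cfg), 0.1)
  expect_equal(sum(rep(alive_increment(cfg), 2500)), 250)
  expect_equal(sum(rep(alive_increment(cfg), 100)), 10)
})

test_that("footstep events: touchdown after swing, chatter debounce, forced closure", {
  cfg <- reward_config()
  # both feet static on the ground
  expect_equal(detect_footstep_event(c(TRUE, TRUE), c(TRUE, TRUE),
                                     c(0, 0), 1.2, cfg), "none")
  # right foot airborne 0.4 s then touches down
  expect_equal(detect_footstep_event(c(FALSE, TRUE), c(TRUE, TRUE),
                                     c(0.4, 0), 1.2, cfg), "new_step")
  # contact chatter: airborne only 10 ms
  expect_equal(detect_footstep_event(c(FALSE, TRUE), c(TRUE, TRUE),
                                     c(0.01, 0), 1.2, cfg), "none")
  # forced closure after the standing horizon
  expect_equal(detect_footstep_event(c(TRUE, TRUE), c(TRUE, TRUE),
                                     c(0, 0), 5.0, cfg), "new_step")
})

test_that("step accumulation integrates duration, velocity error and effort", {
  cfg <- reward_config()
  led <- new_footstep_ledger()
  # velocity matching the command leaves a zero integral
  for (i in 1:50) led <- accumulate_step(led, c(1.3, 0), c(1.3, 0), rep(0, 22), 0.01)
  expect_equal(led$open$v_int, c(0, 0))
  # zero-mean fluctuation around the command also integrates to zero
  led2 <- new_footstep_ledger()
  for (i in 1:50) {
    v <- c(1.3 + 0.2 * (-1)^i, 0)
    led2 <- accumulate_step(led2, v, c(1.3, 0), rep(0, 22), 0.01)
  }
  expect_equal(sqrt(sum(led2$open$v_int^2)), 0, tolerance = 1e-12)
  # constant deviation integrates to (v - v_tgt) * T
  led3 <- new_footstep_ledger()
  for (i in 1:50) led3 <- accumulate_step(led3, c(1.0, 0), c(1.3, 0), rep(0, 22), 0.01)
  expect_equal(led3$open$v_int, c(-0.15, 0), tolerance = 1e-9)
})

test_that("footstep closure reproduces the hand-computed step rewards", {
  cfg <- reward_config()
  # 1.0 s zero-cost step scores w_s
  led <- new_footstep_ledger()
  for (i in 1:100) led <- accumulate_step(led, c(1.3, 0), c(1.3, 0), rep(0, 22), 0.01)
  cl <- close_footstep(led, cfg)
  expect_equal(cl$reward, 10, tolerance = 1e-9)
  # 0.5 s with velocity integral (-0.15, 0): 10*0.5 - 3*0.15 = 4.55
  led <- new_footstep_ledger()
  for (i in 1:50) led <- accumulate_step(led, c(1.0, 0), c(1.3, 0), rep(0, 22), 0.01)
  cl <- close_footstep(led, cfg)
  expect_equal(cl$reward, 4.55, tolerance = 1e-9)
  # 0.5 s, zero velocity cost, one muscle at 0.5: 5 - 0.25*0.5 = 4.875
  led <- new_footstep_ledger()
  acts <- c(0.5, rep(0, 21))
  for (i in 1:50) led <- accumulate_step(led, c(1.3, 0), c(1.3, 0), acts, 0.01)
  cl <- close_footstep(led, cfg)
  expect_equal(cl$reward, 4.875, tolerance = 1e-9)
  # zero-duration closure: reward 0 with a warning flag
  cl0 <- close_footstep(new_footstep_ledger(), cfg)
  expect_equal(cl0$reward, 0)
  expect_true(cl0$zero_duration)
  # the closed record is immutable and the counter advances
  expect_equal(cl$ledger$i_step, 2L)
  expect_equal(cl$ledger$open$duration, 0)
})

test_that("target sampling is seeded, in-range and annulus-bounded", {
  cfg <- reward_config()
  set.seed(99)
  t1 <- sample_target(c(0, 0), 1, cfg)
  set.seed(99)
  t2 <- sample_target(c(0, 0), 1, cfg)
  expect_identical(t1, t2)
  set.seed(123)
  dw <- replicate(1e4, {
    s <- sample_target(c(1, 2), 1, cfg, annulus = c(2, 6))
    d <- sqrt(sum((s$location - c(1, 2))^2))
    expect_gte(d, 2); expect_lte(d, 6)
    s$required_dwell
  })
  expect_true(all(dw >= 2 & dw <= 4))
  expect_equal(mean(dw), 3, tolerance = 0.02)
})

test_that("target dwell clock awards the bonus only inside the radius", {
  cfg <- reward_config()
  # 0.29 m sustained for the required dwell earns 500
  sp <- target_spec(1, c(0, 0), required_dwell = 2.5)
  bonus <- 0
  for (i in 1:260) {
    up <- update_target(sp, c(0.29, 0), 0.01, cfg)
    sp <- up$spec
    bonus <- bonus + up$bonus
    if (up$advance) break
  }
  expect_equal(bonus, 500)
  expect_true(sp$awarded)
  # 0.31 m forever earns nothing
  sp <- target_spec(1, c(0, 0), required_dwell = 2)
  for (i in 1:500) {
    up <- update_target(sp, c(0.31, 0), 0.01, cfg)
    sp <- up$spec
    expect_equal(up$bonus, 0)
  }
  expect_false(sp$awarded)
  # leaving at 1.9 s resets the clock
  sp <- target_spec(1, c(0, 0), required_dwell = 2)
  for (i in 1:190) sp <- update_target(sp, c(0.2, 0), 0.01, cfg)$spec
  expect_gt(sp$dwell, 1.8)
  sp <- update_target(sp, c(0.5, 0), 0.01, cfg)$spec
  expect_equal(sp$dwell, 0)
  # stepping an already-awarded target is a contract violation
  sp <- target_spec(1, c(0, 0), required_dwell = 0.02)
  sp <- update_target(sp, c(0, 0), 0.01, cfg)$spec
  sp <- update_target(sp, c(0, 0), 0.01, cfg)$spec
  expect_true(sp$awarded)
  expect_error(update_target(sp, c(0, 0), 0.01, cfg), "already awarded")
})

test_that("local velocity map layout, length and centre-cell convention", {
  # uniform field: first 121 entries are the forward speed, last 121 zero
  f <- velocity_field(uniform = c(1.4, 0))
  m <- local_velocity_map(f, c(0, 0))
  expect_length(m, 242)
  expect_equal(m[1:121], rep(1.4, 121))
  expect_equal(m[122:242], rep(0, 121))
  # target field: centre cell equals the commanded velocity at the pelvis
  f <- velocity_field(target = c(5, 0), speed = 1.4)
  pos <- c(1.2, 0)
  m <- local_velocity_map(f, pos)
  centre <- c(m[61], m[61 + 121])
  expect_equal(centre, field_at(f, pos), tolerance = 1e-12)
  # pelvis at the target: centre cell magnitude zero
  m0 <- local_velocity_map(f, c(5, 0))
  expect_equal(c(m0[61], m0[182]), c(0, 0))
  # field vectors point toward the target, tapering inside the radius
  expect_equal(sqrt(sum(field_at(f, c(0, 0))^2)), 1.4)
  expect_equal(sqrt(sum(field_at(f, c(5 - 0.15, 0))^2)), 0.7)
})

test_that("decomposition identity and upper bound on random fixtures", {
  cfg <- reward_config()
  set.seed(31)
  for (i in 1:8) {
    fx <- generate_fixture(random_fixture_spec(cfg))
    res <- score_trajectory(fx$log, cfg)
    expect_equal(res$J, res$R_alive + res$R_step + res$R_target,
                 tolerance = 1e-9)
    expect_equal(sum(res$reward_trace), res$J, tolerance = 1e-9)
  }
  # full-length max fixture stays at the 1500 bound
  fx <- generate_fixture(fixture_spec())
  res <- score_trajectory(fx$log, cfg)
  expect_lte(res$J, 1500 + 1e-9)
  # without targets the bound is 250 + 250
  fx2 <- generate_fixture(fixture_spec(targets = list()))
  res2 <- score_trajectory(fx2$log, cfg)
  expect_lte(res2$J, 500 + 1e-9)
  expect_equal(res2$R_target, 0)
})

test_that("step bonus is invariant to the footstep partition for zero-cost gaits", {
  cfg <- reward_config()
  totals <- vapply(list(0.5, 0.8, c(0.3, 1.1), 2.2), function(fs) {
    fx <- generate_fixture(fixture_spec(duration = 12, footsteps = fs,
                                        targets = list()))
    res <- score_trajectory(fx$log, cfg)
    expect_equal(res$R_step, sum(res$footsteps$b_s) * cfg$w_s,
                 tolerance = 1e-9)
    res$R_step
  }, numeric(1))
  expect_lt(max(totals) - min(totals), 1e-9)
})

test_that("velocity cost sees only the within-step average velocity", {
  cfg <- reward_config()
  base <- fixture_spec(duration = 6, footsteps = 0.75,
                       velocity_mode = "piecewise", speeds = 1.4,
                       oscillation = 0, config = cfg)
  wob <- fixture_spec(duration = 6, footsteps = 0.75,
                      velocity_mode = "piecewise", speeds = 1.4,
                      oscillation = 0.25, config = cfg)
  r1 <- score_trajectory(generate_fixture(base)$log, cfg)
  r2 <- score_trajectory(generate_fixture(wob)$log, cfg)
  expect_equal(r1$R_step, r2$R_step, tolerance = 1e-9)
  expect_equal(max(r2$footsteps$c_v), 0, tolerance = 1e-12)
})

test_that("raising any activation trace never increases the total reward", {
  cfg <- reward_config()
  set.seed(77)
  for (i in 1:5) {
    lo_act <- runif(1, 0, 0.4)
    mus <- sample(muscle_order(), 2)
    spec_lo <- fixture_spec(duration = 5, footsteps = 0.6,
                            velocity_mode = "piecewise",
                            activations = stats::setNames(rep(lo_act, 2), mus),
                            config = cfg)
    spec_hi <- fixture_spec(duration = 5, footsteps = 0.6,
                            velocity_mode = "piecewise",
                            activations = stats::setNames(rep(lo_act + 0.3, 2), mus),
                            config = cfg)
    expect_lte(score_trajectory(generate_fixture(spec_hi)$log, cfg)$J,
               score_trajectory(generate_fixture(spec_lo)$log, cfg)$J)
  }
})

test_that("episode result bookkeeping: tidy, glance and the reward table", {
  res <- episode_result(250, 230, 1000, reward_trace = rep(0.1, 10))
  expect_equal(res$J, 1480)
  td <- tidy(res)
  expect_equal(td$reward, c(250, 230, 1000))
  gl <- glance(res)
  expect_equal(gl$J, 1480)
  expect_equal(gl$n_steps, 10)
})
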