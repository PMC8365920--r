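# Environment: interface dimensions, determinism, reward bookkeeping.

test_that("interface dimensions match the published layout", {
  env <- walker_env(episode = episode_config(mode = "compat-22", seed = 1))
  d <- env_dims(env)
  expect_equal(d$n_body, 97L)
  expect_equal(d$n_map, 242L)
  expect_equal(d$n_action, 22L)
  expect_equal(env$episode$max_steps, 2500L)
  expect_length(muscle_names_per_leg(), 11)
  obs <- env_reset(env)
  expect_length(obs$body, 97)
  expect_length(obs$vtgt_map, 242)
  st <- env_step(env, rep(0, 22))
  expect_length(st$observation$body, 97)

  env18 <- walker_env(episode = episode_config(mode = "planar-18", seed = 1))
  obs18 <- env_reset(env18)
  expect_length(obs18$body, 81)
  expect_length(obs18$vtgt_map, 242)
  expect_equal(env_dims(env18)$n_action, 18L)
})

test_that("frontal-plane entries are exact zeros at reset in compat mode", {
  env <- walker_env(episode = episode_config(mode = "compat-22", seed = 2))
  obs <- env_reset(env)
  # pelvis roll, lateral velocity, roll/yaw rate
  expect_identical(obs$body[c(3, 6, 8, 9)], rep(0, 4))
  # per-leg lateral GRF and hip abduction angle/speed (right leg block)
  expect_identical(obs$body[9 + c(2, 5, 9)], rep(0, 3))
  expect_identical(obs$body[53 + c(2, 5, 9)], rep(0, 3))
})

test_that("reset is deterministic per seed and differs across seeds", {
  e1 <- walker_env(episode = episode_config(seed = 5))
  e2 <- walker_env(episode = episode_config(seed = 5))
  o1 <- env_reset(e1); o2 <- env_reset(e2)
  expect_identical(o1, o2)
  expect_identical(e1$target$location, e2$target$location)
  e3 <- walker_env(episode = episode_config(seed = 6))
  o3 <- env_reset(e3)
  expect_false(identical(e1$target$location, e3$target$location))
})

test_that("identical seeds and action sequences give bit-identical episodes", {
  run <- function() {
    env <- walker_env(episode = episode_config(mode = "planar-18", seed = 9,
                                               max_steps = 120))
    obs <- env_reset(env)
    set.seed(1234)
    traces <- list()
    for (i in 1:120) {
      a <- runif(18, 0, 0.3)
      st <- env_step(env, a)
      traces[[i]] <- list(o = st$observation$body, r = st$reward, d = st$done)
      if (st$done) break
    }
    traces
  }
  expect_identical(run(), run())
})

test_that("per-episode reward trace sums to the episode decomposition", {
  env <- walker_env(episode = episode_config(mode = "planar-18", seed = 4,
                                             max_steps = 300))
  out <- rollout(env, policy = "stand", steps = 300)
  res <- out$result
  expect_equal(sum(res$reward_trace), res$J, tolerance = 1e-9)
  expect_equal(res$J, res$R_alive + res$R_step + res$R_target,
               tolerance = 1e-12)
  # offline re-scoring of the trajectory log reproduces the same result
  off <- score_trajectory(out$log, env$reward)
  expect_equal(off$J, res$J, tolerance = 1e-9)
  expect_equal(off$R_alive, res$R_alive, tolerance = 1e-12)
  expect_equal(off$R_step, res$R_step, tolerance = 1e-9)
})

test_that("observations stay finite over random-action episodes", {
  set.seed(2024)
  for (ep in 1:100) {
    env <- walker_env(episode = episode_config(
      mode = "planar-18", seed = ep, max_steps = 25))
    obs <- env_reset(env)
    for (i in 1:25) {
      st <- env_step(env, runif(18))
      expect_true(all(is.finite(st$observation$body)))
      expect_true(all(is.finite(st$observation$vtgt_map)))
      if (st$done) break
    }
  }
})

test_that("HAB/HAD channels affect effort and observation but not dynamics", {
  run22 <- function(frontal) {
    env <- walker_env(episode = episode_config(mode = "compat-22", seed = 3,
                                               max_steps = 60))
    obs <- env_reset(env)
    a <- rep(0, 22)
    a[match(c("HAB_R", "HAD_R", "HAB_L", "HAD_L"), muscle_order())] <- frontal
    qs <- list()
    for (i in 1:60) {
      st <- env_step(env, a)
      qs[[i]] <- env$state$q
    }
    list(q = qs, result = env_result(env), obs = st$observation$body)
  }
  off <- run22(0)
  on <- run22(0.8)
  expect_identical(off$q, on$q)                       # no mechanical action
  expect_lt(on$result$J, off$result$J)                # effort cost increased
  expect_false(identical(off$obs, on$obs))            # observation differs
})

test_that("termination: fall threshold, step cap and stepping-after-done", {
  cfg <- reward_config()
  s <- initial_state()
  expect_false(check_termination(s, 100, cfg, 2500))
  s$q[2] <- 0.59
  expect_true(check_termination(s, 100, cfg, 2500))
  s$q[2] <- 0.9
  expect_true(check_termination(s, 2500, cfg, 2500))

  env <- walker_env(episode = episode_config(mode = "planar-18", seed = 1,
                                             max_steps = 3))
  env_reset(env)
  for (i in 1:3) st <- env_step(env, rep(0, 18))
  expect_true(st$done)
  expect_error(env_step(env, rep(0, 18)), "finished episode")
  # non-finite action entries are rejected with the offending index
  env2 <- walker_env(episode = episode_config(mode = "planar-18", seed = 1))
  env_reset(env2)
  expect_error(env_step(env2, replace(rep(0, 18), 7, Inf)), "index 7")
})

test_that("a fallen episode earns no alive bonus on the fall step", {
  # push the standing model over so it falls within the episode
  env <- walker_env(episode = episode_config(mode = "planar-18", seed = 1,
                                             max_steps = 400))
  env_reset(env)
  env$state$qd[1] <- -3           # hard backward shove
  st <- NULL
  for (i in 1:400) {
    st <- env_step(env, rep(0, 18))
    if (st$done) break
  }
  expect_true(st$info$fallen)
  res <- env_result(env)
  expect_lt(res$R_alive, res$n_steps * 0.1)   # at least the fall step unpaid
  expect_equal(res$J, res$R_alive + res$R_step + res$R_target,
               tolerance = 1e-12)
})
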