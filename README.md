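# gaitenv

A desk-scale neuromechanical locomotion environment for R: a planar
seven-segment musculoskeletal walker driven by Hill-type muscles, a
target-velocity navigation task with a footstep-segmented reward, a
gym-style step/reset interface for control experiments, reflex-style
baseline controllers with a derivative-free tuning hook, and a harness that
generates and scores trajectory fixtures with closed-form expected rewards.

The package is aimed at researchers in biomechanics, motor control and
reinforcement learning who want a fully reproducible, self-contained
walking task — the environment, its scoring, and its printed
maximum-reward decomposition are all recomputable from code, with no
external downloads.

## The reward system

An episode lasts at most 2500 simulation steps of Δt = 0.01 s. The total
reward decomposes exactly as

    J = R_alive + R_step + R_target
      = Σ_sim b_alive
      + Σ_step ( w_s·b_s − w_v·c_v − w_e·c_e )
      + Σ_target b_target

with `b_alive = 0.1` per non-fallen step, `w_s = 10`, `w_v = 3`, `w_e = 1`
and `b_target = 500` for each of two targets held within 0.3 m for a 2–4 s
dwell. Within each footstep, `b_s` is the step duration, `c_v` the norm of
the time-integrated pelvis-velocity error (so only the *average* velocity
per footstep is penalised), and `c_e` the integral of summed squared muscle
activations. The hypothetical zero-cost maximum is
`250 + 250 + 1000 = 1500`.

The walker is actuated by 22 Hill-type muscles (11 per leg: HAB, HAD, HFL,
GLU, HAM, RF, VAS, BFSH, GAS, SOL, TA) and exposes the published interface
in its compatibility mode: 22-dimensional excitation actions, a
97-dimensional body observation and a 242-dimensional local target-velocity
map. The native sagittal mode uses 18 muscles and an 81-dimensional body
vector. See `vignettes/gaitenv-methods.Rmd` for the model equations,
parameter tables and design notes.

## Worked example

```r
library(gaitenv)

# a zero-cost, full-length stepping episode reaching both targets
fx  <- generate_fixture(fixture_spec())
res <- score_trajectory(fx$log)
res
#> Episode result (2500 simulation steps)
#>   J        = 1500.000000
#>   R_alive  = 250.000000
#>   R_step   = 250.000000
#>   R_target = 1000.000000
#>   footsteps: 32  (total duration 25.00 s)
```

The three lines are the episode's exact reward decomposition: 2500 alive
steps at 0.1, footsteps covering all 25 s at weight 10 with zero velocity
and effort costs, and two 500-point target bonuses.

Running the live environment under the shipped reflex baseline:

```r
env <- walker_env(episode = episode_config(mode = "planar-18", seed = 3,
                                           forward_speed = 0.4))
out <- rollout(env, policy = "reflex",
               params = read_reflex_params(
                 system.file("extdata", "reflex_tuned.yaml",
                             package = "gaitenv")))
glance(out$result)
#> # A tibble: 1 × 8
#>       J R_alive R_step R_target n_steps n_footsteps targets_reached fallen
#>   <dbl>   <dbl>  <dbl>    <dbl>   <int>       <int>           <int> <lgl>
#> 1  897.    250.   147.      500    2500          20               1 FALSE
```

The shipped reflex baseline walks the full 25 s episode with 20 footsteps,
reaches the first target (+500) and accrues the full alive bonus; its step
term is reduced by velocity and effort costs, as expected for a non-learned
controller.

`tidy()`, `glance()` and `autoplot()` methods are provided for episode
results; `plot_replay()` draws a stick-figure replay of any trajectory log.

A thin command-line front end is installed at `inst/cli/gaitenv` with
subcommands `simulate`, `rollout-baseline`, `gen-fixture`,
`score-trajectory` and `replay-plot`:

```sh
Rscript inst/cli/gaitenv gen-fixture --seed 7 --out /tmp/fx.csv
Rscript inst/cli/gaitenv score-trajectory --log /tmp/fx.csv
```

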