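# arenalab

A headless virtual laboratory for comparative-cognition experiments on
computational agents: a deterministic, discrete-time 3D arena simulator
written in R.

Comparative cognition studies what animals can do by placing them in
carefully constructed apparatus — mazes, detour barriers, operant chambers,
foraging patches — and scoring their behaviour. arenalab recreates that
setting for *computational* subjects. A spherical agent (diameter 1) acts in
an enclosed 40 × 40-unit arena furnished from a fixed object ontology:
immovable walls, ramps (climbable iff height:length ≤ 4:1), and tunnels;
pushable blocks of mass 1, 1.5, or 2; positively and negatively valenced
goal spheres (episode-ending or not, static, bouncing, decaying, ripening,
growing, shrinking); passable death and hot zones; fruit-dropping spawner
trees, goal dispensers, and a pressable spawner button; and sign boards for
conditioning stimuli. Tasks are plain YAML files; experiments are episodes.

## The model in brief

At each step the agent takes one of nine discrete actions — the cross of
{no force, forward, backward} × {no turn, 6° left, 6° right}. Cumulative
reward *R* evolves as

```
R_T = Σ_contacts (± v_i)  −  (steps outside hot zones)/t  −  10·(steps inside hot zones)/t
```

where *t* is the arena's `timeLimit` (no decrement when *t* = 0) and a
goal's valence *v* equals its diameter. Death-zone contact contributes
exactly −1 and ends the episode. Health starts at 100, changes by 100 points
per unit of reward (a 0.5 goal restores 50), is clamped to [0, 100], and
fails the episode at 0. An episode is a *pass* iff `R_T ≥ passMark`.

Observations are any combination of: an `8 × r` raycast matrix (r odd; six
object-category rows, a no-hit flag, and normalised distance), a flat-shaded
`k × k` ray-grid camera image (4 ≤ k ≤ 512, RGB or grayscale), and
proprioception (health, velocity, position), with scheduled lights-out
periods zeroing all visual values. Everything — placement, dispenser drops,
button draws, policies — is a pure function of the configuration and a seed.

## Worked example: foraging above chance

The built-in foraging task puts a spawner tree at the arena centre that
drops ten size-2 `GoodGoalMulti` goals; the agent starts at a random *x* on
the `z = 5` line. The heuristic raycast forager (45 rays over the frontal
60°) steers toward the nearest positive-goal ray; the random-action agent
defines chance performance.

```r
library(arenalab)

log <- run_episode(heuristic_policy("forager"), build_foraging_task(),
                   seed = 1, max_steps = 300)
glance(log)
#> # A tibble: 1 × 5
#>   steps final_reward final_health outcome termination_cause
#>   <int>        <dbl>        <dbl> <chr>   <chr>
#> 1   250         19.0         84.4 pass    timeout

res <- run_battery(
  agents = list(random = random_policy(), forager = heuristic_policy("forager")),
  configs = list(foraging = build_foraging_task()),
  episodes_per_config = 10, seed = 1, max_steps = 300)
chance_summary(res)
#> # A tibble: 2 × 5
#>   agent   episodes median_reward   q25   q75
#>   <chr>      <int>         <dbl> <dbl> <dbl>
#> 1 forager       10         19.0  19.0  19.0
#> 2 random        10         -1.00 -1.00 -1.00
```

The forager collects nearly the whole crop (ten goals of valence 2, minus
the per-step decrement: 20 − 250/250 = 19), while the random agent's reward
just runs down to −1 by timeout — the chance floor. `autoplot(log)` draws
the bird's-eye trajectory, `autoplot(res)` the score distributions, and
`pass_rate_by_level(res)` tabulates pass proportions.

The calibrated ramp rule can be probed behaviourally:

```r
probe_ramp_climbability()
#> # A tibble: 5 × 4
#>   ratio height climbed max_elevation
#>   <dbl>  <dbl> <lgl>           <dbl>
#> 1   1        2 TRUE             1.95
#> 2   2        4 TRUE             3.94
#> 3   4        8 TRUE             7.76
#> 4   4.5      9 FALSE            0
#> 5   8       16 FALSE            0
```

Other entry points: `parse_config()`/`write_config()` for the YAML schema,
`resolve_randomness()` + `place_with_precedence()` for deterministic
placement, `build_operant_task()` and `build_curriculum()` for the
operant-chamber task and its five-stage shaping curriculum,
`generate_configs()` for the procedural template DSL, `oracle_policy()` for
scripted reference solvers, and `testbed_manifest()` for the 10 × 30 × 3
battery structure. A thin command-line front end lives at
`inst/cli/arenalab.R` (`validate`, `resolve`, `run`, `gen`, `task`,
`battery`).

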