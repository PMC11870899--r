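---
title: "arenalab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arenalab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenalab)
```

## What arenalab simulates

arenalab is a headless, deterministic-under-seed, discrete-time arena
simulator for comparative-cognition-style experiments on computational
agents. The experimental setting it emulates is the classical animal
laboratory: a single subject (a spherical agent of diameter 1) is placed in
an enclosed 40 x 40-unit arena populated with task apparatus — walls, ramps
and tunnels; pushable blocks of varying mass; appetitive and aversive
"goals" (valenced spheres) and zones; fruit-dropping trees and goal
dispensers; a pressable button (an operant-chamber lever analogue); and
two-dimensional sign boards for conditioning stimuli. The subject acts in
discrete time to maximise cumulative reward before the episode ends.

Everything is driven from declarative YAML task configurations, so the same
file format describes a single hand-built task, a procedurally generated
battery of hundreds of variants, or a multi-arena curriculum.

## Coordinates, time, and the reward model

Coordinates are `(x, y, z)` with `y` vertical; the floor is the `y = 0`
plane and placements must keep footprints inside `[0, 40]^2`. Time is
discrete: one agent action per step, one physics substep per step.

Reward starts at 0. With a positive step budget `t` (`timeLimit`), every
step adds `-1/t`; inside a hot zone the decrement is ten times faster
(`-10/t`, *replacing* the base rate — the factor of ten is read as the total
rate relative to time alone). With `t = 0` there is no decrement and no
timeout. Contacting a valenced sphere adds its signed valence; valence
equals the sphere's diameter (proportionality constant 1), which is anchored
by the health conversion below. A death zone adds exactly -1 and ends the
episode. `GoodGoal`/`BadGoal` end the episode on contact; their `Multi`
variants, the decoy, and all time-varying goals do not.

Health is an interpretable transform of reward flow: it starts at 100, moves
by 100 health points per unit of reward change (so a 0.5-valence goal
restores 50), is clamped to `[0, 100]`, and ends the episode in failure at
0. Because the same factor applies to decrements, an episode with `t` steps
and no food runs health from 100 to 0 exactly at the timeout; arenalab
resolves that boundary in favour of *timeout* as the recorded cause. A
`passMark` per arena converts final reward into a pass/fail outcome
(`pass` iff `reward >= passMark`).

Time-varying goals use piecewise-linear schedules: flat at the initial
valence for `delay` steps, then linear over `duration` steps to the terminal
valence, clamped thereafter. Decay and ripen are mirror images; grow and
shrink apply the same interpolation to physical size (valence tracks current
size), and growth freezes while the surrounding space is blocked, resuming
when it frees.

## Physics: deliberately simple, exactly reproducible

The force catalogue this models is qualitative, not numeric; arenalab's
physics is therefore a desk-scale calibration rather than an engine
emulation, and determinism outranks realism. One semi-implicit Euler substep
per environment step; sphere-vs-box and sphere-vs-inclined-plane contacts
only; blocks translate without rotating.

The nine actions are the cross of {no force, forward, backward} x {no turn,
6 degrees left, 6 degrees right}; turns are exact 6-degree yaw increments.
The force model is: an applied-force impulse per forward/backward component;
constant gravity on `y`; drag proportional to body cross-section; Coulomb
ground friction; collision reaction impulses split in inverse proportion to
mass (so a mass-1 light block is displaced farther than a mass-2 heavy block
by the same push); and normal support. Bounce goals are frictionless with
restitution 1, so they reflect off walls at constant speed.

The constants live in one calibration table (`R/calibration.R`) and were
fixed once against two behavioural anchors:

* a forward-driving agent crosses the 40-unit arena in roughly 150 steps
  (steady per-step displacement 0.275 units);
* ramps are climbable iff their height:length ratio is at most 4:1.

Climbing works by contact with the ramp's inclined surface: uphill motion is
projected along the slope (scaled by `cos` of the slope angle) and a
step-up gate blocks any rise of more than 0.45 units in one stride, which
makes steep faces — and ramps past the 4:1 ratio, which are additionally
gated outright — behave as walls. `probe_ramp_climbability()` verifies the
rule behaviourally; its "reached the top" criterion allows a one-stride
(0.3-unit) shortfall because the final on-slope footfall lands below the
crest.

Hemi-cylindrical tunnels are approximated for collision by two side walls
and a ceiling slab, which preserves their task semantics (traversable
through the bore, an obstacle otherwise). Zones are entirely outside the
collision system, so a trajectory through a zone is bit-identical to the
same trajectory with the zone removed.

Known limitations: no torque or rolling, no block-vs-block impulse
resolution (blocks pushed into walls are clamped, not impulse-corrected),
and spheres do not collide with each other (goal-goal rest contacts are
ignored; agent-goal contact is collection, not collision).

## Observations

Three channels, usable in any combination:

* **Raycasts** — an `8 x r` matrix (`r` odd, enforced) of rays fanned evenly
  over a configurable span on the agent's horizontal plane, columns left to
  right with the centre ray dead ahead. The eight rows are arenalab's
  layout (only the matrix shape is fixed by convention): six one-hot object
  categories (positive goal, negative goal/zone, immovable, movable,
  dispenser/button, sign board), a no-hit flag, and distance normalised by
  the 60-unit ray range (the arena diagonal is about 56.6, so nothing
  in-range is ever clipped). The boundary fence is not a raycast target,
  which keeps the no-hit flag meaningful. Transparent walls and tunnels *do*
  register on raycasts while being invisible to the camera — a deliberate
  choice (a ray sensor is a collision probe, not a colour probe), worth
  keeping in mind when porting tasks from engines that resolve it the other
  way.
* **Camera** — a flat-shaded `k x k` ray-grid renderer (`4 <= k <= 512`,
  enforced), 60-degree field of view, each pixel taking the configured RGB
  of the nearest opaque surface or the floor/fence/sky constants; grayscale
  is standard luminance. No lighting, shadows, or textures: only pixel
  semantics matter here.
* **Proprioception** — health, velocity, and global position.

Lights-out windows (explicit `[start, end)` intervals or an alternating
period) zero every visual value; proprioception is unaffected; masking is
idempotent.

## Configurations, randomisation, and placement

`parse_config()`/`write_config()` round-trip the YAML schema exactly.
Randomisation is expressed either with the sentinel `-1` in a coordinate,
rotation, or colour channel, or with the canonical explicit token
`{random: {kind: ..., min: ..., max: ...}}`; `resolve_randomness()` resolves
all tokens as a pure function of `(spec, seed)` (positions uniform over the
legal area, rotations uniform over `[0, 360)`).

Placement follows precedence: the agent is always spawned first regardless
of its position in the file; remaining objects follow file order; any object
whose conservative yaw-aware bounding box intersects an already-placed solid
is re-spawned at a uniformly drawn free location (up to 100 attempts, then
an error naming the object). Zones never conflict. After placement,
`detect_overlaps()` is empty and every solid footprint lies inside the
arena. One YAML dialect note: bare `y` is a boolean in YAML 1.1, so the
parser deliberately keeps single-letter `y`/`n` as strings — the vertical
coordinate key parses as intended while real booleans (`true`/`false`) are
untouched.

## The environment loop

`make_env()`/`env_reset()`/`env_step()` follow the episodic reset/step
contract: step returns the observation bundle, the reward increment,
`terminated`/`truncated` flags (never both), and an info list with position,
velocity, health, arena index, and outcome. During the first
`frozenAgentDelays` steps the agent is immobilised, no decrement applies,
and other objects keep moving — the subject watches the scene before acting.
Dispenser schedules are precomputed per episode (deterministic under seed):
trees drop their crop at randomised within-interval times onto a canopy
annulus (radius 1.3 to 2 around the trunk — an annulus rather than a disc so
fruit never comes to rest on the trunk, where it would be uncollectable);
dispensers emit on the exact schedule at their hatch. Button presses are
contact events on the button's front face only, subject to a cooldown.

In multi-arena episodes, collecting an episode-ending goal advances to the
next arena with cumulative reward and health carried over (the advance rule
is arenalab's convention for hierarchical curricula), while death zones, health failure, and timeout end the whole episode.

Every episode yields a tidy log (one row per step: position, action,
cumulative reward, health) with `tidy()`, `glance()`, and `autoplot()`
methods; the accounting identity `final reward = sum of per-step deltas`
holds exactly and is asserted in the tests.

## Agents

* **Random-action agent** (chance reference): draws an action from nine
  weights (uniform by default) and repeats it for a number of steps drawn
  from a clipped normal — mean 5, sd 1, rounded, clipped at 1 (clipping
  after rounding is arenalab's reading of "a positive number"). An optional
  `correlation` parameter mixes an exponential recency weighting of past
  choices into the draw, implementing action autocorrelation; the mechanism
  (decay 0.8 per draw) is arenalab's, since only the capability is named.
* **Heuristic raycast navigators**: the forager steers towards the nearest
  positive-goal ray (centre ray forward, left of centre forwards-left,
  right of centre forwards-right), rotates left when nothing is visible,
  and when stuck (speed under 0.01 units/step across a 5-step window) picks
  forwards-left or forwards-right with probability one half until speed
  recovers. The operant variant steers towards button, goal, and immovable
  categories, repeats its previous action when nothing is detected, and
  moves forwards-left when stationary. Raycasts carry category only, so the
  operant navigator genuinely cannot tell which side of the button is the
  pressable face — a faithful limitation.
* **Scripted oracles** (privileged full-state reference solvers): greedy
  nearest-goal pursuit for foraging; for the operant chamber, drive to the
  button's front face, press, then detour around the enclosure to the
  spawned goal.

## Built-in tasks, generation, and evaluation

`build_foraging_task()` places a spawner tree at (20, 0, 20) dropping ten
size-2 `GoodGoalMulti` goals, with the agent at a random x on the `z = 5`
line and a random initial rotation. Values the task leaves open were fixed
once: `timeLimit` 250 (health then runs out exactly at the timeout for an
unfed agent), `passMark` 5 (at least three goals net of the decrement), tree
delay 10 and inter-drop interval 15 (the full crop is down by step ~160,
comfortably within the budget).

`build_operant_task(stage)` places the spawner button at (38.5, 0, 18.8)
facing the arena interior, enclosed by a rear wall flush against the
boundary and two side walls (the enclosure geometry is arenalab's choice;
only the button and goal positions are normative), spawning a size-1
`GoodGoal` at (39, 3, 22) on press. Stages 1-5 spawn the agent at
(36, 0, 20), (30, 0, 20), (20, 0, 20), (20, 0, z) with random z, and fully
random; stage 0 is the final task. `build_curriculum()` assembles cumulative
stages with earlier configurations interleaved round-robin.

The template DSL (`parse_template()`/`generate_configs()`) supports fixed
lists, numeric ranges, random colours, and conditional R expressions over
previously declared choices (declaration order is the dependency order), so
constraints like "ramp height at most four times ramp length" propagate into
every generated file. `testbed_manifest()` enumerates the 10-level x
30-task x 3-variant battery structure with its level names;
`build_level_exemplar()` ships one illustrative, synthetic task generator
per level — these are not the battery's actual tasks.

`run_battery()` sweeps agents x configurations x episodes with derived
per-episode seeds and returns a tidy table; `pass_rate_by_level()` and
`chance_summary()` are exact tabulations on it. Rank-based hypothesis tests
across agents are deliberately not wrapped: the tables feed directly into
`stats::kruskal.test()` and friends.

## Determinism and numerical choices

All randomness flows through isolated RNG handles derived from the
environment seed (never the global RNG state), with separate streams for
resolution, placement, bounce directions, dispenser schedules, and button
draws, so an episode is a pure function of `(config, seed, action
sequence)` — bitwise, as asserted on serialised logs and world states.
Tolerances elsewhere are exact comparisons where the quantity is exact
(turn angles, decrement ratios, contact deltas) and small epsilons
(`1e-9`) where floating-point summation is involved.

## Problem sizes used in the test suite

The suite exercises the full stack at deliberately modest sizes, chosen as
the smallest that make the stochastic laws sharp: 90,000 action draws
(binomial standard error ~0.001 per action against a +-0.005 band), 10,000
repeat-length and coin-flip draws, 30,000 button presses, and 100 episodes
per agent for the forager-vs-chance ordering (the medians differ by ~20
reward units, so the ordering is far outside sampling noise). What passing
these tests shows is that the *mechanics* are exact and the baselines
behave as specified on the built-in tasks; it says nothing about trained
learners, rendering fidelity, or the contents of the full 900-task battery,
all of which are out of scope.
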