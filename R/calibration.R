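# Physics calibration constants.
#
# The simulator is desk-scale and deterministic: one semi-implicit Euler
# substep per environment step, sphere-vs-box contacts, no rotational
# dynamics. The force magnitudes below are arenalab-defined; they were fixed
# once against two behavioural anchors: (i) a forward-driving agent crosses
# the 40-unit arena in roughly 150 steps, and (ii) the agent ascends exactly
# those ramps whose height:length ratio does not exceed 4:1 (the climbability
# rule, which is additionally enforced as a hard gate so the printed rule is
# exact).

PHYS <- list(
  gravity   = 0.05,  # per-step downward velocity increment (units/step^2)
  force     = 0.065, # applied-force impulse per Forwards/Backwards component
  drag      = 0.20,  # per-step multiplicative horizontal velocity loss, scaled by size
  friction  = 0.01,  # per-step Coulomb speed decrement while grounded
  step_up   = 0.45,  # maximum walkable rise per step; taller faces block
  bounce_speed = 0.3,  # default initial speed of *Bounce goals (units/step)
  ray_max   = 60     # raycast range; normalising constant for ray distances
)

# steady-state speed implied by the constants above: post-drag velocity
# v = (force * (1 - drag) - friction) / drag = 0.21, so the per-step
# displacement while driving is v + force = 0.275 units/step
# => 40-unit traversal in roughly 150 driven steps.
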