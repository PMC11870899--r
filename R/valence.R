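#' Reward and health accounting
#'
#' Cumulative reward starts at 0 and decreases by `1/t` per step when the
#' episode has a positive step budget `t` (`timeLimit`); inside a hot zone the
#' decrement is ten times faster, replacing the base rate. When `t = 0` there
#' is no per-step decrement. Contact with valenced objects adds or subtracts
#' their current valence (valence equals the sphere's size; time-varying goals
#' follow their schedule). Health starts at 100, moves by 100 health points per
#' unit of reward change, is clamped to `[0, 100]`, and ends the episode in
#' failure when it reaches 0.
#'
#' @param in_hot_zone Is the agent inside a hot zone this step?
#' @param t The arena `timeLimit` (0 disables the decrement).
#' @return `step_reward_delta()`: the per-step reward increment (<= 0).
#' @name valence
NULL

#' @rdname valence
#' @export
step_reward_delta <- function(in_hot_zone, t) {
  if (t < 0) stop("timeLimit must be >= 0", call. = FALSE)
  if (t == 0) return(0)
  if (in_hot_zone) -10 / t else -1 / t
}

#' @rdname valence
#' @param goal_kind An object kind from [ontology()].
#' @param valence The goal's current valence magnitude (its size for static
#'   goals, the scheduled value for ripening/decaying goals).
#' @return `on_contact()`: a list with `reward_delta`, `terminate`, `remove`.
#' @export
on_contact <- function(goal_kind, valence) {
  info <- kind_info(goal_kind)
  if (goal_kind == "DeathZone") {
    return(list(reward_delta = -1, terminate = TRUE, remove = FALSE))
  }
  if (goal_kind == "HotZone") {
    return(list(reward_delta = 0, terminate = FALSE, remove = FALSE))
  }
  if (!info$category %in% c("goal_positive", "goal_negative")) {
    stop("'", goal_kind, "' is not a valenced object", call. = FALSE)
  }
  list(reward_delta = info$valence_sign * valence,
       terminate = info$episode_ending,
       remove = TRUE)
}

## ---- schedules -------------------------------------------------------------

goal_schedule <- function(mode, full, empty, delay = 0, duration = 100,
                          start_size = NULL, end_size = NULL) {
  stopifnot(mode %in% c("static", "decay", "ripen", "grow", "shrink"))
  if (delay < 0) stop("schedule delay must be >= 0", call. = FALSE)
  if (mode != "static" && duration < 1) {
    stop("schedule duration must be >= 1", call. = FALSE)
  }
  structure(list(mode = mode, full = full, empty = empty,
                 delay = delay, duration = duration,
                 start_size = start_size, end_size = end_size),
            class = "goal_schedule")
}

# linear ramp from a to b, flat before delay, clamped at the terminal value
sched_interp <- function(a, b, delay, duration, step) {
  if (step <= delay) return(a)
  frac <- clamp((step - delay) / duration, 0, 1)
  a + (b - a) * frac
}

#' @rdname valence
#' @param s A goal schedule (internal representation of the `special`
#'   parameters `fullValence`, `emptyValence`, `delay`, `duration`).
#' @param steps_since_spawn Steps elapsed since the goal appeared.
#' @return `scheduled_valence()`: the goal's current valence.
#' @export
scheduled_valence <- function(s, steps_since_spawn) {
  stopifnot(inherits(s, "goal_schedule"), steps_since_spawn >= 0)
  switch(s$mode,
    static = s$full,
    decay = ,
    shrink = sched_interp(s$full, s$empty, s$delay, s$duration, steps_since_spawn),
    ripen = ,
    grow = sched_interp(s$empty, s$full, s$delay, s$duration, steps_since_spawn)
  )
}

#' @rdname valence
#' @param space_free Is there room for the goal to grow? Growth is frozen
#'   (size held at its last unblocked value) while `FALSE`.
#' @param last_size The size at the last unblocked step (used when blocked).
#' @return `scheduled_size()`: the goal's current diameter.
#' @export
scheduled_size <- function(s, steps_since_spawn, space_free = TRUE,
                           last_size = NULL) {
  stopifnot(inherits(s, "goal_schedule"))
  if (!s$mode %in% c("grow", "shrink")) {
    stop("scheduled_size applies to grow/shrink goals only", call. = FALSE)
  }
  if (!space_free) return(last_size %||% s$start_size)
  sched_interp(s$start_size, s$end_size, s$delay, s$duration, steps_since_spawn)
}

#' @rdname valence
#' @param health Current health in `[0, 100]`.
#' @param reward_delta The reward change this step.
#' @return `update_health()`: a list with the new `health` and a `failed`
#'   flag (health reached 0).
#' @export
update_health <- function(health, reward_delta) {
  stopifnot(health >= 0, health <= 100)
  h <- clamp(health + 100 * reward_delta, 0, 100)
  list(health = h, failed = h <= 0)
}

#' @rdname valence
#' @param reward Final cumulative episode reward.
#' @param pass_mark The arena `passMark`.
#' @return `episode_outcome()`: `"pass"` iff `reward >= pass_mark`.
#' @export
episode_outcome <- function(reward, pass_mark) {
  if (reward >= pass_mark) "pass" else "fail"
}
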