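#' Create an episodic arena environment
#'
#' The environment follows the familiar episodic reset/step contract:
#' [env_reset()] returns the first observation; [env_step()] advances one
#' step and returns the observation, the reward increment, termination and
#' truncation flags, and an info list. Episodes end on collecting an
#' episode-ending goal, death-zone contact, health reaching zero, or timeout
#' (truncation at `timeLimit` when it is positive). Everything is
#' deterministic under `(config, seed, action sequence)`.
#'
#' During the first `frozenAgentDelays` steps of an arena the agent is
#' immobilised: its action is ignored, no per-step reward decrement applies,
#' and all other objects continue to move and interact.
#'
#' In `multi-arena-single-episode` mode, collecting an episode-ending goal
#' advances the agent to the next arena (cumulative reward and health carry
#' over) instead of ending the episode; death zones, health failure and
#' timeout end the whole episode. The episode ends after the last arena.
#'
#' @param cfg An `arena_config`.
#' @param observations Which channels to return: a list with any of
#'   `raycast = list(r, angle_span)`, `camera = list(k, grayscale)`,
#'   `proprio = TRUE`. At least one channel must be enabled.
#' @param seed Integer seed controlling all environment randomness.
#' @return An `arena_env` handle (a stateful environment object).
#' @export
#' @examples
#' cfg <- arena_config(arena_spec(list(item_spec("Agent",
#'   positions = list(list(x = 20, y = 0, z = 20)))), time_limit = 50))
#' env <- make_env(cfg, seed = 1)
#' obs <- env_reset(env)
#' res <- env_step(env, "Forwards")
#' res$reward_delta
make_env <- function(cfg,
                     observations = list(raycast = list(r = 45, angle_span = 60),
                                         proprio = TRUE),
                     seed = 0L) {
  stopifnot(inherits(cfg, "arena_config"))
  if (!length(cfg$arenas)) stop("configuration has no arenas", call. = FALSE)
  if (!any(c("raycast", "camera", "proprio") %in% names(observations))) {
    stop("at least one observation channel must be enabled", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$cfg <- cfg
  env$obs_spec <- observations
  env$seed <- as.integer(seed)
  env$active <- FALSE
  class(env) <- "arena_env"
  env
}

#' @export
print.arena_env <- function(x, ...) {
  cat("<arena_env> ", length(x$cfg$arenas), " arena(s), seed ", x$seed,
      if (isTRUE(x$active)) ", episode active" else "", "\n", sep = "")
  invisible(x)
}

load_arena <- function(env, pos) {
  spec <- env$cfg$arenas[[pos]]
  s <- env$seed
  concrete <- resolve_randomness(spec, derive_seed(s, pos, 1L))
  has_agent <- any(vapply(concrete$items, function(it) it$name == "Agent", logical(1)))
  if (!has_agent) {
    rngA <- rng_new(derive_seed(s, pos, 6L))
    concrete$items <- c(concrete$items, list(
      list(name = "Agent",
           position = vec3(rng_runif(rngA, 1, 0.5, ARENA_SIZE - 0.5), 0,
                           rng_runif(rngA, 1, 0.5, ARENA_SIZE - 0.5)),
           rotation = rng_runif(rngA, 1, 0, 360),
           size = vec3(1, 1, 1), color = NULL, special = list())))
  }
  placed <- place_with_precedence(concrete, derive_seed(s, pos, 2L))
  env$world <- world_init(placed, derive_seed(s, pos, 3L))
  env$arena <- placed
  env$arena_pos <- pos
  env$step_in_arena <- 0L
  env$next_body_id <- length(env$world$bodies)
  # precompute deterministic dispenser schedules for this arena
  rngS <- rng_new(derive_seed(s, pos, 4L))
  scheds <- list()
  for (b in env$world$bodies) {
    kind_map <- c(SpawnerTree = "tree", SpawnerDispenserTall = "dispenserTall",
                  SpawnerDispenserShort = "dispenserShort")
    if (b$kind %in% names(kind_map)) {
      sp <- b$special
      scheds[[length(scheds) + 1L]] <- spawn_schedule(
        list(kind = kind_map[[b$kind]],
             count = sp$count %||% 0, delay = sp$delay %||% 0,
             interval = sp$interval %||% 25, goalSize = sp$goalSize %||% 1,
             position = vec3(b$x, b$y, b$z), rotation = b$yaw,
             size = c(b$sx, b$sy, b$sz)),
        rngS)
    }
  }
  env$spawn_events <- if (length(scheds)) dplyr::bind_rows(scheds) else
    tibble::tibble(step = integer(), kind = character(), x = numeric(),
                   y = numeric(), z = numeric(), size = numeric())
  env$button_rng <- rng_new(derive_seed(s, pos, 5L))
  env$button_last_press <- list()
  invisible(env)
}

#' @rdname make_env
#' @param env An `arena_env`.
#' @param arena_index Optional arena to start from (1-based position in the
#'   config; defaults to the first).
#' @return `env_reset()`: the initial observation bundle.
#' @export
env_reset <- function(env, arena_index = NULL) {
  stopifnot(inherits(env, "arena_env"))
  load_arena(env, arena_index %||% 1L)
  env$reward <- 0
  env$health <- 100
  env$step_total <- 0L
  env$terminated <- FALSE
  env$truncated <- FALSE
  env$cause <- "none"
  env$outcome <- NA_character_
  env$log <- list()
  env$active <- TRUE
  build_observation(env)
}

# current valence magnitude of a goal body
body_valence <- function(b, step) {
  if (is.null(b$schedule)) return(b$sx)
  if (b$schedule$mode %in% c("decay", "ripen")) {
    return(scheduled_valence(b$schedule, max(0L, step - b$spawn_step)))
  }
  b$sx  # grow/shrink: valence proportional to current size
}

spawn_goal_body <- function(env, kind, x, y, z, size) {
  env$next_body_id <- env$next_body_id + 1L
  b <- new_body(kind, vec3(x, y, z), 0, vec3(size, size, size),
                spawn_step = env$step_in_arena, id = env$next_body_id)
  env$world$bodies[[length(env$world$bodies) + 1L]] <- b
  invisible(env)
}

update_scheduled_goals <- function(env) {
  bodies <- env$world$bodies
  for (i in seq_along(bodies)) {
    b <- bodies[[i]]
    if (is.null(b$schedule) || !b$schedule$mode %in% c("grow", "shrink")) next
    steps <- max(0L, env$step_in_arena - b$spawn_step)
    target <- scheduled_size(b$schedule, steps, TRUE)
    if (target < b$sx || space_free_for(env, b, target)) {
      grow <- target - b$sx
      b$sx <- target; b$sy <- target; b$sz <- target
      if (grow > 0) b$y <- b$y  # grows in place, resting on its base
      bodies[[i]] <- b
    }
  }
  env$world$bodies <- bodies
  invisible(env)
}

space_free_for <- function(env, b, diameter) {
  r <- diameter / 2
  for (o in env$world$bodies) {
    if (o$id == b$id || !o$solid || o$zone) next
    if (is_sphere(o)) {
      d2 <- (b$x - o$x)^2 + (b$z - o$z)^2
      if (d2 < (r + body_radius(o))^2) return(FALSE)
    } else if (!is.null(sphere_body_mtv(b$x, b$y + r, b$z, r, o))) {
      return(FALSE)
    }
  }
  TRUE
}

#' @rdname make_env
#' @param action One of [actions()].
#' @return `env_step()`: a list with `observation`, `reward_delta`,
#'   `terminated`, `truncated`, and `info` (position, velocity, health,
#'   arena index, outcome).
#' @export
env_step <- function(env, action = "NoAction") {
  stopifnot(inherits(env, "arena_env"))
  if (!isTRUE(env$active)) {
    stop("episode is over; call env_reset() first", call. = FALSE)
  }
  spec <- env$arena
  frozen <- env$step_in_arena < spec$frozen_agent_delays
  env$world <- step_world(env$world, action, frozen = frozen)
  env$step_in_arena <- env$step_in_arena + 1L
  env$step_total <- env$step_total + 1L
  update_scheduled_goals(env)
  ev <- env$world$events

  delta <- 0
  remove_ids <- integer(0)
  terminated <- FALSE
  cause <- "none"
  # goal contacts
  for (id in ev$goal_contacts) {
    b <- body_by_id(env$world, id)
    hit <- on_contact(b$kind, body_valence(b, env$step_in_arena))
    delta <- delta + hit$reward_delta
    if (hit$remove) remove_ids <- c(remove_ids, id)
    if (hit$terminate && !terminated) {
      terminated <- TRUE; cause <- "goal"
    }
  }
  # zones (death takes precedence over hot)
  if (ev$in_death) {
    hit <- on_contact("DeathZone", NA)
    delta <- delta + hit$reward_delta
    terminated <- TRUE; cause <- "deathzone"
  }
  # per-step decrement (suspended while frozen)
  if (!frozen) {
    delta <- delta + step_reward_delta(ev$in_hot && !ev$in_death, spec$time_limit)
  }
  # dispensers and button presses
  due <- tick_spawner(env$spawn_events, env$step_in_arena)
  if (nrow(due)) {
    for (k in seq_len(nrow(due))) {
      spawn_goal_body(env, due$kind[k], due$x[k], due$y[k], due$z[k], due$size[k])
    }
  }
  for (id in ev$button_presses) {
    b <- body_by_id(env$world, id)
    key <- as.character(id)
    last <- env$button_last_press[[key]] %||% -Inf
    since <- env$step_in_arena - last
    sp <- b$special
    res <- press_button(list(
      spawnProbability = sp$spawnProbability %||% 1,
      weights = sp$weights %||% list(GoodGoal = 1, GoodGoalMulti = 1, BadGoal = 1),
      spawnPosition = sp$spawnPosition %||% c(b$x, 1, b$z + 2),
      resetSteps = sp$resetSteps %||% 20,
      goalSize = sp$goalSize %||% 1), since, env$button_rng)
    if (since >= (sp$resetSteps %||% 20)) {
      env$button_last_press[[key]] <- env$step_in_arena
    }
    if (!is.null(res)) {
      spawn_goal_body(env, res$kind, res$x, res$y, res$z, res$size)
    }
  }
  if (length(remove_ids)) {
    keep <- vapply(env$world$bodies, function(b) !(b$id %in% remove_ids), logical(1))
    env$world$bodies <- env$world$bodies[keep]
  }

  env$reward <- env$reward + delta
  hu <- update_health(env$health, delta)
  env$health <- hu$health
  if (hu$failed && !terminated) {
    terminated <- TRUE; cause <- "healthZero"
  }
  truncated <- FALSE
  # reaching the step budget truncates; if health hits zero on that same
  # final step, the episode still counts as a timeout
  if ((!terminated || cause == "healthZero") && spec$time_limit > 0 &&
      env$step_in_arena >= spec$time_limit) {
    truncated <- TRUE; terminated <- FALSE; cause <- "timeout"
  }

  # multi-arena advance: an episode-ending goal moves to the next arena
  multi <- env$cfg$episode_mode == "multi-arena-single-episode"
  if (terminated && cause == "goal" && multi &&
      env$arena_pos < length(env$cfg$arenas)) {
    load_arena(env, env$arena_pos + 1L)
    terminated <- FALSE
    cause <- "none"
  }

  env$terminated <- terminated
  env$truncated <- truncated
  env$cause <- if (terminated || truncated) cause else "none"
  if (terminated || truncated) {
    env$active <- FALSE
    env$outcome <- episode_outcome(env$reward, spec$pass_mark)
  }
  ag <- env$world$bodies[[1]]
  env$log[[length(env$log) + 1L]] <- list(
    step = env$step_total, arena = env$arena_pos - 1L, action = action,
    x = ag$x, y = ag$y, z = ag$z, reward = env$reward, health = env$health,
    reward_delta = delta)
  list(observation = build_observation(env),
       reward_delta = delta,
       terminated = terminated,
       truncated = truncated,
       info = list(position = c(x = ag$x, y = ag$y, z = ag$z),
                   velocity = c(x = ag$vx, y = ag$vy, z = ag$vz),
                   health = env$health,
                   arena_index = env$arena_pos - 1L,
                   outcome = env$outcome))
}

body_by_id <- function(world, id) {
  for (b in world$bodies) if (b$id == id) return(b)
  NULL
}

build_observation <- function(env) {
  spec <- env$obs_spec
  out <- list()
  if (!is.null(spec$raycast)) {
    out$raycast <- raycast_scan(env$world,
                                r = spec$raycast$r %||% 45,
                                angle_span = spec$raycast$angle_span %||% 60)
  }
  if (!is.null(spec$camera)) {
    out$camera <- render_camera(env$world,
                                k = spec$camera$k %||% 32,
                                grayscale = isTRUE(spec$camera$grayscale))
  }
  out <- apply_lights_out(out, env$arena$lights_out, env$step_in_arena)
  if (isTRUE(spec$proprio)) {
    out$proprio <- proprio_obs(env$world, env$health)
  }
  out
}

#' Extract the episode log
#'
#' One row per step taken: step index, arena index, action, agent position,
#' cumulative reward and health. The outcome (`pass`/`fail` against the
#' arena's `passMark`) and the termination cause are attached as attributes
#' and surfaced by [glance.arena_episode_log()].
#'
#' @param env An `arena_env` after an episode.
#' @return An `arena_episode_log` tibble.
#' @export
episode_log <- function(env) {
  stopifnot(inherits(env, "arena_env"))
  rows <- env$log %||% list()
  log <- if (length(rows)) {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    tibble::tibble(step = integer(), arena = integer(), action = character(),
                   x = numeric(), y = numeric(), z = numeric(),
                   reward = numeric(), health = numeric(),
                   reward_delta = numeric())
  }
  structure(log, outcome = env$outcome, termination_cause = env$cause,
            final_reward = env$reward, final_health = env$health,
            class = c("arena_episode_log", class(log)))
}

#' Run one full episode under a policy
#'
#' Drives reset/step with the given policy until termination or truncation
#' (or `max_steps`, a safety cap for unbounded `timeLimit = 0` episodes) and
#' returns the complete [episode_log()].
#'
#' @param policy A policy from [random_policy()], [heuristic_policy()],
#'   [oracle_policy()], or any list with fields `needs` (subset of
#'   `"raycast"`, `"camera"`, `"proprio"`, `"state"`), `init(rng)` and
#'   `act(obs, info, memory, rng)`.
#' @param cfg An `arena_config`.
#' @param seed Integer seed (environment and policy randomness).
#' @param max_steps Hard cap on steps (default 1000).
#' @param observations Override the observation channels (defaults follow the
#'   policy's `needs`).
#' @return An `arena_episode_log` tibble.
#' @export
run_episode <- function(policy, cfg, seed = 0L, max_steps = 1000L,
                        observations = NULL) {
  if (is.null(observations)) {
    observations <- list()
    if ("raycast" %in% policy$needs) {
      observations$raycast <- policy$raycast %||% list(r = 45, angle_span = 60)
    }
    if ("camera" %in% policy$needs) observations$camera <- list(k = 32)
    observations$proprio <- TRUE
  }
  env <- make_env(cfg, observations = observations, seed = seed)
  obs <- env_reset(env)
  rng <- rng_new(derive_seed(seed, 97L))
  memory <- if (!is.null(policy$init)) policy$init(rng) else NULL
  info <- NULL
  for (k in seq_len(max_steps)) {
    if ("state" %in% policy$needs) obs$world <- env$world
    step_info <- list(world = if ("state" %in% policy$needs) env$world,
                      health = env$health,
                      velocity = c(env$world$bodies[[1]]$vx,
                                   env$world$bodies[[1]]$vy,
                                   env$world$bodies[[1]]$vz))
    dec <- policy$act(obs, step_info, memory, rng)
    memory <- dec$memory
    res <- env_step(env, dec$action)
    obs <- res$observation
    if (res$terminated || res$truncated) break
  }
  episode_log(env)
}
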