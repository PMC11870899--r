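#' Random-action agents
#'
#' The random agent simulates chance performance. Each time its repeat
#' counter is exhausted it draws a new action in proportion to
#' `action_weights` (optionally blended with an exponential recency weighting
#' of its own past choices when `correlation > 0`), together with a new
#' repeat length. The default repeat distribution is the number of steps
#' drawn from a normal with mean 5 and standard deviation 1, rounded to the
#' nearest integer and clipped to be at least 1.
#'
#' @param action_weights Nine non-negative weights over [actions()]
#'   (default uniform).
#' @param repeat_dist One of `list(kind = "normal", mean, sd)`,
#'   `list(kind = "fixed", n)`, or `list(kind = "geometric", p)`.
#' @param correlation In `[0, 1)`: weight given to recently chosen actions
#'   when drawing the next one (0 = independent draws).
#' @return A policy object usable with [run_episode()].
#' @export
random_policy <- function(action_weights = rep(1, 9),
                          repeat_dist = list(kind = "normal", mean = 5, sd = 1),
                          correlation = 0) {
  params <- random_params(action_weights, repeat_dist, correlation)
  list(
    name = "random",
    needs = character(0),
    params = params,
    init = function(rng) NULL,
    act = function(obs, info, memory, rng) {
      out <- random_action(params, rng, memory)
      list(action = out$action, memory = out$memory)
    }
  )
}

random_params <- function(action_weights, repeat_dist, correlation) {
  if (length(action_weights) != 9 || any(action_weights < 0) ||
      sum(action_weights) <= 0) {
    stop("action_weights must be 9 non-negative weights with positive sum",
         call. = FALSE)
  }
  list(action_weights = action_weights, repeat_dist = repeat_dist,
       correlation = correlation)
}

#' @rdname random_policy
#' @param params A parameter list from inside `random_policy()` (fields
#'   `action_weights`, `repeat_dist`, `correlation`).
#' @param rng An RNG handle.
#' @param memory The policy memory (`NULL` on the first call).
#' @return `random_action()`: a list with `action` and the updated `memory`.
#' @export
random_action <- function(params, rng, memory = NULL) {
  if (is.null(memory)) {
    memory <- list(action = NULL, remaining = 0L, recency = rep(0, 9))
  }
  if (memory$remaining <= 0L) {
    w <- params$action_weights / sum(params$action_weights)
    if (params$correlation > 0 && sum(memory$recency) > 0) {
      rw <- memory$recency / sum(memory$recency)
      w <- (1 - params$correlation) * w + params$correlation * rw
    }
    memory$action <- rng_sample(rng, actions(), 1, prob = w)
    memory$remaining <- draw_repeat(params$repeat_dist, rng)
    memory$recency <- 0.8 * memory$recency
    ix <- match(memory$action, actions())
    memory$recency[ix] <- memory$recency[ix] + 1
  }
  memory$remaining <- memory$remaining - 1L
  list(action = memory$action, memory = memory)
}

draw_repeat <- function(dist, rng) {
  kind <- dist$kind %||% "normal"
  n <- switch(kind,
    normal = round(rng_rnorm(rng, 1, dist$mean %||% 5, dist$sd %||% 1)),
    fixed = dist$n %||% 5,
    geometric = 1 + rng_do(rng, function() stats::rgeom(1, dist$p %||% 0.2)),
    stop("unknown repeat distribution kind: '", kind, "'", call. = FALSE)
  )
  max(1L, as.integer(n))
}

#' @rdname random_policy
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return `random_repeat_lengths()`: an integer vector of `n` repeat-length
#'   draws from `repeat_dist` (rounded, clipped at 1).
#' @export
random_repeat_lengths <- function(n, repeat_dist = list(kind = "normal",
                                                        mean = 5, sd = 1),
                                  seed = 0L) {
  rng <- rng_new(seed)
  vapply(seq_len(n), function(i) draw_repeat(repeat_dist, rng), integer(1))
}

## ---- heuristic raycast navigators -----------------------------------------

#' Heuristic raycast agents
#'
#' Hand-coded navigators using raycast observations (by default 45 rays over
#' the frontal 60 degrees). The `forager` variant steers towards the nearest
#' positive-goal ray: centre ray means `Forwards`, a ray left of centre
#' `ForwardsLeft`, right of centre `ForwardsRight`; with no goal in view it
#' rotates left; when stuck (speed below `stuck_speed` over a 5-step window)
#' it moves `ForwardsLeft` or `ForwardsRight` with probability one half until
#' speed recovers. The `operant` variant steers towards button, positive-goal
#' and immovable rays; with nothing detected it repeats its previous action,
#' and when stationary it moves forwards-and-left. Raycasts carry category
#' only, so the operant navigator cannot tell which side of a button must be
#' pressed.
#'
#' @param variant `"forager"` or `"operant"`.
#' @param ray_count Odd ray count (default 45).
#' @param angle_span Fan width in degrees (default 60).
#' @param stuck_speed Speed threshold below which the agent counts as stuck.
#' @return A policy object usable with [run_episode()].
#' @export
heuristic_policy <- function(variant = c("forager", "operant"),
                             ray_count = 45, angle_span = 60,
                             stuck_speed = 0.01) {
  variant <- match.arg(variant)
  params <- list(variant = variant, ray_count = ray_count,
                 angle_span = angle_span, stuck_speed = stuck_speed)
  list(
    name = paste0("heuristic_", variant),
    needs = c("raycast", "proprio"),
    raycast = list(r = ray_count, angle_span = angle_span),
    params = params,
    init = function(rng) list(speeds = numeric(0), prev = "NoAction"),
    act = function(obs, info, memory, rng) {
      speed <- sqrt(sum(info$velocity[c(1, 3)]^2))
      out <- heuristic_action(obs$raycast, speed, params, memory, rng)
      list(action = out$action, memory = out$memory)
    }
  )
}

#' @rdname heuristic_policy
#' @param obs A `raycast_obs` of shape `8 x ray_count`.
#' @param agent_speed Current horizontal speed (units/step).
#' @param params Parameter list (fields as in `heuristic_policy()`).
#' @param memory Policy memory (`NULL` on first call).
#' @param rng An RNG handle (used only for stuck recovery).
#' @return `heuristic_action()`: a list with `action` and updated `memory`.
#' @export
heuristic_action <- function(obs, agent_speed, params, memory = NULL,
                             rng = rng_new(0)) {
  if (is.null(memory)) memory <- list(speeds = numeric(0), prev = "NoAction")
  r <- params$ray_count
  if (!is.matrix(obs) || nrow(obs) != 8 || ncol(obs) != r) {
    stop("raycast observation must be an 8 x ", r, " matrix", call. = FALSE)
  }
  memory$speeds <- tail(c(memory$speeds, agent_speed), 5)
  stuck <- length(memory$speeds) >= 5 && all(memory$speeds < params$stuck_speed)
  centre <- (r + 1) / 2
  steer <- function(targets) {
    hit <- which(targets & obs["no_hit", ] == 0)
    if (!length(hit)) return(NULL)
    best <- hit[which.min(obs["distance", hit])]
    if (best == centre) "Forwards"
    else if (best < centre) "ForwardsLeft"
    else "ForwardsRight"
  }
  if (params$variant == "forager") {
    if (stuck) {
      action <- if (rng_runif(rng, 1) < 0.5) "ForwardsLeft" else "ForwardsRight"
    } else {
      action <- steer(obs["goal_positive", ] == 1) %||% "Left"
    }
  } else {
    targets <- obs["dispenser", ] == 1 | obs["goal_positive", ] == 1 |
      obs["immovable", ] == 1
    if (agent_speed < params$stuck_speed && memory$prev != "NoAction") {
      action <- "ForwardsLeft"
    } else {
      action <- steer(targets) %||% memory$prev
      if (identical(action, "NoAction")) action <- "Forwards"
    }
  }
  memory$prev <- action
  list(action = action, memory = memory)
}

## ---- scripted oracles ------------------------------------------------------

#' Scripted oracle policies
#'
#' Near-optimal reference agents with privileged access to the full world
#' state, used as worked-example solvers: the `foraging` oracle greedily
#' pursues the nearest positive goal (waiting by the spawner tree before the
#' first drop); the `operant` oracle drives to the button's front face,
#' presses it, then detours around the enclosure walls to collect the
#' spawned goal. In an empty arena the oracle takes `NoAction` forever.
#'
#' @param task `"foraging"` or `"operant"`.
#' @return A policy object usable with [run_episode()].
#' @export
oracle_policy <- function(task = c("foraging", "operant")) {
  task <- match.arg(task)
  list(
    name = paste0("oracle_", task),
    needs = "state",
    init = function(rng) list(phase = "start", waypoints = list(),
                              speeds = numeric(0)),
    act = function(obs, info, memory, rng) {
      world <- info$world
      ag <- world$bodies[[1]]
      memory$speeds <- tail(c(memory$speeds, sqrt(ag$vx^2 + ag$vz^2)), 4)
      stuck <- length(memory$speeds) >= 4 && all(memory$speeds < 0.01)
      act <- if (task == "foraging") {
        oracle_forage(world, ag)
      } else {
        res <- oracle_operant(world, ag, memory)
        memory <- res$memory
        res$action
      }
      if (stuck && act != "NoAction") act <- "ForwardsLeft"
      list(action = act, memory = memory)
    }
  )
}

navigate_towards <- function(ag, tx, tz) {
  bearing <- atan2(tx - ag$x, tz - ag$z) * 180 / pi
  d <- yaw_diff(ag$yaw, bearing)
  if (d < -24) "Left"
  else if (d > 24) "Right"
  else if (d < -3) "ForwardsLeft"
  else if (d > 3) "ForwardsRight"
  else "Forwards"
}

oracle_forage <- function(world, ag) {
  goals <- Filter(function(b) b$category == "goal_positive" && !b$zone &&
                    b$valence_sign > 0, world$bodies[-1])
  if (length(goals)) {
    d2 <- vapply(goals, function(g) (g$x - ag$x)^2 + (g$z - ag$z)^2, numeric(1))
    g <- goals[[which.min(d2)]]
    return(navigate_towards(ag, g$x, g$z))
  }
  trees <- Filter(function(b) b$kind %in% c("SpawnerTree", "SpawnerDispenserTall",
                                            "SpawnerDispenserShort"),
                  world$bodies[-1])
  if (length(trees)) {
    tr <- trees[[1]]
    # wait just outside the canopy for the first drop
    wx <- tr$x; wz <- tr$z - 4
    if ((ag$x - wx)^2 + (ag$z - wz)^2 > 1) {
      return(navigate_towards(ag, wx, wz))
    }
    return("Left")
  }
  "NoAction"
}

oracle_operant <- function(world, ag, memory) {
  goal <- Filter(function(b) b$kind == "GoodGoal", world$bodies[-1])
  button <- Filter(function(b) b$kind == "SpawnerButton", world$bodies[-1])
  if (length(goal)) {
    g <- goal[[1]]
    if (length(memory$waypoints) == 0 && length(button)) {
      bt <- button[[1]]
      front <- local_to_world(0, 1, bt$yaw)
      # detour: out in front of the button, shifted laterally towards the goal
      lat <- c(g$x - bt$x, g$z - bt$z)
      lat <- lat - sum(lat * front) * front
      ln <- sqrt(sum(lat^2))
      if (ln > 0.5) {
        lat <- lat / ln
        w1 <- c(bt$x + front[1] * 3 + lat[1] * 3.5,
                bt$z + front[2] * 3 + lat[2] * 3.5)
        memory$waypoints <- list(w1, c(g$x, g$z))
      } else {
        memory$waypoints <- list(c(g$x, g$z))
      }
    }
    if (length(memory$waypoints) == 0) memory$waypoints <- list(c(g$x, g$z))
    w <- memory$waypoints[[1]]
    # retarget the final waypoint onto the (possibly rolling) goal
    if (length(memory$waypoints) == 1) w <- c(g$x, g$z)
    if ((ag$x - w[1])^2 + (ag$z - w[2])^2 < 0.8^2 && length(memory$waypoints) > 1) {
      memory$waypoints <- memory$waypoints[-1]
      w <- memory$waypoints[[1]]
    }
    return(list(action = navigate_towards(ag, w[1], w[2]), memory = memory))
  }
  if (length(button)) {
    bt <- button[[1]]
    front <- local_to_world(0, 1, bt$yaw)
    press <- c(bt$x + front[1] * (bt$sz / 2 + 1.1),
               bt$z + front[2] * (bt$sz / 2 + 1.1))
    d2 <- (ag$x - press[1])^2 + (ag$z - press[2])^2
    if (d2 > 0.6^2) {
      return(list(action = navigate_towards(ag, press[1], press[2]),
                  memory = memory))
    }
    # at the front face: push into the button
    return(list(action = navigate_towards(ag, bt$x, bt$z), memory = memory))
  }
  list(action = "NoAction", memory = memory)
}
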