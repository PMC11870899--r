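#' The nine discrete agent actions
#'
#' Movement is discrete: each step the agent chooses one of nine actions, the
#' cross of \{no force, forward force, backward force\} with \{no turn, 6
#' degrees left, 6 degrees right\}. The default action is `NoAction`.
#'
#' @return Character vector of the nine action names.
#' @export
actions <- function() {
  c("NoAction", "Forwards", "Left", "Right", "ForwardsLeft", "ForwardsRight",
    "Backwards", "BackwardsLeft", "BackwardsRight")
}

action_components <- function(action) {
  if (!action %in% actions()) stop("unknown action code: '", action, "'", call. = FALSE)
  fwd <- if (grepl("^Forwards", action)) 1 else if (grepl("^Backwards", action)) -1 else 0
  turn <- if (grepl("Left$", action)) -1 else if (grepl("Right$", action)) 1 else 0
  list(forward = fwd, turn = turn)
}

#' Apply an action to the agent body
#'
#' Left/Right components rotate the heading by exactly -6/+6 degrees;
#' Forwards/Backwards components add an applied-force impulse of fixed
#' magnitude along the (new) heading. `NoAction` leaves the body untouched.
#'
#' @param agent An agent body (see [world_init()]).
#' @param action One of [actions()].
#' @return The updated body.
#' @export
apply_action <- function(agent, action) {
  cmp <- action_components(action)
  agent$yaw <- norm_yaw(agent$yaw + 6 * cmp$turn)
  if (cmp$forward != 0) {
    h <- heading_vec(agent$yaw)
    agent$vx <- agent$vx + cmp$forward * PHYS$force * h[1]
    agent$vz <- agent$vz + cmp$forward * PHYS$force * h[2]
  }
  agent
}

#' Is a ramp climbable?
#'
#' Ramps can be climbed if and only if their height:length ratio does not
#' exceed 4:1. The physics step enforces the same rule as a hard gate, so a
#' forward-driving agent ascends exactly the climbable ramps (see
#' [probe_ramp_climbability()]).
#'
#' @param height Ramp height (arena units), `>= 0`.
#' @param length Ramp length along the slope direction (arena units), `> 0`.
#' @return `TRUE` iff `height / length <= 4`.
#' @export
is_ramp_climbable <- function(height, length) {
  if (length <= 0) stop("ramp length must be positive", call. = FALSE)
  if (height < 0) stop("ramp height must be non-negative", call. = FALSE)
  height / length <= 4 + 1e-12
}

## ---- bodies and world state ------------------------------------------------

new_body <- function(kind, position, rotation = 0, size = vec3(1, 1, 1),
                     color = NULL, special = list(), spawn_step = 0L, id = NA_integer_) {
  info <- kind_info(kind)
  p <- as_vec3(position); s <- as_vec3(size)
  if (is.null(color)) color <- list(r = info$r, g = info$g, b = info$b)
  sched <- NULL
  if (info$scheduled != "static") {
    sched <- goal_schedule(
      mode = info$scheduled,
      full = special$fullValence %||% s$x,
      empty = special$emptyValence %||% 0,
      delay = special$delay %||% 0,
      duration = special$duration %||% 100,
      start_size = special$startSize %||% s$x,
      end_size = special$endSize %||% s$x
    )
  }
  list(id = id, kind = kind, category = info$category,
       x = p$x, y = p$y, z = p$z, yaw = norm_yaw(rotation),
       sx = s$x, sy = s$y, sz = s$z,
       vx = 0, vy = 0, vz = 0,
       mass = info$mass, movable = info$movable, solid = info$solid,
       zone = info$zone, bounce = info$bounce,
       valence_sign = info$valence_sign, episode_ending = info$episode_ending,
       color = color, schedule = sched, spawn_step = as.integer(spawn_step),
       special = special)
}

is_sphere <- function(b) {
  b$kind == "Agent" || b$category %in% c("goal_positive", "goal_negative") && !b$zone
}

body_radius <- function(b) b$sx / 2

body_center_y <- function(b) b$y + b$sy / 2

#' Initialise a world state from a concrete arena
#'
#' Builds the dynamic state advanced by [step_world()]: the agent body first,
#' then one body per placed object, with Bounce goals given their initial
#' velocity (prespecified direction, or drawn uniformly when randomised).
#'
#' @param arena A placed `concrete_arena` (see [place_with_precedence()]).
#' @param seed Integer seed for initial Bounce directions.
#' @return A `world_state` list with fields `step` and `bodies`.
#' @export
world_init <- function(arena, seed = 0L) {
  stopifnot(inherits(arena, "concrete_arena"))
  rng <- rng_new(derive_seed(seed, 37L))
  agent <- NULL
  rest <- list()
  for (it in arena$items) {
    b <- new_body(it$name, it$position, it$rotation, it$size, it$color, it$special)
    if (it$name == "Agent") {
      if (!is.null(agent)) stop("arena contains more than one agent", call. = FALSE)
      agent <- b
    } else {
      rest[[length(rest) + 1L]] <- b
    }
  }
  if (is.null(agent)) stop("arena contains no agent", call. = FALSE)
  bodies <- c(list(agent), rest)
  for (i in seq_along(bodies)) {
    bodies[[i]]$id <- i
    b <- bodies[[i]]
    if (b$bounce) {
      dir <- b$special$direction %||% -1
      if (is.character(dir) || identical(as.numeric(dir), -1)) {
        dir <- rng_runif(rng, 1, 0, 360)
      }
      sp <- b$special$initialSpeed %||% PHYS$bounce_speed
      h <- heading_vec(as.numeric(dir))
      bodies[[i]]$vx <- sp * h[1]
      bodies[[i]]$vz <- sp * h[2]
    }
  }
  structure(list(step = 0L, bodies = bodies), class = "world_state")
}

## ---- geometry helpers ------------------------------------------------------

world_to_local <- function(dx, dz, yaw) {
  a <- deg2rad(yaw)
  c(dx * cos(a) - dz * sin(a), dx * sin(a) + dz * cos(a))
}

local_to_world <- function(lx, lz, yaw) {
  a <- deg2rad(yaw)
  c(lx * cos(a) + lz * sin(a), -lx * sin(a) + lz * cos(a))
}

# sub-boxes used for collision: most solids are one box; hemi-cylindrical
# tunnels are approximated by two side walls and a ceiling slab so the bore
# stays passable. Offsets/half-sizes are in the body's local frame.
collision_boxes <- function(b) {
  hx <- b$sx / 2; hy <- b$sy / 2; hz <- b$sz / 2
  if (b$kind %in% c("CylinderTunnel", "CylinderTunnelTransparent")) {
    t <- 0.15 * b$sx
    return(list(
      list(off = c(-hx + t / 2, hy, 0), half = c(t / 2, hy, hz)),
      list(off = c(hx - t / 2, hy, 0), half = c(t / 2, hy, hz)),
      list(off = c(0, hy * 1.75, 0), half = c(hx, hy * 0.25, hz))
    ))
  }
  list(list(off = c(0, hy, 0), half = c(hx, hy, hz)))
}

# is (x, z) inside body b's footprint (local frame)?
in_footprint <- function(b, x, z) {
  l <- world_to_local(x - b$x, z - b$z, b$yaw)
  abs(l[1]) <= b$sx / 2 & abs(l[2]) <= b$sz / 2
}

ramp_ratio <- function(b) b$sy / b$sz

# slope surface height at world (x, z); ramps ascend along local +z
ramp_height_at <- function(b, x, z) {
  l <- world_to_local(x - b$x, z - b$z, b$yaw)
  b$y + b$sy * clamp((l[2] + b$sz / 2) / b$sz, 0, 1)
}

is_climbable_ramp <- function(b) {
  b$kind == "Ramp" && is_ramp_climbable(b$sy, b$sz)
}

# highest walkable support under (x, z) for a body whose bottom is `bottom`
support_height <- function(bodies, self_id, x, z, bottom) {
  h <- 0
  for (o in bodies) {
    if (o$id == self_id || !o$solid || o$zone) next
    if (is_sphere(o)) next
    if (!in_footprint(o, x, z)) next
    top <- if (is_climbable_ramp(o)) ramp_height_at(o, x, z) else o$y + o$sy
    if (top > h && top <= bottom + PHYS$step_up) h <- top
  }
  h
}

# minimum translation vector for a sphere against a body's collision boxes;
# returns NULL or list(mtv = c(x, y, z), normal = c(x, y, z))
sphere_body_mtv <- function(cx, cy, cz, r, o) {
  best <- NULL
  for (box in collision_boxes(o)) {
    l <- world_to_local(cx - o$x, cz - o$z, o$yaw)
    lc <- c(l[1] - box$off[1], cy - (o$y + box$off[2]), l[2] - box$off[3])
    h <- box$half
    q <- clamp(lc, -h, h)
    d <- lc - q
    dist2 <- sum(d * d)
    if (dist2 > r * r) next
    if (dist2 > 1e-12) {
      dist <- sqrt(dist2)
      n_local <- d / dist
      depth <- r - dist
    } else {
      # centre inside the box: push out along the axis of least penetration
      pen <- h - abs(lc)
      ax <- which.min(pen)
      n_local <- c(0, 0, 0)
      n_local[ax] <- ifelse(lc[ax] >= 0, 1, -1)
      depth <- pen[ax] + r
    }
    nw <- local_to_world(n_local[1], n_local[3], o$yaw)
    normal <- c(nw[1], n_local[2], nw[2])
    if (is.null(best) || depth > best$depth) {
      best <- list(mtv = normal * depth, normal = normal, depth = depth)
    }
  }
  best
}

## ---- the transition function ----------------------------------------------

#' Advance the world by one physics step
#'
#' Applies, in order: the agent's action (turn and applied-force impulse),
#' gravity, integration, ramp climbing with the 4:1 gate, sphere-vs-box
#' collision resolution (movable blocks receive an impulse inversely
#' proportional to their mass; Bounce goals reflect), arena-wall containment,
#' then drag and ground friction. The transition is deterministic: identical
#' `(state, action)` give bitwise-identical successor states.
#'
#' Contact events for the reward layer are returned in the `events` field:
#' goal contacts, death/hot-zone occupancy, and button front-face presses.
#'
#' @param world A `world_state`.
#' @param action One of [actions()].
#' @param frozen If `TRUE` the agent is immobilised (action ignored) while
#'   other bodies continue to move.
#' @return The successor `world_state`, with `$events`.
#' @export
step_world <- function(world, action = "NoAction", frozen = FALSE) {
  stopifnot(inherits(world, "world_state"))
  bodies <- world$bodies
  if (!frozen) {
    bodies[[1]] <- apply_action(bodies[[1]], action)
  } else {
    action_components(action)  # still validate the code
    bodies[[1]]$vx <- 0; bodies[[1]]$vy <- 0; bodies[[1]]$vz <- 0
  }
  for (i in seq_along(bodies)) {
    b <- bodies[[i]]
    if (!b$movable && !is_sphere(b)) next   # static scenery never integrates
    if (frozen && i == 1L) next
    bodies[[i]] <- integrate_body(b, bodies)
  }
  # movable blocks pushed by the agent
  bodies <- resolve_agent_block_pushes(bodies)
  world$bodies <- bodies
  world$step <- world$step + 1L
  world$events <- detect_events(bodies, world$step)
  world
}

integrate_body <- function(b, bodies) {
  dx <- b$vx; dz <- b$vz
  bottom <- b$y
  # ramp gate and slope scaling (spheres only; blocks treat ramps as walls)
  if (is_sphere(b) && (dx != 0 || dz != 0)) {
    cx <- b$x + dx; cz <- b$z + dz
    for (o in bodies) {
      if (o$id == b$id || o$kind != "Ramp") next
      cur_in <- in_footprint(o, b$x, b$z)
      if (!cur_in && !in_footprint(o, cx, cz)) next
      if (!is_climbable_ramp(o)) next   # handled as a solid box below
      # moving uphill: displacement is projected along the slope, then the
      # step-up gate decides whether the (scaled) rise is walkable; stepping
      # over the crest keeps the full stride
      f <- 1 / sqrt(1 + ramp_ratio(o)^2)
      cx2 <- b$x + dx * f; cz2 <- b$z + dz * f
      h2 <- if (in_footprint(o, cx2, cz2)) ramp_height_at(o, cx2, cz2) else bottom
      if (h2 > bottom + 1e-9) {
        if (h2 > bottom + PHYS$step_up) {
          dx <- 0; dz <- 0; b$vx <- 0; b$vz <- 0   # steep face: blocked
        } else {
          dx <- dx * f; dz <- dz * f
        }
      }
      break
    }
  }
  b$x <- b$x + dx; b$z <- b$z + dz
  b$vy <- b$vy - PHYS$gravity
  b$y <- b$y + b$vy
  supp <- support_height(bodies, b$id, b$x, b$z, bottom)
  grounded <- FALSE
  if (b$y <= supp) {
    b$y <- supp; b$vy <- 0; grounded <- TRUE
  }
  b <- resolve_box_collisions(b, bodies)
  b <- contain_in_arena(b)
  # dissipation: drag proportional to cross-section, Coulomb ground friction
  if (!b$bounce) {
    cd <- min(0.9, PHYS$drag * (b$sx + b$sz) / 2)
    b$vx <- b$vx * (1 - cd); b$vz <- b$vz * (1 - cd)
    if (grounded) {
      sp <- sqrt(b$vx^2 + b$vz^2)
      if (sp > 0) {
        sp2 <- max(0, sp - PHYS$friction)
        b$vx <- b$vx * sp2 / sp; b$vz <- b$vz * sp2 / sp
      }
    }
  }
  b
}

resolve_box_collisions <- function(b, bodies) {
  if (!is_sphere(b)) return(b)
  r <- body_radius(b)
  for (o in bodies) {
    if (o$id == b$id || !o$solid || o$zone || is_sphere(o)) next
    if (o$movable) next                     # handled by the push pass
    if (is_climbable_ramp(o)) next          # walkable surface, not a wall
    hit <- sphere_body_mtv(b$x, body_center_y(b), b$z, r, o)
    if (is.null(hit)) next
    b$x <- b$x + hit$mtv[1]
    b$y <- b$y + hit$mtv[2]
    b$z <- b$z + hit$mtv[3]
    v <- c(b$vx, b$vy, b$vz)
    vn <- sum(v * hit$normal)
    if (vn < 0) {
      if (b$bounce) {
        v <- v - 2 * vn * hit$normal        # restitution 1
      } else {
        v <- v - vn * hit$normal
      }
      b$vx <- v[1]; b$vy <- v[2]; b$vz <- v[3]
    }
  }
  b
}

contain_in_arena <- function(b) {
  if (is_sphere(b)) {
    r <- body_radius(b)
    lo <- r; hi <- ARENA_SIZE - r
    cx <- b$x; cz <- b$z
  } else {
    a <- deg2rad(b$yaw)
    wx <- (abs(cos(a)) * b$sx + abs(sin(a)) * b$sz) / 2
    wz <- (abs(sin(a)) * b$sx + abs(cos(a)) * b$sz) / 2
    lo <- c(wx, wz); hi <- c(ARENA_SIZE - wx, ARENA_SIZE - wz)
  }
  reflect <- function(p, v, lo, hi) {
    if (p < lo) { p <- lo; v <- if (b$bounce) abs(v) else 0 }
    if (p > hi) { p <- hi; v <- if (b$bounce) -abs(v) else 0 }
    c(p, v)
  }
  if (is_sphere(b)) {
    rx <- reflect(b$x, b$vx, lo, hi); b$x <- rx[1]; b$vx <- rx[2]
    rz <- reflect(b$z, b$vz, lo, hi); b$z <- rz[1]; b$vz <- rz[2]
  } else {
    rx <- reflect(b$x, b$vx, lo[1], hi[1]); b$x <- rx[1]; b$vx <- rx[2]
    rz <- reflect(b$z, b$vz, lo[2], hi[2]); b$z <- rz[1]; b$vz <- rz[2]
  }
  if (b$y < 0) { b$y <- 0; b$vy <- 0 }
  b
}

resolve_agent_block_pushes <- function(bodies) {
  ag <- bodies[[1]]
  r <- body_radius(ag)
  for (i in seq_along(bodies)) {
    o <- bodies[[i]]
    if (i == 1L || !o$movable || !o$solid) next
    hit <- sphere_body_mtv(ag$x, body_center_y(ag), ag$z, r, o)
    if (is.null(hit)) next
    share_o <- ag$mass / (ag$mass + o$mass)
    share_a <- 1 - share_o
    n <- hit$normal
    # reaction: the block is displaced opposite to the contact normal,
    # inversely proportional to its mass; the agent recoils
    o$x <- o$x - n[1] * hit$depth * share_o
    o$z <- o$z - n[3] * hit$depth * share_o
    ag$x <- ag$x + n[1] * hit$depth * share_a
    ag$z <- ag$z + n[3] * hit$depth * share_a
    vrel <- c(ag$vx - o$vx, 0, ag$vz - o$vz)
    vn <- sum(vrel * n)
    if (vn < 0) {
      j <- -vn * (ag$mass * o$mass) / (ag$mass + o$mass)
      o$vx <- o$vx - n[1] * j / o$mass
      o$vz <- o$vz - n[3] * j / o$mass
      ag$vx <- ag$vx + n[1] * j / ag$mass
      ag$vz <- ag$vz + n[3] * j / ag$mass
    }
    o <- contain_in_arena(o)
    # blocks are high-friction: damp transferred velocity
    o$vx <- o$vx * 0.6; o$vz <- o$vz * 0.6
    bodies[[i]] <- o
  }
  bodies[[1]] <- contain_in_arena(ag)
  bodies
}

## ---- contact events --------------------------------------------------------

agent_in_zone <- function(ag, o) {
  l <- world_to_local(ag$x - o$x, ag$z - o$z, o$yaw)
  cy <- body_center_y(ag)
  abs(l[1]) <= o$sx / 2 && abs(l[2]) <= o$sz / 2 &&
    cy >= o$y && cy <= o$y + o$sy
}

detect_events <- function(bodies, step) {
  ag <- bodies[[1]]
  r <- body_radius(ag)
  goal_contacts <- integer(0)
  in_death <- FALSE; in_hot <- FALSE
  button_presses <- integer(0)
  for (o in bodies[-1]) {
    if (o$zone) {
      if (agent_in_zone(ag, o)) {
        if (o$kind == "DeathZone") in_death <- TRUE
        if (o$kind == "HotZone") in_hot <- TRUE
      }
    } else if (o$category %in% c("goal_positive", "goal_negative")) {
      d2 <- (ag$x - o$x)^2 + (body_center_y(ag) - body_center_y(o))^2 + (ag$z - o$z)^2
      if (d2 <= (r + body_radius(o))^2) {
        goal_contacts <- c(goal_contacts, o$id)
      }
    } else if (o$kind == "SpawnerButton") {
      hit <- sphere_body_mtv(ag$x, body_center_y(ag), ag$z, r + 0.05, o)
      if (!is.null(hit)) {
        # a press requires contact on the front face (local +z)
        front <- local_to_world(0, 1, o$yaw)
        to_agent <- c(ag$x - o$x, ag$z - o$z)
        len <- sqrt(sum(to_agent^2))
        if (len > 0 && sum(to_agent * front) / len > 0.5) {
          button_presses <- c(button_presses, o$id)
        }
      }
    }
  }
  # death takes precedence over hot where the zones overlap
  if (in_death) in_hot <- FALSE
  list(goal_contacts = goal_contacts, in_death = in_death, in_hot = in_hot,
       button_presses = button_presses, step = step)
}

#' Probe ramp climbability with a scripted forward drive
#'
#' For each height:length ratio, builds an arena with a single ramp and drives
#' the agent straight at it, recording whether the agent's elevation reaches
#' the ramp top. Used to verify that the physics gate reproduces the 4:1
#' climbability rule behaviourally.
#'
#' @param ratios Numeric vector of height:length ratios to probe.
#' @param length Ramp length (default 2).
#' @param steps Number of forward steps to drive (default 200).
#' @return A tibble with columns `ratio`, `height`, `climbed`, `max_elevation`.
#' @export
probe_ramp_climbability <- function(ratios = c(1, 2, 4, 4.5, 8), length = 2,
                                    steps = 200) {
  res <- lapply(ratios, function(ratio) {
    height <- ratio * length
    arena <- structure(list(
      time_limit = 0, pass_mark = 0, frozen_agent_delays = 0, lights_out = NULL,
      items = list(
        list(name = "Agent", position = vec3(20, 0, 14), rotation = 0,
             size = vec3(1, 1, 1), color = NULL, special = list()),
        list(name = "Ramp", position = vec3(20, 0, 20), rotation = 0,
             size = vec3(4, height, length), color = NULL, special = list())
      )), class = "concrete_arena")
    w <- world_init(arena, seed = 0L)
    max_elev <- 0
    for (k in seq_len(steps)) {
      w <- step_world(w, "Forwards")
      max_elev <- max(max_elev, w$bodies[[1]]$y)
    }
    # the last on-slope footfall can sit up to one stride below the crest,
    # so "reached the top" allows a one-step (< 0.3 unit) shortfall
    tibble::tibble(ratio = ratio, height = height,
                   climbed = max_elev >= height - 0.3,
                   max_elevation = max_elev)
  })
  dplyr::bind_rows(res)
}
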