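#' Resolve randomisation tokens to a concrete arena
#'
#' Replaces every randomisation token in an arena specification by a concrete
#' draw (positions uniform over the legal arena area, rotations uniform over
#' `[0, 360)`, colours uniform over the 256^3 RGB space), expands per-instance
#' entries, and fills per-kind defaults (rotation 0, unit size or the kind's
#' fixed size, the kind's default colour, a random position when none is
#' given). Resolution is a pure function of `(spec, seed)`.
#'
#' @param spec An `arena_spec`.
#' @param seed Integer seed.
#' @return A `concrete_arena`: like an `arena_spec`, but `items` is a flat list
#'   of single-instance objects with fields `name`, `position`, `rotation`,
#'   `size`, `color`, `special`, and no tokens remain.
#' @export
resolve_randomness <- function(spec, seed) {
  stopifnot(inherits(spec, "arena_spec"))
  rng <- rng_new(derive_seed(seed, 11L))
  items <- list()
  for (it in spec$items) {
    n <- max(1, length(it$positions), length(it$rotations),
             length(it$sizes), length(it$colors))
    for (k in seq_len(n)) {
      items[[length(items) + 1L]] <- resolve_instance(it, k, rng)
    }
  }
  structure(list(time_limit = spec$time_limit, pass_mark = spec$pass_mark,
                 frozen_agent_delays = spec$frozen_agent_delays,
                 lights_out = spec$lights_out, items = items),
            class = "concrete_arena")
}

# fixed footprint sizes for kinds whose geometry is not configurable
.fixed_sizes <- list(
  Agent = c(1, 1, 1),
  SpawnerTree = c(1.5, 4, 1.5),
  SpawnerDispenserTall = c(1.5, 3, 1.5),
  SpawnerDispenserShort = c(1.5, 1.5, 1.5),
  SpawnerButton = c(1, 1, 1),
  SignBoard = c(2, 1.5, 0.4)
)

default_size <- function(kind) {
  s <- .fixed_sizes[[kind]] %||% c(1, 1, 1)
  vec3(s[1], s[2], s[3])
}

resolve_instance <- function(it, k, rng) {
  info <- kind_info(it$name)
  pos <- if (k <= length(it$positions)) it$positions[[k]] else
    random_token("position", min = c(0, 0, 0), max = c(ARENA_SIZE, 0, ARENA_SIZE))
  rot <- if (k <= length(it$rotations)) it$rotations[[k]] else 0
  size <- if (k <= length(it$sizes)) it$sizes[[k]] else default_size(it$name)
  col <- if (k <= length(it$colors)) it$colors[[k]] else
    list(r = info$r, g = info$g, b = info$b)
  if (info$fixed_size) size <- default_size(it$name)
  list(name = it$name,
       position = resolve_position(pos, rng),
       rotation = norm_yaw(resolve_rotation(rot, rng)),
       size = resolve_size(size, rng),
       color = resolve_color(col, rng),
       special = it$special)
}

resolve_position <- function(p, rng) {
  if (!is_token(p)) return(p)
  mn <- p$min %||% c(0, 0, 0)
  mx <- p$max %||% c(ARENA_SIZE, 0, ARENA_SIZE)
  if (any(mn[c(1, 3)] < 0) || any(mx[c(1, 3)] > ARENA_SIZE) || any(mn > mx)) {
    stop("random position bounds outside the arena", call. = FALSE)
  }
  draw <- vapply(1:3, function(i) {
    if (mx[i] > mn[i]) rng_runif(rng, 1, mn[i], mx[i]) else mn[i]
  }, numeric(1))
  vec3(draw[1], draw[2], draw[3])
}

resolve_rotation <- function(r, rng) {
  if (!is_token(r)) return(as.numeric(r))
  mn <- r$min %||% 0
  mx <- r$max %||% 360
  rng_runif(rng, 1, mn, mx)
}

resolve_size <- function(s, rng) {
  if (!is_token(s)) return(s)
  mn <- s$min %||% 0.5
  mx <- s$max %||% mn
  if (mn < 0) stop("random size bounds must be non-negative", call. = FALSE)
  v <- if (mx > mn) rng_runif(rng, 1, mn, mx) else mn
  vec3(v, v, v)
}

resolve_color <- function(col, rng) {
  if (!is_token(col)) return(col)
  ch <- floor(rng_runif(rng, 3, 0, 256))
  ch[ch > 255] <- 255
  list(r = ch[1], g = ch[2], b = ch[3])
}

## ---- overlap detection and precedence placement ---------------------------

# conservative world-frame AABB of a y-rotated box
world_aabb <- function(inst) {
  s <- as_vec3(inst$size)
  hx <- s$x / 2; hy <- s$y / 2; hz <- s$z / 2
  a <- deg2rad(inst$rotation %||% 0)
  wx <- abs(cos(a)) * hx + abs(sin(a)) * hz
  wz <- abs(sin(a)) * hx + abs(cos(a)) * hz
  p <- as_vec3(inst$position)
  list(min = c(p$x - wx, p$y, p$z - wz),
       max = c(p$x + wx, p$y + 2 * hy, p$z + wz))
}

aabb_intersect <- function(a, b, eps = 1e-9) {
  all(a$min + eps < b$max) && all(b$min + eps < a$max)
}

#' Detect overlapping solid objects
#'
#' Uses conservative axis-aligned bounding boxes (after applying each object's
#' yaw). Zones (DeathZone, HotZone) are passable volumes and never conflict.
#'
#' @param arena A `concrete_arena`.
#' @return A tibble with columns `i`, `j` (1-based item indices, `i < j`), one
#'   row per conflicting pair; zero rows when the arena is conflict-free.
#' @export
detect_overlaps <- function(arena) {
  stopifnot(inherits(arena, "concrete_arena"))
  items <- arena$items
  solid <- vapply(items, function(it) kind_info(it$name)$solid, logical(1))
  ids <- which(solid)
  out <- list()
  if (length(ids) >= 2) {
    boxes <- lapply(items[ids], world_aabb)
    for (a in seq_along(ids)[-length(ids)]) {
      for (b in (a + 1):length(ids)) {
        if (aabb_intersect(boxes[[a]], boxes[[b]])) {
          out[[length(out) + 1L]] <- c(ids[a], ids[b])
        }
      }
    }
  }
  if (!length(out)) return(tibble::tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

#' Place objects with agent-first precedence
#'
#' The agent is always placed first, regardless of where it appears in the
#' item list; remaining objects are placed in file order. Whenever an object's
#' bounding volume intersects an already-placed solid, it is re-spawned at a
#' uniformly drawn free location (up to 100 attempts, then an error naming the
#' object). Solids are also nudged so their footprint lies fully inside the
#' 40 x 40 arena. The result always passes [detect_overlaps()] cleanly.
#'
#' @param arena A `concrete_arena`.
#' @param seed Integer seed for relocation draws.
#' @param max_attempts Relocation attempts per object before giving up.
#' @return A `concrete_arena` with conflict-free placements.
#' @export
place_with_precedence <- function(arena, seed, max_attempts = 100L) {
  stopifnot(inherits(arena, "concrete_arena"))
  rng <- rng_new(derive_seed(seed, 23L))
  items <- arena$items
  is_agent <- vapply(items, function(it) identical(it$name, "Agent"), logical(1))
  order_ix <- c(which(is_agent), which(!is_agent))
  placed_boxes <- list()
  for (ix in order_ix) {
    it <- items[[ix]]
    info <- kind_info(it$name)
    if (!info$solid) next
    it <- clamp_into_arena(it)
    box <- world_aabb(it)
    attempt <- 0L
    while (any(vapply(placed_boxes, aabb_intersect, logical(1), b = box))) {
      attempt <- attempt + 1L
      if (attempt > max_attempts) {
        stop("could not place object '", it$name, "' (item ", ix,
             ") without overlap after ", max_attempts, " attempts",
             call. = FALSE)
      }
      s <- as_vec3(it$size)
      a <- deg2rad(it$rotation %||% 0)
      wx <- (abs(cos(a)) * s$x + abs(sin(a)) * s$z) / 2
      wz <- (abs(sin(a)) * s$x + abs(cos(a)) * s$z) / 2
      it$position <- vec3(rng_runif(rng, 1, wx, ARENA_SIZE - wx),
                          as_vec3(it$position)$y,
                          rng_runif(rng, 1, wz, ARENA_SIZE - wz))
      box <- world_aabb(it)
    }
    placed_boxes[[length(placed_boxes) + 1L]] <- box
    items[[ix]] <- it
  }
  arena$items <- items
  arena
}

clamp_into_arena <- function(it) {
  s <- as_vec3(it$size)
  a <- deg2rad(it$rotation %||% 0)
  wx <- min((abs(cos(a)) * s$x + abs(sin(a)) * s$z) / 2, ARENA_SIZE / 2)
  wz <- min((abs(sin(a)) * s$x + abs(cos(a)) * s$z) / 2, ARENA_SIZE / 2)
  p <- as_vec3(it$position)
  it$position <- vec3(clamp(p$x, wx, ARENA_SIZE - wx), max(p$y, 0),
                      clamp(p$z, wz, ARENA_SIZE - wz))
  it
}
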