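#' Dispensers: spawner trees and goal dispensers
#'
#' Spawner trees and tall/short dispensers emit `GoodGoalMulti` goals on a
#' schedule: nothing before `delay`, then one goal per `interval` window until
#' `count` goals have been produced. Tree drops land at a random point within
#' the canopy footprint (a disc of radius 2 around the trunk) with a random
#' within-interval drop time, in the style of naturally falling fruit;
#' dispensers emit at their hatch position on the exact schedule.
#'
#' `spawn_schedule()` precomputes the full deterministic-under-seed schedule
#' for an episode; `tick_spawner()` filters it for one step.
#'
#' @param spawner A list with fields `kind` (`"tree"`, `"dispenserTall"`,
#'   `"dispenserShort"`), `count`, `delay`, `interval`, `goalSize`, and the
#'   spawner's `position`/`rotation`.
#' @param rng An internal RNG handle (from a seed).
#' @return A tibble of spawn events: `step`, `kind`, `x`, `y`, `z`, `size`.
#' @export
spawn_schedule <- function(spawner, rng) {
  count <- spawner$count %||% 0
  if (count <= 0) {
    return(tibble::tibble(step = integer(), kind = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          size = numeric()))
  }
  delay <- spawner$delay %||% 0
  interval <- spawner$interval %||% 25
  size <- spawner$goalSize %||% 1
  pos <- as_vec3(spawner$position)
  tree <- identical(spawner$kind, "tree")
  steps <- numeric(count)
  xs <- numeric(count); zs <- numeric(count)
  for (k in seq_len(count)) {
    base <- delay + (k - 1) * interval
    if (tree && interval > 1) {
      steps[k] <- base + floor(rng_runif(rng, 1, 0, interval))
    } else {
      steps[k] <- base
    }
    if (tree) {
      # uniform over the canopy annulus (radius 1.3-2 around the trunk, so
      # fruit never comes to rest on the trunk itself), rejection-free polar draw
      u <- rng_runif(rng, 2)
      rr <- sqrt(1.3^2 + u[1] * (2^2 - 1.3^2)); th <- 2 * pi * u[2]
      xs[k] <- clamp(pos$x + rr * cos(th), size / 2, ARENA_SIZE - size / 2)
      zs[k] <- clamp(pos$z + rr * sin(th), size / 2, ARENA_SIZE - size / 2)
    } else {
      hatch <- local_to_world(0, as_vec3(spawner$size %||% c(1.5, 3, 1.5))$z / 2 + size / 2 + 0.1,
                              spawner$rotation %||% 0)
      xs[k] <- clamp(pos$x + hatch[1], size / 2, ARENA_SIZE - size / 2)
      zs[k] <- clamp(pos$z + hatch[2], size / 2, ARENA_SIZE - size / 2)
    }
  }
  drop_y <- if (tree) 3.5 else 1
  tibble::tibble(step = as.integer(steps), kind = "GoodGoalMulti",
                 x = xs, y = drop_y, z = zs, size = size)
}

#' @rdname spawn_schedule
#' @param step The current step.
#' @param schedule A schedule tibble from `spawn_schedule()`.
#' @return `tick_spawner()`: the rows of `schedule` due at `step`.
#' @export
tick_spawner <- function(schedule, step) {
  schedule[schedule$step == step, , drop = FALSE]
}

#' Press a spawner button
#'
#' A registered press (agent contact with the button's front face) spawns,
#' with probability `spawnProbability`, one goal whose kind is drawn in
#' proportion to `weights` over \{GoodGoal, GoodGoalMulti, BadGoal\}, at
#' `spawnPosition`. Presses during the cooldown (`resetSteps` steps after the
#' previous registered press) do nothing.
#'
#' @param button A list with `spawnProbability`, `weights` (named list),
#'   `spawnPosition`, `resetSteps`, `goalSize`.
#' @param steps_since_last_press Steps since the last registered press
#'   (`Inf` for a first press).
#' @param rng An internal RNG handle.
#' @return `NULL` (no spawn) or a one-row spawn-event tibble.
#' @export
press_button <- function(button, steps_since_last_press, rng) {
  reset <- button$resetSteps %||% 20
  if (steps_since_last_press < reset) return(NULL)
  p <- button$spawnProbability %||% 1
  weights <- button$weights %||% list(GoodGoal = 1, GoodGoalMulti = 1, BadGoal = 1)
  kinds <- c("GoodGoal", "GoodGoalMulti", "BadGoal")
  w <- vapply(kinds, function(k) as.numeric(weights[[k]] %||% 0), numeric(1))
  if (p > 0 && sum(w) <= 0) {
    stop("button weights must not all be zero when spawnProbability > 0",
         call. = FALSE)
  }
  if (rng_runif(rng, 1) > p) return(NULL)
  kind <- rng_sample(rng, kinds, 1, prob = w / sum(w))
  pos <- as_vec3(button$spawnPosition %||% c(20, 1, 20))
  size <- button$goalSize %||% 1
  tibble::tibble(step = NA_integer_, kind = kind,
                 x = pos$x, y = pos$y, z = pos$z, size = size)
}

## ---- sign boards -----------------------------------------------------------

# preset symbols: 16 x 16 monochrome bitmaps drawn procedurally. Only the
# identifiers are normative; the drawings are arenalab's own.
.sign_presets <- local({
  n <- 16
  grid <- expand.grid(col = seq_len(n), row = seq_len(n))
  xx <- (grid$col - 0.5) / n * 2 - 1   # [-1, 1]
  yy <- 1 - (grid$row - 0.5) / n * 2   # [-1, 1], +y up
  as_mat <- function(v) matrix(as.integer(v), n, n, byrow = FALSE)
  circle <- abs(sqrt(xx^2 + yy^2) - 0.7) < 0.18
  tick <- (abs(yy - (-0.1 - 1.2 * (xx + 0.5))) < 0.22 & xx >= -0.75 & xx <= -0.2) |
    (abs(yy - (-0.7 + 1.1 * (xx + 0.2))) < 0.2 & xx > -0.25 & xx <= 0.8)
  left_arrow <- (abs(yy) < 0.18 & xx > -0.5 & xx < 0.85) |
    (xx > -0.85 & xx < -0.15 & abs(yy) < (xx + 0.9) * 0.8 &
       abs(yy) > (xx + 0.3) * 0.9)
  letter_a <- (abs(xx + 0.55 * yy - 0.28) < 0.16 & yy > -0.85 & yy < 0.85) |
    (abs(xx - 0.55 * yy + 0.28) < 0.16 & yy > -0.85 & yy < 0.85) |
    (abs(yy + 0.25) < 0.14 & abs(xx) < 0.45)
  uturn <- (abs(xx + 0.45) < 0.14 & yy < 0.3) |
    (abs(xx - 0.45) < 0.14 & yy < 0.1 & yy > -0.5) |
    (abs(sqrt(xx^2 + (yy - 0.25)^2) - 0.45) < 0.15 & yy > 0.25) |
    (yy < -0.35 & yy > -0.95 & abs(xx - 0.45) < (-(yy + 0.35)) * 0.7)
  list(
    "circle" = as_mat(circle),
    "tick" = as_mat(tick),
    "left-arrow" = as_mat(left_arrow),
    "letter-a" = as_mat(letter_a),
    "u-turn-arrow" = as_mat(uturn)
  )
})

#' Render a sign board to a concrete pixel grid
#'
#' Sign boards display either one of the preset symbols (`"tick"`,
#' `"u-turn-arrow"`, `"circle"`, `"letter-a"`, `"left-arrow"`) or a
#' user-defined pixel grid. Grids are written in YAML as rows joined by `/`,
#' with cells `0`, `1`, or `*`; each `*` resolves independently to 0 or 1
#' with probability one half, deterministically under the episode seed.
#'
#' @param sign A list with either `symbol` (preset name) or `grid` (string).
#' @param rng An internal RNG handle for `*` cells.
#' @return An integer 0/1 matrix.
#' @export
render_signboard <- function(sign, rng = rng_new(0)) {
  if (!is.null(sign$symbol)) {
    m <- .sign_presets[[sign$symbol]]
    if (is.null(m)) stop("unknown sign board symbol: '", sign$symbol, "'", call. = FALSE)
    return(m)
  }
  if (is.null(sign$grid)) stop("sign board needs a 'symbol' or a 'grid'", call. = FALSE)
  rows <- strsplit(sign$grid, "/", fixed = TRUE)[[1]]
  cells <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  if (length(unique(vapply(cells, length, integer(1)))) != 1) {
    stop("sign board grid rows must have equal length", call. = FALSE)
  }
  m <- do.call(rbind, lapply(cells, function(r) {
    vapply(r, function(c) {
      if (c == "0") return(0L)
      if (c == "1") return(1L)
      if (c == "*") return(NA_integer_)
      stop("sign board grid cells must be 0, 1 or *", call. = FALSE)
    }, integer(1), USE.NAMES = FALSE)
  }))
  nas <- which(is.na(m))
  if (length(nas)) m[nas] <- as.integer(rng_runif(rng, length(nas)) < 0.5)
  m
}

#' @rdname render_signboard
#' @export
sign_presets <- function() names(.sign_presets)
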