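#' Procedural configuration templates
#'
#' A template is a YAML document with two top-level keys: `config`, an arena
#' configuration in the usual schema whose values may contain `$name`
#' placeholders, and `template`, holding named `choices` and free-form
#' `labels`. Choice kinds are `fixed-list` (pick one of `options`),
#' `numeric-range` (uniform over `[min, max]`), `random-color` (uniform over
#' the RGB cube), and `conditional` (an R expression over previously declared
#' choices, evaluated with the template's deterministic RNG, so e.g.
#' `"runif(1, 0.5, 4 * rampLength)"` keeps a ramp climbable). Choices are
#' resolved in declaration order; a conditional may only reference choices
#' declared before it.
#'
#' @param yaml_text Template YAML as a single string.
#' @return A `arena_template` list with `base`, `choices`, `labels`.
#' @export
parse_template <- function(yaml_text) {
  raw <- yaml::yaml.load(yaml_text, handlers = .yaml_handlers)
  tpl <- raw$template %||% list()
  base <- raw$config %||% stop("template needs a 'config' section", call. = FALSE)
  choices <- tpl$choices %||% list()
  for (nm in names(choices)) {
    kind <- choices[[nm]]$kind %||% stop("choice '", nm, "' needs a kind", call. = FALSE)
    if (!kind %in% c("fixed-list", "numeric-range", "random-color", "conditional")) {
      stop("choice '", nm, "': unknown kind '", kind, "'", call. = FALSE)
    }
    if (kind == "fixed-list" && !length(choices[[nm]]$options)) {
      stop("choice '", nm, "': fixed-list needs non-empty options", call. = FALSE)
    }
  }
  structure(list(base = base, choices = choices,
                 labels = tpl$labels %||% character(0)),
            class = "arena_template")
}

#' @rdname parse_template
#' @export
read_template <- function(path) {
  parse_template(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

resolve_choices <- function(choices, rng) {
  out <- list()
  for (nm in names(choices)) {
    ch <- choices[[nm]]
    out[[nm]] <- switch(ch$kind,
      "fixed-list" = ch$options[[rng_sample(rng, length(ch$options), 1)]],
      "numeric-range" = rng_runif(rng, 1, ch$min %||% 0, ch$max %||% 1),
      "random-color" = {
        v <- floor(rng_runif(rng, 3, 0, 256)); v[v > 255] <- 255
        list(r = v[1], g = v[2], b = v[3])
      },
      "conditional" = {
        expr <- ch$expr %||% stop("conditional choice '", nm, "' needs an expr",
                                  call. = FALSE)
        # prior choices are visible by name; base and stats (runif, sample,
        # rnorm, ...) are in scope for the expression
        ev <- new.env(parent = asNamespace("stats"))
        for (k in names(out)) assign(k, out[[k]], envir = ev)
        tryCatch(
          rng_do(rng, function() eval(parse(text = expr), envir = ev)),
          error = function(e) stop("conditional choice '", nm,
                                   "' failed: ", conditionMessage(e),
                                   call. = FALSE))
      })
  }
  out
}

substitute_choices <- function(x, values) {
  if (is.character(x) && any(startsWith(x, "$"))) {
    repl <- lapply(x, function(xi) {
      if (!startsWith(xi, "$")) return(xi)
      nm <- substring(xi, 2)
      if (!nm %in% names(values)) {
        stop("template references undeclared choice '", nm, "'", call. = FALSE)
      }
      values[[nm]]
    })
    # a lone scalar placeholder stays a scalar; a YAML sequence of
    # placeholders (e.g. a colors list) stays a sequence
    if (length(repl) == 1 && !is.list(repl[[1]])) return(repl[[1]])
    return(repl)
  }
  if (is.list(x)) return(lapply(x, substitute_choices, values = values))
  x
}

#' Generate configurations from a template
#'
#' Draws `n` independent choice assignments and instantiates the template for
#' each. Every output parses and validates as an ordinary configuration;
#' generation is a pure function of `(template, n, seed)`. The drawn choice
#' values and the template's labels are attached to each configuration as
#' attributes `choices` and `labels`.
#'
#' @param template An `arena_template`.
#' @param n Number of configurations.
#' @param seed Integer seed.
#' @return A list of `arena_config`.
#' @export
generate_configs <- function(template, n, seed = 0L) {
  stopifnot(inherits(template, "arena_template"))
  lapply(seq_len(n), function(i) {
    rng <- rng_new(derive_seed(seed, i, 53L))
    values <- resolve_choices(template$choices, rng)
    raw <- substitute_choices(template$base, values)
    cfg <- parse_config(yaml::as.yaml(raw, precision = 15))
    attr(cfg, "choices") <- values
    attr(cfg, "labels") <- template$labels
    cfg
  })
}

## ---- built-in tasks --------------------------------------------------------

#' The foraging task
#'
#' A spawner tree at the arena centre (20, 0, 20) drops 10 `GoodGoalMulti`
#' goals of size 2; the agent spawns at a random x-coordinate at (x, 0, 5)
#' with a random initial rotation, and must collect the goals before its
#' health runs out.
#'
#' @param time_limit Episode step budget (default 250).
#' @param pass_mark Reward threshold for a pass (default 5: at least three
#'   goals net of the time decrement).
#' @return An `arena_config`.
#' @export
build_foraging_task <- function(time_limit = 250, pass_mark = 5) {
  arena_config(arena_spec(items = list(
    item_spec("Agent",
              positions = list(list(x = -1, y = 0, z = 5)),
              rotations = list("random")),
    item_spec("SpawnerTree",
              positions = list(list(x = 20, y = 0, z = 20)),
              special = list(count = 10, goalSize = 2, delay = 10,
                             interval = 15))
  ), time_limit = time_limit, pass_mark = pass_mark))
}

#' The operant-chamber task and its curriculum stages
#'
#' A spawner button at (38.5, 0, 18.8), enclosed by walls on three sides so
#' the agent must approach from the front, spawns a size-1 `GoodGoal` at
#' (39, 3, 22) when pressed. Stage 0 is the final task (agent at a random
#' (x, z)); stages 1-5 form a shaping curriculum with the agent spawned at
#' (36, 0, 20), (30, 0, 20), (20, 0, 20), (20, 0, z) with random z, and
#' fully random, respectively.
#'
#' @param stage Integer 0-5.
#' @param time_limit Episode step budget (default 500).
#' @return An `arena_config`.
#' @export
build_operant_task <- function(stage = 0, time_limit = 500) {
  if (!stage %in% 0:5) stop("stage must be 0..5", call. = FALSE)
  agent_pos <- switch(as.character(stage),
    "1" = list(x = 36, y = 0, z = 20),
    "2" = list(x = 30, y = 0, z = 20),
    "3" = list(x = 20, y = 0, z = 20),
    "4" = list(x = 20, y = 0, z = -1),
    list(x = -1, y = 0, z = -1))
  arena_config(arena_spec(items = list(
    item_spec("Agent", positions = list(agent_pos),
              rotations = list("random")),
    item_spec("SpawnerButton",
              positions = list(list(x = 38.5, y = 0, z = 18.8)),
              rotations = list(270),  # front face towards the arena interior
              special = list(spawnProbability = 1,
                             weights = list(GoodGoal = 1),
                             spawnPosition = list(x = 39, y = 3, z = 22),
                             resetSteps = 100)),
    # enclosure: rear wall (against the boundary) and two side walls
    item_spec("Wall",
              positions = list(list(x = 39.5, y = 0, z = 18.8),
                               list(x = 39, y = 0, z = 17.8),
                               list(x = 39, y = 0, z = 19.8)),
              rotations = list(0, 0, 0),
              sizes = list(list(x = 1, y = 2, z = 1),
                           list(x = 2, y = 2, z = 1),
                           list(x = 2, y = 2, z = 1)))
  ), time_limit = time_limit, pass_mark = 0.5))
}

#' Build a (cumulative) training curriculum
#'
#' Stage `i` of a cumulative curriculum contains the configurations of stages
#' 1..i interleaved round-robin, emulating shaping protocols where earlier
#' exercises stay in rotation as new ones are introduced.
#'
#' @param task `"operant"` (stages from [build_operant_task()]) or
#'   `"foraging"` (a single-stage curriculum).
#' @param total_stages Number of stages (default 5 for operant).
#' @param cumulative Interleave earlier stages into later ones?
#' @param steps_per_stage Training-step budget recorded per stage.
#' @return A list of `curriculum_stage` lists with fields `index`, `configs`,
#'   `steps`, `cumulative`.
#' @export
build_curriculum <- function(task = c("operant", "foraging"),
                             total_stages = 5, cumulative = TRUE,
                             steps_per_stage = 400000) {
  task <- match.arg(task)
  if (total_stages < 1) stop("total_stages must be >= 1", call. = FALSE)
  stage_cfg <- function(i) {
    if (task == "operant") build_operant_task(min(i, 5)) else build_foraging_task()
  }
  lapply(seq_len(total_stages), function(i) {
    configs <- if (cumulative) lapply(seq_len(i), stage_cfg) else list(stage_cfg(i))
    structure(list(index = i, configs = configs, steps = steps_per_stage,
                   cumulative = cumulative), class = "curriculum_stage")
  })
}

## ---- the testbed manifest --------------------------------------------------

.testbed_levels <- c(
  "Food Retrieval", "Preferences", "Static Obstacles", "Avoidance",
  "Spatial Reasoning and Support", "Generalisation", "Internal Modelling",
  "Object Permanence and Working Memory",
  "Numerosity and Advanced Preferences", "Causal Reasoning")

#' The testbed manifest
#'
#' The full battery structure: ten named levels of spatial and physical
#' cognition, thirty tasks per level, three variants per task — 900 entries.
#' Only the manifest structure is enumerated here; the task contents
#' themselves are not reproduced (see [build_level_exemplar()] for one
#' illustrative generator per level).
#'
#' @return A 900-row tibble with columns `level`, `level_name`, `task`,
#'   `variant`.
#' @export
testbed_manifest <- function() {
  grid <- expand.grid(variant = 1:3, task = 1:30, level = 1:10)
  tibble::tibble(level = grid$level,
                 level_name = .testbed_levels[grid$level],
                 task = grid$task,
                 variant = grid$variant)
}

#' Illustrative per-level task generators
#'
#' One simple, synthetic exemplar configuration per testbed level (an
#' open-arena retrieval for level 1, a zone-avoidance corridor for level 4,
#' and so on). These illustrate the style of task each level probes; they are
#' not the battery's actual tasks.
#'
#' @param level Integer 1-10.
#' @return An `arena_config`.
#' @export
build_level_exemplar <- function(level) {
  if (!level %in% 1:10) stop("level must be 1..10", call. = FALSE)
  agent_random <- item_spec("Agent", positions = list("random"),
                            rotations = list("random"))
  goal <- function(x, z, size = 1, kind = "GoodGoal") {
    item_spec(kind, positions = list(list(x = x, y = 0, z = z)),
              sizes = list(size))
  }
  wall <- function(x, z, sx, sz, h = 2, rot = 0) {
    item_spec("Wall", positions = list(list(x = x, y = 0, z = z)),
              rotations = list(rot),
              sizes = list(list(x = sx, y = h, z = sz)))
  }
  items <- switch(level,
    list(agent_random, goal(-1, -1)),                                   # L1
    list(agent_random, goal(10, 30, 1), goal(30, 30, 2)),               # L2
    list(agent_random, wall(20, 20, 8, 1), goal(20, 24)),               # L3
    list(item_spec("Agent", positions = list(list(x = 20, y = 0, z = 4))),
         wall(14, 20, 1, 24), wall(26, 20, 1, 24),
         item_spec("DeathZone",
                   positions = list(list(x = 17, y = 0, z = 18)),
                   sizes = list(list(x = 4, y = 1, z = 4))),
         goal(20, 34)),                                                 # L4
    list(agent_random, wall(20, 20, 6, 6, 3),
         item_spec("Ramp", positions = list(list(x = 20, y = 0, z = 14)),
                   sizes = list(list(x = 4, y = 3, z = 5))),
         item_spec("GoodGoal", positions = list(list(x = 20, y = 3, z = 20)),
                   sizes = list(1))),                                   # L5
    list(agent_random,
         item_spec("Wall", positions = list(list(x = 20, y = 0, z = 20)),
                   sizes = list(list(x = 8, y = 2, z = 1)),
                   colors = list("random")),
         goal(-1, -1)),                                                 # L6
    list(agent_random, wall(20, 20, 8, 1), goal(20, 24)),               # L7
    list(agent_random, wall(26, 20, 1, 10), goal(30, 20)),              # L8
    list(agent_random, goal(8, 32, 0.5), goal(12, 32, 0.5),
         goal(30, 32, 2, "GoodGoalMulti")),                             # L9
    list(agent_random,
         item_spec("LightBlock", positions = list(list(x = 20, y = 0, z = 18)),
                   sizes = list(list(x = 2, y = 2, z = 2))),
         goal(20, 30))                                                  # L10
  )
  lights <- if (level %in% c(7, 8)) list(intervals = list(c(20, 40))) else NULL
  arena_config(arena_spec(items = items, time_limit = 250, pass_mark = 0.5,
                          lights_out = lights))
}
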