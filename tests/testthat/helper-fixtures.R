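# fixtures are built in code: small concrete arenas and worlds for unit tests

# a concrete (token-free) arena from bare object descriptions
fix_arena <- function(..., time_limit = 0, pass_mark = 0,
                      frozen_agent_delays = 0, lights_out = NULL) {
  items <- lapply(list(...), function(o) {
    list(name = o$name,
         position = arenalab:::as_vec3(o$position %||% c(20, 0, 20)),
         rotation = o$rotation %||% 0,
         size = arenalab:::as_vec3(o$size %||% 1),
         color = o$color,
         special = o$special %||% list())
  })
  structure(list(time_limit = time_limit, pass_mark = pass_mark,
                 frozen_agent_delays = frozen_agent_delays,
                 lights_out = lights_out, items = items),
            class = "concrete_arena")
}

fix_obj <- function(name, position = c(20, 0, 20), rotation = 0, size = 1,
                    color = NULL, special = list()) {
  list(name = name, position = position, rotation = rotation, size = size,
       color = color, special = special)
}

# world with the agent at a given pose plus extra objects
fix_world <- function(agent_pos = c(20, 0, 20), agent_yaw = 0, ...,
                      seed = 0L) {
  world_init(fix_arena(fix_obj("Agent", agent_pos, agent_yaw), ...),
             seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# config: a lone agent in an empty arena
empty_arena_cfg <- function(time_limit = 100, agent = c(20, 0, 20), ...) {
  arena_config(arena_spec(list(
    item_spec("Agent",
              positions = list(list(x = agent[1], y = agent[2], z = agent[3])))
  ), time_limit = time_limit, ...))
}
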