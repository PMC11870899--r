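#' Arena configuration files
#'
#' Tasks are described declaratively in YAML. A configuration file holds one
#' or more arenas, each with a step budget (`timeLimit`), a pass threshold
#' (`passMark`), an initial immobilisation period (`frozenAgentDelays`), an
#' optional lights-out schedule, and an ordered list of items. Each item names
#' an object kind from [ontology()] and gives parallel lists of `positions`,
#' `rotations`, `sizes` and `colors` (one entry per instance), plus a
#' kind-specific `special` mapping (spawner counts and delays, button weights,
#' sign-board symbols, valence schedules, ...).
#'
#' Coordinates are `(x, y, z)` with `y` the vertical axis; placements must lie
#' inside the 40 x 40 arena footprint. Any position component, rotation or
#' colour can be randomised, either with the sentinel `-1` (or the string
#' `"random"`), or with an explicit canonical token
#' `{random: {kind: ..., min: ..., max: ...}}`. Item order matters: it defines
#' placement precedence (see [place_with_precedence()]).
#'
#' @param yaml_text A single string of YAML.
#' @return `parse_config()` returns an `arena_config` object: a list with
#'   `arenas` (named list of `arena_spec`) and `episode_mode`.
#' @seealso [write_config()], [resolve_randomness()], [read_config()]
#' @export
#' @examples
#' cfg <- parse_config("
#' arenas:
#'   0:
#'     timeLimit: 100
#'     items:
#'     - name: GoodGoal
#'       positions: [{x: 20, y: 0, z: 20}]
#'       sizes: [2]
#' ")
#' cfg$arenas[[1]]$time_limit
parse_config <- function(yaml_text) {
  raw <- tryCatch(
    yaml::yaml.load(yaml_text, handlers = .yaml_handlers),
    error = function(e) stop("malformed YAML: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  known_top <- c("arenas", "episodeMode")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    warning("unknown top-level keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  mode <- raw$episodeMode %||% "sequential-episodes"
  if (!mode %in% c("sequential-episodes", "multi-arena-single-episode")) {
    stop("unknown episodeMode: '", mode, "'", call. = FALSE)
  }
  arenas_raw <- raw$arenas %||% list()
  idx <- names(arenas_raw) %||% as.character(seq_along(arenas_raw) - 1L)
  if (anyDuplicated(idx)) stop("duplicate arena indices", call. = FALSE)
  if (any(is.na(suppressWarnings(as.integer(idx)))) ||
      any(as.integer(idx) < 0)) {
    stop("arena indices must be non-negative integers", call. = FALSE)
  }
  arenas <- lapply(arenas_raw, parse_arena)
  names(arenas) <- idx
  arenas <- arenas[order(as.integer(idx))]
  new_config(arenas, mode)
}

# YAML 1.1 treats bare y/n as booleans, but `y` is this schema's vertical
# coordinate key; keep those single letters as strings while leaving real
# booleans (true/yes/...) alone
.yaml_handlers <- list(
  "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
  "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE
)

new_config <- function(arenas = list(), episode_mode = "sequential-episodes") {
  structure(list(arenas = arenas, episode_mode = episode_mode),
            class = "arena_config")
}

parse_arena <- function(a) {
  known <- c("timeLimit", "passMark", "frozenAgentDelays", "lightsOut", "items")
  unknown <- setdiff(names(a), known)
  if (length(unknown)) {
    warning("unknown arena keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  t <- as.numeric(a$timeLimit %||% 250)
  if (t < 0) stop("timeLimit must be >= 0", call. = FALSE)
  fd <- as.numeric(a$frozenAgentDelays %||% 0)
  if (fd < 0) stop("frozenAgentDelays must be >= 0", call. = FALSE)
  structure(list(
    time_limit = t,
    pass_mark = as.numeric(a$passMark %||% 0),
    frozen_agent_delays = fd,
    lights_out = parse_lights_out(a$lightsOut),
    items = lapply(a$items %||% list(), parse_item)
  ), class = "arena_spec")
}

parse_lights_out <- function(lo) {
  if (is.null(lo)) return(NULL)
  if (!is.null(lo$period)) {
    p <- as.numeric(lo$period)
    if (p <= 0) stop("lightsOut period must be positive", call. = FALSE)
    return(list(period = p))
  }
  if (!is.null(lo$intervals)) {
    iv <- lapply(lo$intervals, function(x) {
      x <- as.numeric(unlist(x))
      if (length(x) != 2 || x[2] <= x[1]) {
        stop("lightsOut intervals must be [start, end) pairs", call. = FALSE)
      }
      x
    })
    return(list(intervals = iv))
  }
  stop("lightsOut must give 'intervals' or 'period'", call. = FALSE)
}

parse_item <- function(it) {
  name <- it$name %||% stop("item without a name", call. = FALSE)
  if (!is_known_kind(name)) {
    stop("unknown object kind: '", name, "'", call. = FALSE)
  }
  info <- kind_info(name)
  positions <- lapply(it$positions %||% list(), parse_position)
  rotations <- lapply(it$rotations %||% list(), parse_rotation)
  sizes <- lapply(it$sizes %||% list(), parse_size)
  colors <- lapply(it$colors %||% list(), parse_color)
  lens <- c(length(positions), length(rotations), length(sizes), length(colors))
  lens <- lens[lens > 0]
  if (length(lens) && length(unique(lens)) > 1) {
    stop("item '", name, "': non-empty positions/rotations/sizes/colors ",
         "lists must have equal length", call. = FALSE)
  }
  if (length(colors) && info$fixed_color) {
    warning("item '", name, "': colors are fixed for this kind and ignored",
            call. = FALSE)
    colors <- list()
  }
  special <- it$special %||% list()
  allowed <- special_keys_for(name)
  bad <- setdiff(names(special), allowed)
  if (length(bad)) {
    stop("item '", name, "': unknown special parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, positions = positions, rotations = rotations,
                 sizes = sizes, colors = colors, special = special),
            class = "object_spec")
}

## ---- randomisation tokens --------------------------------------------------

random_token <- function(kind, min = NULL, max = NULL) {
  stopifnot(kind %in% c("scalar", "position", "rotation", "color"))
  structure(list(kind = kind, min = min, max = max), class = "arena_random_token")
}

is_token <- function(x) inherits(x, "arena_random_token")

parse_token <- function(x) {
  # explicit canonical form: {random: {kind: ..., min: ..., max: ...}}
  r <- x$random
  kind <- r$kind %||% stop("random token needs a kind", call. = FALSE)
  random_token(kind,
               min = if (!is.null(r$min)) as.numeric(unlist(r$min)),
               max = if (!is.null(r$max)) as.numeric(unlist(r$max)))
}

parse_position <- function(p) {
  if (is.character(p) && identical(p, "random")) {
    return(random_token("position", min = c(0, 0, 0), max = c(ARENA_SIZE, 0, ARENA_SIZE)))
  }
  if (is.list(p) && !is.null(p$random)) return(parse_token(p))
  v <- as_vec3(p)
  # sentinel -1 on a horizontal component means "randomise that component"
  if (identical(v$x, -1) || identical(v$z, -1)) {
    mn <- c(if (v$x == -1) 0 else v$x, v$y, if (v$z == -1) 0 else v$z)
    mx <- c(if (v$x == -1) ARENA_SIZE else v$x, v$y,
            if (v$z == -1) ARENA_SIZE else v$z)
    return(random_token("position", min = mn, max = mx))
  }
  if (v$x < 0 || v$x > ARENA_SIZE || v$z < 0 || v$z > ARENA_SIZE || v$y < 0) {
    stop("position out of arena bounds: (", v$x, ", ", v$y, ", ", v$z, ")",
         call. = FALSE)
  }
  v
}

parse_rotation <- function(r) {
  if (is.character(r) && identical(r, "random")) {
    return(random_token("rotation", min = 0, max = 360))
  }
  if (is.list(r) && !is.null(r$random)) return(parse_token(r))
  r <- as.numeric(r)
  if (identical(r, -1)) return(random_token("rotation", min = 0, max = 360))
  r
}

parse_size <- function(s) {
  if (is.list(s) && !is.null(s$random)) return(parse_token(s))
  as_vec3(s)
}

parse_color <- function(col) {
  if (is.character(col) && identical(col, "random")) return(random_token("color"))
  if (is.list(col) && !is.null(col$random)) return(parse_token(col))
  v <- c(col$r %||% 0, col$g %||% 0, col$b %||% 0)
  if (any(v == -1)) return(random_token("color"))
  if (any(v < 0 | v > 255)) stop("colour channels must be in [0, 255]", call. = FALSE)
  list(r = as.numeric(v[1]), g = as.numeric(v[2]), b = as.numeric(v[3]))
}

## ---- writing ---------------------------------------------------------------

#' Serialise a configuration back to YAML
#'
#' The output is canonical arenalab YAML: randomisation tokens are written in
#' their explicit `{random: ...}` form, so `parse_config(write_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param cfg An `arena_config`.
#' @return A single YAML string.
#' @export
write_config <- function(cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  out <- list(
    arenas = lapply(cfg$arenas, unparse_arena),
    episodeMode = cfg$episode_mode
  )
  yaml::as.yaml(out, precision = 15)
}

unparse_arena <- function(a) {
  out <- list(timeLimit = a$time_limit, passMark = a$pass_mark,
              frozenAgentDelays = a$frozen_agent_delays)
  if (!is.null(a$lights_out)) out$lightsOut <- a$lights_out
  out$items <- lapply(a$items, unparse_item)
  out
}

unparse_item <- function(it) {
  out <- list(name = it$name)
  if (length(it$positions)) out$positions <- lapply(it$positions, unparse_value)
  if (length(it$rotations)) out$rotations <- lapply(it$rotations, unparse_value)
  if (length(it$sizes)) out$sizes <- lapply(it$sizes, unparse_value)
  if (length(it$colors)) out$colors <- lapply(it$colors, unparse_value)
  if (length(it$special)) out$special <- it$special
  out
}

unparse_value <- function(x) {
  if (is_token(x)) {
    tok <- list(kind = x$kind)
    if (!is.null(x$min)) tok$min <- x$min
    if (!is.null(x$max)) tok$max <- x$max
    return(list(random = tok))
  }
  x
}

#' Read / write configuration files on disk
#'
#' @param path Path to a UTF-8 YAML file.
#' @return `read_config()` returns an `arena_config`.
#' @export
read_config <- function(path) {
  parse_config(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                     collapse = "\n"))
}

#' @rdname read_config
#' @param cfg An `arena_config`.
#' @export
save_config <- function(cfg, path) {
  writeLines(write_config(cfg), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config> ", length(x$arenas), " arena(s), mode: ",
      x$episode_mode, "\n", sep = "")
  for (i in seq_along(x$arenas)) {
    a <- x$arenas[[i]]
    cat("  arena ", names(x$arenas)[i], ": timeLimit=", a$time_limit,
        " passMark=", a$pass_mark, " items=", length(a$items), "\n", sep = "")
  }
  invisible(x)
}

## ---- programmatic constructors (used by procgen and tests) -----------------

#' Build configurations programmatically
#'
#' Convenience constructors mirroring the YAML schema, used by the procedural
#' generators and handy in tests.
#'
#' @param name Object kind (see [ontology()]).
#' @param positions,rotations,sizes,colors Parallel per-instance lists; scalars
#'   are promoted (a numeric size becomes a cube).
#' @param special Named list of kind-specific parameters.
#' @return An `object_spec` / `arena_spec` / `arena_config`.
#' @export
item_spec <- function(name, positions = list(), rotations = list(),
                      sizes = list(), colors = list(), special = list()) {
  parse_item(list(name = name,
                  positions = positions, rotations = rotations,
                  sizes = sizes, colors = colors, special = special))
}

#' @rdname item_spec
#' @param items List of `object_spec`.
#' @param time_limit,pass_mark,frozen_agent_delays Arena parameters
#'   (defaults 250, 0, 0).
#' @param lights_out `NULL`, `list(intervals = list(c(start, end), ...))` or
#'   `list(period = p)`.
#' @export
arena_spec <- function(items = list(), time_limit = 250, pass_mark = 0,
                       frozen_agent_delays = 0, lights_out = NULL) {
  if (time_limit < 0 || frozen_agent_delays < 0) {
    stop("timeLimit and frozenAgentDelays must be >= 0", call. = FALSE)
  }
  structure(list(time_limit = as.numeric(time_limit),
                 pass_mark = as.numeric(pass_mark),
                 frozen_agent_delays = as.numeric(frozen_agent_delays),
                 lights_out = lights_out,
                 items = items),
            class = "arena_spec")
}

#' @rdname item_spec
#' @param arenas List of `arena_spec` (indices assigned 0, 1, ...).
#' @param episode_mode `"sequential-episodes"` or
#'   `"multi-arena-single-episode"`.
#' @export
arena_config <- function(arenas, episode_mode = "sequential-episodes") {
  if (inherits(arenas, "arena_spec")) arenas <- list(arenas)
  names(arenas) <- as.character(seq_along(arenas) - 1L)
  new_config(arenas, episode_mode)
}

#' Validate a configuration
#'
#' Re-runs all schema checks (kind names, list lengths, bounds, special
#' parameters) on an already-built configuration, returning it invisibly.
#' Errors describe the first violation found.
#'
#' @param cfg An `arena_config`.
#' @export
validate_config <- function(cfg) {
  reparsed <- parse_config(write_config(cfg))
  invisible(reparsed)
}
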