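#' The arenalab object ontology
#'
#' Every object that can populate an arena belongs to one of a fixed set of
#' kinds: immovable obstacles (walls, ramps, tunnels), movable blocks,
#' valenced goals and zones, dispensers, sign boards, and the agent itself.
#' The registry records, per kind, the physical and semantic attributes the
#' simulator needs: solidity (zones are passable), movability and mass,
#' valence sign and whether contact ends the episode, the observation
#' category a raycast reports, whether the colour is user-configurable, and
#' the default colour used by the camera renderer.
#'
#' @return A tibble with one row per object kind.
#' @export
#' @examples
#' ontology()
ontology <- function() {
  .arenalab_ontology
}

# categories reported by the raycast sensor (rows 1-6 of the 8 x r matrix)
RAY_CATEGORIES <- c("goal_positive", "goal_negative", "immovable",
                    "movable", "dispenser", "signboard")

.make_ontology <- function() {
  row <- function(kind, solid, movable, mass, zone, category, valence_sign,
                  episode_ending, bounce, fixed_color, fixed_size, scheduled,
                  r, g, b) {
    tibble::tibble(kind = kind, solid = solid, movable = movable, mass = mass,
                   zone = zone, category = category, valence_sign = valence_sign,
                   episode_ending = episode_ending, bounce = bounce,
                   fixed_color = fixed_color, fixed_size = fixed_size,
                   scheduled = scheduled, r = r, g = g, b = b)
  }
  dplyr::bind_rows(
    # immovable obstacles
    row("Wall",                      TRUE,  FALSE, Inf, FALSE, "immovable", 0, FALSE, FALSE, FALSE, FALSE, "static", 153, 153, 153),
    row("WallTransparent",           TRUE,  FALSE, Inf, FALSE, "immovable", 0, FALSE, FALSE, TRUE,  FALSE, "static", 255, 255, 255),
    row("Ramp",                      TRUE,  FALSE, Inf, FALSE, "immovable", 0, FALSE, FALSE, FALSE, FALSE, "static", 255, 0, 255),
    row("CylinderTunnel",            TRUE,  FALSE, Inf, FALSE, "immovable", 0, FALSE, FALSE, FALSE, FALSE, "static", 153, 153, 153),
    row("CylinderTunnelTransparent", TRUE,  FALSE, Inf, FALSE, "immovable", 0, FALSE, FALSE, TRUE,  FALSE, "static", 255, 255, 255),
    # movable blocks (masses are normative: light 1, heavy 2, shaped/hollow 1.5)
    row("LightBlock", TRUE, TRUE, 1,   FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 190, 190, 190),
    row("HeavyBlock", TRUE, TRUE, 2,   FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 120, 120, 120),
    row("UBlock",     TRUE, TRUE, 1.5, FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 160, 160, 160),
    row("LBlock",     TRUE, TRUE, 1.5, FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 160, 160, 160),
    row("JBlock",     TRUE, TRUE, 1.5, FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 160, 160, 160),
    row("HollowBox",  TRUE, TRUE, 1.5, FALSE, "movable", 0, FALSE, FALSE, TRUE, FALSE, "static", 170, 170, 170),
    # valenced spheres
    row("GoodGoal",            TRUE, FALSE, 1, FALSE, "goal_positive",  1, TRUE,  FALSE, FALSE, FALSE, "static", 0, 255, 0),
    row("GoodGoalBounce",      TRUE, FALSE, 1, FALSE, "goal_positive",  1, TRUE,  TRUE,  FALSE, FALSE, "static", 0, 255, 0),
    row("GoodGoalMulti",       TRUE, FALSE, 1, FALSE, "goal_positive",  1, FALSE, FALSE, FALSE, FALSE, "static", 0, 255, 128),
    row("GoodGoalMultiBounce", TRUE, FALSE, 1, FALSE, "goal_positive",  1, FALSE, TRUE,  FALSE, FALSE, "static", 0, 255, 128),
    row("BadGoal",             TRUE, FALSE, 1, FALSE, "goal_negative", -1, TRUE,  FALSE, FALSE, FALSE, "static", 255, 0, 0),
    row("BadGoalBounce",       TRUE, FALSE, 1, FALSE, "goal_negative", -1, TRUE,  TRUE,  FALSE, FALSE, "static", 255, 0, 0),
    row("BadGoalMulti",        TRUE, FALSE, 1, FALSE, "goal_negative", -1, FALSE, FALSE, FALSE, FALSE, "static", 255, 128, 0),
    row("BadGoalMultiBounce",  TRUE, FALSE, 1, FALSE, "goal_negative", -1, FALSE, TRUE,  FALSE, FALSE, "static", 255, 128, 0),
    row("DecoyGoal",           TRUE, FALSE, 1, FALSE, "goal_positive",  0, FALSE, FALSE, FALSE, FALSE, "static", 200, 200, 200),
    row("DecoyGoalBounce",     TRUE, FALSE, 1, FALSE, "goal_positive",  0, FALSE, TRUE,  FALSE, FALSE, "static", 200, 200, 200),
    # time-varying goals (valence and/or size follow a schedule; never episode-ending)
    row("GrowGoal",   TRUE, FALSE, 1, FALSE, "goal_positive", 1, FALSE, FALSE, FALSE, FALSE, "grow",   0, 255, 128),
    row("ShrinkGoal", TRUE, FALSE, 1, FALSE, "goal_positive", 1, FALSE, FALSE, FALSE, FALSE, "shrink", 0, 255, 128),
    row("RipenGoal",  TRUE, FALSE, 1, FALSE, "goal_positive", 1, FALSE, FALSE, FALSE, FALSE, "ripen",  230, 230, 0),
    row("DecayGoal",  TRUE, FALSE, 1, FALSE, "goal_positive", 1, FALSE, FALSE, FALSE, FALSE, "decay",  230, 230, 0),
    # zones: passable box volumes with valence
    row("DeathZone", FALSE, FALSE, Inf, TRUE, "goal_negative", -1, TRUE,  FALSE, FALSE, FALSE, "static", 255, 0, 0),
    row("HotZone",   FALSE, FALSE, Inf, TRUE, "goal_negative", -1, FALSE, FALSE, FALSE, FALSE, "static", 255, 165, 0),
    # dispensers and sign boards
    row("SpawnerTree",           TRUE, FALSE, Inf, FALSE, "dispenser", 0, FALSE, FALSE, TRUE, TRUE, "static", 101, 67, 33),
    row("SpawnerDispenserTall",  TRUE, FALSE, Inf, FALSE, "dispenser", 0, FALSE, FALSE, FALSE, TRUE, "static", 100, 100, 180),
    row("SpawnerDispenserShort", TRUE, FALSE, Inf, FALSE, "dispenser", 0, FALSE, FALSE, FALSE, TRUE, "static", 100, 100, 180),
    row("SpawnerButton",         TRUE, FALSE, Inf, FALSE, "dispenser", 0, FALSE, FALSE, TRUE, TRUE, "static", 245, 222, 179),
    row("SignBoard",             TRUE, FALSE, Inf, FALSE, "signboard", 0, FALSE, FALSE, FALSE, TRUE, "static", 222, 184, 135),
    # the agent: a sphere of diameter 1
    row("Agent", TRUE, TRUE, 1, FALSE, "movable", 0, FALSE, FALSE, TRUE, TRUE, "static", 50, 50, 200)
  )
}

.arenalab_ontology <- .make_ontology()

object_kinds <- function() .arenalab_ontology$kind

kind_info <- function(kind) {
  i <- match(kind, .arenalab_ontology$kind)
  if (is.na(i)) stop("unknown object kind: '", kind, "'", call. = FALSE)
  as.list(.arenalab_ontology[i, ])
}

is_known_kind <- function(kind) kind %in% .arenalab_ontology$kind

# special (kind-specific) parameters accepted in a config `special:` mapping
.special_schema <- list(
  spawner = c("count", "delay", "interval", "goalSize"),
  button  = c("spawnProbability", "weights", "spawnPosition", "resetSteps"),
  sign    = c("symbol", "grid"),
  sched   = c("fullValence", "emptyValence", "delay", "duration",
              "startSize", "endSize"),
  bounce  = c("initialSpeed", "direction")
)

special_keys_for <- function(kind) {
  info <- kind_info(kind)
  if (kind %in% c("SpawnerTree", "SpawnerDispenserTall", "SpawnerDispenserShort"))
    return(.special_schema$spawner)
  if (kind == "SpawnerButton") return(.special_schema$button)
  if (kind == "SignBoard") return(.special_schema$sign)
  if (info$scheduled != "static") return(.special_schema$sched)
  if (info$bounce) return(.special_schema$bounce)
  character(0)
}
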