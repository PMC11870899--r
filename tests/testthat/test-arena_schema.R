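test_that("parsing fills defaults and preserves explicit values", {
  cfg <- parse_config("arenas:\n  0:\n    timeLimit: 250\n")
  expect_length(cfg$arenas, 1)
  a <- cfg$arenas[[1]]
  expect_equal(a$time_limit, 250)
  expect_equal(a$pass_mark, 0)
  expect_equal(a$frozen_agent_delays, 0)
  expect_length(a$items, 0)
  # defaults applied when keys are absent entirely
  cfg2 <- parse_config("arenas:\n  0: {}\n")
  expect_equal(cfg2$arenas[[1]]$time_limit, 250)
  expect_equal(cfg2$episode_mode, "sequential-episodes")
})

test_that("items parse to per-kind object specs", {
  cfg <- parse_config("
arenas:
  0:
    items:
    - name: GoodGoal
      positions: [{x: 20, y: 0, z: 20}]
      sizes: [2]
")
  it <- cfg$arenas[[1]]$items[[1]]
  expect_equal(it$name, "GoodGoal")
  expect_equal(it$positions[[1]], list(x = 20, y = 0, z = 20))
  expect_equal(it$sizes[[1]], list(x = 2, y = 2, z = 2))
})

test_that("schema violations are rejected with informative errors", {
  expect_error(parse_config("arenas:\n  0:\n    items:\n    - name: FlyingCarpet\n"),
               "unknown object kind")
  expect_error(parse_config("arenas:\n  0:\n    items:\n    - name: Wall\n      positions: [{x: 99, y: 0, z: 2}]\n"),
               "out of arena bounds")
  expect_error(
    parse_config("arenas:\n  0:\n    items:\n    - name: Wall\n      positions: [{x: 1, y: 0, z: 2}, {x: 3, y: 0, z: 4}]\n      rotations: [0]\n"),
    "equal length")
  expect_error(parse_config("arenas:\n  0:\n    items:\n    - name: SignBoard\n      special: {count: 3}\n"),
               "unknown special parameter")
  expect_warning(parse_config("arenas:\n  0:\n    frobnicate: 1\n"),
                 "unknown arena keys")
  expect_warning(
    parse_config("arenas:\n  0:\n    items:\n    - name: LightBlock\n      positions: [{x: 5, y: 0, z: 5}]\n      colors: [{r: 1, g: 2, b: 3}]\n"),
    "colors are fixed")
})

test_that("write-then-parse is the identity on valid configurations", {
  empty <- arena_config(arena_spec())
  expect_equal(parse_config(write_config(empty)), empty)
  forage <- build_foraging_task()
  expect_equal(parse_config(write_config(forage)), forage)
  # randomisation tokens survive a round trip losslessly
  tok <- arena_config(arena_spec(list(
    item_spec("Agent", positions = list(list(x = -1, y = 0, z = 5)),
              rotations = list("random")),
    item_spec("Wall", positions = list("random"), colors = list("random"),
              sizes = list(list(x = 2, y = 1, z = 2)))
  ), time_limit = 123))
  expect_equal(parse_config(write_config(tok)), tok)
  # sentinel -1 and the explicit token form parse to the same spec
  s1 <- parse_config("arenas:\n  0:\n    items:\n    - name: Agent\n      positions: [{x: -1, y: 0, z: 5}]\n")
  s2 <- parse_config(write_config(s1))
  expect_equal(s1, s2)
})

test_that("randomness resolution is reproducible and respects bounds", {
  spec <- build_foraging_task()$arenas[[1]]
  a <- resolve_randomness(spec, seed = 7)
  b <- resolve_randomness(spec, seed = 7)
  expect_identical(a, b)
  c2 <- resolve_randomness(spec, seed = 8)
  expect_false(identical(a, c2))
  # token-free specs pass through unchanged
  plain <- empty_arena_cfg()$arenas[[1]]
  r1 <- resolve_randomness(plain, 1)
  expect_equal(r1$items[[1]]$position, list(x = 20, y = 0, z = 20))
  # agent x is randomised, z and y fixed
  ag <- a$items[[1]]
  expect_equal(ag$position$z, 5)
  expect_equal(ag$position$y, 0)
  expect_true(ag$position$x >= 0 && ag$position$x <= 40)
  # out-of-arena token bounds error
  bad <- arena_spec(list(item_spec("Wall", positions = list(
    list(random = list(kind = "position", min = c(30, 0, 0), max = c(60, 0, 10)))))))
  expect_error(resolve_randomness(bad, 1), "outside the arena")
})

test_that("random rotations are uniform over [0, 360)", {
  spec <- arena_spec(list(
    item_spec("Wall",
              positions = replicate(2000, list(x = 20, y = 0, z = 20),
                                    simplify = FALSE),
              rotations = replicate(2000, "random", simplify = FALSE))
  ))
  draws <- unlist(lapply(seq_len(5), function(s) {
    conc <- resolve_randomness(spec, seed = s)
    vapply(conc$items, function(it) it$rotation, numeric(1))
  }))
  expect_length(draws, 10000)
  expect_true(all(draws >= 0 & draws < 360))
  expect_equal(mean(draws), 180, tolerance = 0.03)
})

test_that("overlap detection flags solid pairs and ignores zones", {
  two_walls <- fix_arena(fix_obj("Wall", c(10, 0, 10), size = c(2, 2, 2)),
                         fix_obj("Wall", c(10, 0, 10), size = c(2, 2, 2)),
                         fix_obj("Agent", c(30, 0, 30)))
  ov <- detect_overlaps(two_walls)
  expect_equal(nrow(ov), 1)
  expect_equal(c(ov$i, ov$j), c(1L, 2L))
  # a zone co-located with a wall is passable, hence no conflict
  zoned <- fix_arena(fix_obj("Wall", c(10, 0, 10), size = c(2, 2, 2)),
                     fix_obj("DeathZone", c(10, 0, 10), size = c(4, 1, 4)),
                     fix_obj("Agent", c(30, 0, 30)))
  expect_equal(nrow(detect_overlaps(zoned)), 0)
  empty <- fix_arena(fix_obj("Agent", c(5, 0, 5)))
  expect_equal(nrow(detect_overlaps(empty)), 0)
  # touching faces do not count as overlap
  touching <- fix_arena(fix_obj("Wall", c(10, 0, 10), size = c(2, 2, 2)),
                        fix_obj("Wall", c(12, 0, 10), size = c(2, 2, 2)))
  expect_equal(nrow(detect_overlaps(touching)), 0)
})

test_that("precedence placement keeps earlier objects and relocates later ones", {
  # ramp listed after the wall: the ramp is the one displaced
  arena <- fix_arena(fix_obj("Agent", c(5, 0, 5)),
                     fix_obj("Wall", c(20, 0, 20), size = c(4, 2, 4)),
                     fix_obj("Ramp", c(20, 0, 20), size = c(2, 1, 2)))
  placed <- place_with_precedence(arena, seed = 1)
  expect_equal(placed$items[[2]]$position, arenalab:::vec3(20, 0, 20))
  expect_false(isTRUE(all.equal(placed$items[[3]]$position,
                                arenalab:::vec3(20, 0, 20))))
  expect_equal(nrow(detect_overlaps(placed)), 0)
  # the agent is spawned first even when listed last
  arena2 <- fix_arena(fix_obj("HeavyBlock", c(20, 0, 20), size = c(2, 2, 2)),
                      fix_obj("Agent", c(20, 0, 20)))
  placed2 <- place_with_precedence(arena2, seed = 2)
  expect_equal(placed2$items[[2]]$position, arenalab:::vec3(20, 0, 20))
  expect_false(isTRUE(all.equal(placed2$items[[1]]$position,
                                arenalab:::vec3(20, 0, 20))))
  # conflict-free arenas pass through unchanged
  ok <- fix_arena(fix_obj("Agent", c(5, 0, 5)),
                  fix_obj("Wall", c(20, 0, 20), size = c(2, 2, 2)))
  expect_identical(place_with_precedence(ok, seed = 3)$items, ok$items)
})

test_that("placement errors when no free location exists", {
  full <- fix_arena(fix_obj("Wall", c(20, 0, 20), size = c(40, 2, 40)),
                    fix_obj("Wall", c(20, 0, 20), size = c(4, 2, 4)))
  expect_error(place_with_precedence(full, seed = 1), "could not place")
})

test_that("placement is pure under seed and contains solids in the arena", {
  spec <- arena_spec(list(
    item_spec("Agent", positions = list("random")),
    item_spec("Wall", positions = list("random", "random"),
              sizes = list(list(x = 6, y = 2, z = 2), list(x = 6, y = 2, z = 2)),
              rotations = list("random", "random")),
    item_spec("GoodGoal", positions = list("random"), sizes = list(2))
  ))
  for (s in 1:10) {
    conc <- resolve_randomness(spec, seed = s)
    p1 <- place_with_precedence(conc, seed = s)
    p2 <- place_with_precedence(conc, seed = s)
    expect_identical(p1, p2)
    expect_equal(nrow(detect_overlaps(p1)), 0)
    for (it in p1$items) {
      box <- arenalab:::world_aabb(it)
      expect_true(box$min[1] >= -1e-9 && box$max[1] <= 40 + 1e-9)
      expect_true(box$min[3] >= -1e-9 && box$max[3] <= 40 + 1e-9)
    }
  }
})
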