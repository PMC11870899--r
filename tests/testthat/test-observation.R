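test_that("raycast matrices are 8 x r with odd r enforced", {
  w <- fix_world(c(20, 0, 20))
  obs <- raycast_scan(w, r = 45, angle_span = 60)
  expect_equal(dim(obs), c(8, 45))
  expect_error(raycast_scan(w, r = 4), "odd")
  expect_error(raycast_scan(w, r = 0), "odd")
  expect_error(raycast_scan(w, r = 45, angle_span = 0), "angle span")
  obs1 <- raycast_scan(w, r = 1)
  expect_equal(dim(obs1), c(8, 1))
})

test_that("rays report category and normalised distance of the nearest hit", {
  # wall dead ahead of a single forward ray
  w <- fix_world(c(20, 0, 10), 0, fix_obj("Wall", c(20, 0, 20),
                                          size = c(4, 2, 1)))
  obs <- raycast_scan(w, r = 1)
  expect_equal(unname(obs["immovable", 1]), 1)
  expect_equal(unname(obs["no_hit", 1]), 0)
  expect_equal(unname(obs["distance", 1]), 9.5 / 60)   # 10 units minus the near face
  # a goal nearer than the wall wins the ray
  w2 <- fix_world(c(20, 0, 10), 0,
                  fix_obj("Wall", c(20, 0, 20), size = c(4, 2, 1)),
                  fix_obj("GoodGoal", c(20, 0, 15), size = 1))
  obs2 <- raycast_scan(w2, r = 1)
  expect_equal(unname(obs2["goal_positive", 1]), 1)
  expect_equal(unname(obs2["distance", 1]), 4.5 / 60)
  # unobstructed rays set the no-hit flag (the boundary fence is not a target)
  empty <- raycast_scan(fix_world(c(20, 0, 20)), r = 5)
  expect_true(all(empty["no_hit", ] == 1))
  expect_true(all(empty["distance", ] == 1))
})

test_that("rays fan evenly over the span, left to right", {
  # goals at -30, 0, +30 degrees relative to the agent's heading land on the
  # first, centre, and last of 45 rays over 60 degrees
  place_at_angle <- function(angle, dist = 10) {
    h <- arenalab:::heading_vec(angle)
    c(20 + dist * h[1], 0, 20 + dist * h[2])
  }
  w <- fix_world(c(20, 0, 20), 0,
                 fix_obj("GoodGoal", place_at_angle(-30), size = 0.8),
                 fix_obj("BadGoal", place_at_angle(0), size = 0.8),
                 fix_obj("GoodGoalMulti", place_at_angle(30), size = 0.8))
  obs <- raycast_scan(w, r = 45, angle_span = 60)
  expect_equal(unname(obs["goal_positive", 1]), 1)    # leftmost ray
  expect_equal(unname(obs["goal_negative", 23]), 1)   # centre ray, directly ahead
  expect_equal(unname(obs["goal_positive", 45]), 1)   # rightmost ray
})

test_that("each ray column is exclusively a category hit or a no-hit", {
  spec <- arena_spec(list(
    item_spec("Agent", positions = list("random"), rotations = list("random")),
    item_spec("Wall", positions = list("random"),
              sizes = list(list(x = 4, y = 2, z = 1))),
    item_spec("GoodGoal", positions = list("random")),
    item_spec("DeathZone", positions = list("random"),
              sizes = list(list(x = 4, y = 1, z = 4))),
    item_spec("LightBlock", positions = list("random"))
  ))
  for (s in 1:8) {
    placed <- place_with_precedence(resolve_randomness(spec, s), s)
    w <- world_init(placed, s)
    obs <- raycast_scan(w, r = 15, angle_span = 120)
    flags <- colSums(obs[1:6, , drop = FALSE])
    expect_true(all(flags + obs["no_hit", ] == 1))
    expect_true(all(obs["distance", ] >= 0 & obs["distance", ] <= 1))
  }
})

test_that("camera bounds are enforced and empty arenas show scenery only", {
  w <- fix_world(c(20, 0, 20))
  expect_error(render_camera(w, k = 3), "4 <= k <= 512")
  expect_error(render_camera(w, k = 600), "4 <= k <= 512")
  img <- render_camera(w, k = 8)
  expect_equal(dim(img), c(8, 8, 3))
  cols <- unique(matrix(img, ncol = 3))
  scenery <- rbind(c(135, 206, 235), c(180, 180, 180), c(245, 245, 245))
  for (i in seq_len(nrow(cols))) {
    expect_true(any(apply(scenery, 1, function(s) all(s == cols[i, ]))))
  }
})

test_that("the camera sees opaque objects but not transparent ones", {
  w <- fix_world(c(20, 0, 10), 0,
                 fix_obj("GoodGoal", c(20, 0, 14), size = 2))
  img <- render_camera(w, k = 9)
  centre <- img[5, 5, ]
  expect_equal(unname(centre), c(0, 255, 0))  # the goal's default green
  wt <- fix_world(c(20, 0, 10), 0,
                  fix_obj("WallTransparent", c(20, 0, 14), size = c(8, 4, 1)))
  img2 <- render_camera(wt, k = 9)
  expect_false(all(img2[5, 5, ] == c(255, 255, 255)))
  # but the transparent wall does register on raycasts as immovable
  obs <- raycast_scan(wt, r = 1)
  expect_equal(unname(obs["immovable", 1]), 1)
})

test_that("grayscale collapses the image to a luminance matrix", {
  w <- fix_world(c(20, 0, 10), 0, fix_obj("Wall", c(20, 0, 11.2),
                                          size = c(20, 10, 1)))
  g <- render_camera(w, k = 6, grayscale = TRUE)
  expect_equal(dim(g), c(6, 6))
  # wall fills the whole view: constant luminance
  expect_equal(length(unique(as.vector(g))), 1)
  expect_equal(g[1, 1], 0.299 * 153 + 0.587 * 153 + 0.114 * 153)
})

test_that("lights-out zeroes visual channels on scheduled steps only", {
  w <- fix_world(c(20, 0, 10), 0, fix_obj("Wall", c(20, 0, 20),
                                          size = c(4, 2, 1)))
  obs <- raycast_scan(w, r = 5)
  sched <- list(intervals = list(c(10, 20)))
  expect_identical(apply_lights_out(obs, sched, 5), obs)
  dark <- apply_lights_out(obs, sched, 15)
  expect_true(all(dark == 0))
  expect_identical(apply_lights_out(obs, sched, 20), obs)  # end is exclusive
  # alternating schedule: second phase is dark
  alt <- list(period = 25)
  expect_identical(apply_lights_out(obs, alt, 10), obs)
  expect_true(all(apply_lights_out(obs, alt, 30) == 0))
  expect_identical(apply_lights_out(obs, alt, 55), obs)
  # idempotent; no schedule is the identity
  expect_identical(apply_lights_out(dark, sched, 15), dark)
  expect_identical(apply_lights_out(obs, NULL, 15), obs)
})

test_that("lights-out masks bundles but leaves proprioception intact", {
  cfg <- arena_config(arena_spec(list(
    item_spec("Agent", positions = list(list(x = 20, y = 0, z = 10))),
    item_spec("Wall", positions = list(list(x = 20, y = 0, z = 20)),
              sizes = list(list(x = 4, y = 2, z = 1)))
  ), time_limit = 100, lights_out = list(intervals = list(c(0, 5)))))
  env <- make_env(cfg, observations = list(
    raycast = list(r = 5, angle_span = 60), proprio = TRUE), seed = 1)
  obs <- env_reset(env)
  expect_true(all(obs$raycast == 0))
  expect_equal(obs$proprio$health, 100)
  expect_equal(unname(obs$proprio$position["z"]), 10)
  for (k in 1:6) res <- env_step(env, "NoAction")
  expect_false(all(res$observation$raycast == 0))  # lights back on
})

test_that("camera and raycast agree on a goal dead ahead", {
  w <- fix_world(c(20, 0, 10), 0, fix_obj("GoodGoal", c(20, 0, 20), size = 2))
  obs <- raycast_scan(w, r = 1)
  d_ray <- unname(obs["distance", 1]) * 60
  expect_equal(d_ray, 9, tolerance = 1e-6)  # 10 units minus the 1-unit radius
  img <- render_camera(w, k = 11)
  expect_equal(unname(img[6, 6, ]), c(0, 255, 0))
})
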