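test_that("the per-step decrement is 1/t, 10x inside hot zones, 0 when t = 0", {
  expect_equal(step_reward_delta(FALSE, 100), -0.01)
  expect_equal(step_reward_delta(TRUE, 100), -0.10)
  expect_equal(step_reward_delta(FALSE, 0), 0)
  expect_equal(step_reward_delta(TRUE, 0), 0)
  expect_equal(step_reward_delta(TRUE, 100) / step_reward_delta(FALSE, 100), 10)
  expect_error(step_reward_delta(FALSE, -1), ">= 0")
})

test_that("contact effects follow the object's valence class", {
  hit <- on_contact("GoodGoal", 2)
  expect_equal(hit, list(reward_delta = 2, terminate = TRUE, remove = TRUE))
  expect_equal(on_contact("BadGoal", 1.5),
               list(reward_delta = -1.5, terminate = TRUE, remove = TRUE))
  multi <- on_contact("GoodGoalMulti", 0.5)
  expect_equal(multi$reward_delta, 0.5)
  expect_false(multi$terminate)
  expect_true(multi$remove)
  expect_equal(on_contact("BadGoalMulti", 0.5)$reward_delta, -0.5)
  decoy <- on_contact("DecoyGoal", 2)
  expect_equal(decoy$reward_delta, 0)
  expect_false(decoy$terminate)
  expect_true(decoy$remove)
  death <- on_contact("DeathZone", NA)
  expect_equal(death$reward_delta, -1)
  expect_true(death$terminate)
  expect_false(death$remove)
  expect_error(on_contact("Wall", 1), "not a valenced object")
})

test_that("collecting a half-size goal restores fifty health", {
  hit <- on_contact("GoodGoalMulti", 0.5)
  expect_equal(update_health(40, hit$reward_delta)$health, 90)
  expect_equal(update_health(80, hit$reward_delta)$health, 100)  # clamp at 100
})

test_that("health moves 100 points per unit reward and fails at zero", {
  expect_equal(update_health(100, -0.01), list(health = 99, failed = FALSE))
  expect_equal(update_health(0.5, -0.01), list(health = 0, failed = TRUE))
  expect_equal(update_health(100, 0.5)$health, 100)
  expect_error(update_health(150, 0))
})

test_that("valence schedules interpolate linearly and clamp at the ends", {
  static <- arenalab:::goal_schedule("static", full = 2, empty = 0)
  expect_equal(scheduled_valence(static, 0), 2)
  expect_equal(scheduled_valence(static, 999), 2)
  decay <- arenalab:::goal_schedule("decay", full = 1, empty = 0,
                                    delay = 10, duration = 20)
  expect_equal(scheduled_valence(decay, 0), 1)
  expect_equal(scheduled_valence(decay, 10), 1)
  expect_equal(scheduled_valence(decay, 20), 0.5)
  expect_equal(scheduled_valence(decay, 30), 0)
  expect_equal(scheduled_valence(decay, 1000), 0)
  ripen <- arenalab:::goal_schedule("ripen", full = 1, empty = 0,
                                    delay = 0, duration = 20)
  expect_equal(scheduled_valence(ripen, 10), 0.5)
})

test_that("decay and ripen are mirror images", {
  for (delay in c(0, 5, 17)) {
    for (duration in c(1, 10, 40)) {
      d <- arenalab:::goal_schedule("decay", full = 1.5, empty = 0.25,
                                    delay = delay, duration = duration)
      r <- arenalab:::goal_schedule("ripen", full = 1.5, empty = 0.25,
                                    delay = delay, duration = duration)
      for (step in c(0, delay, delay + duration %/% 2, delay + duration, 500)) {
        expect_equal(scheduled_valence(d, step) + scheduled_valence(r, step),
                     1.5 + 0.25)
      }
    }
  }
})

test_that("grow/shrink sizes follow the schedule and freeze when blocked", {
  grow <- arenalab:::goal_schedule("grow", full = 3, empty = 1, delay = 0,
                                   duration = 20, start_size = 1, end_size = 3)
  expect_equal(scheduled_size(grow, 10, TRUE), 2)
  expect_equal(scheduled_size(grow, 10, FALSE, last_size = 1.4), 1.4)
  shrink <- arenalab:::goal_schedule("shrink", full = 3, empty = 3, delay = 0,
                                     duration = 10, start_size = 3, end_size = 3)
  expect_equal(scheduled_size(shrink, 7, TRUE), 3)
  expect_error(scheduled_size(arenalab:::goal_schedule("static", 1, 0), 1, TRUE),
               "grow/shrink")
})

test_that("episode outcome is pass iff reward reaches the pass mark", {
  expect_equal(episode_outcome(1.0, 0.5), "pass")
  expect_equal(episode_outcome(0.49, 0.5), "fail")
  expect_equal(episode_outcome(0, 0), "pass")
})

test_that("reward accounting is exact over a logged episode", {
  cfg <- arena_config(arena_spec(list(
    item_spec("Agent", positions = list(list(x = 20, y = 0, z = 10))),
    item_spec("GoodGoalMulti", positions = list(list(x = 20, y = 0, z = 14)),
              sizes = list(0.5)),
    item_spec("GoodGoal", positions = list(list(x = 20, y = 0, z = 18)),
              sizes = list(1))
  ), time_limit = 200))
  env <- make_env(cfg, observations = list(proprio = TRUE), seed = 1)
  env_reset(env)
  repeat {
    r <- env_step(env, "Forwards")
    if (r$terminated || r$truncated) break
  }
  log <- episode_log(env)
  expect_equal(sum(log$reward_delta), attr(log, "final_reward"))
  expect_equal(log$reward[nrow(log)], attr(log, "final_reward"))
  # both goals collected: +0.5, then +1 ends the episode
  expect_equal(attr(log, "termination_cause"), "goal")
  expect_equal(attr(log, "final_reward"),
               1.5 - nrow(log) / 200, tolerance = 1e-12)
})

test_that("with a step budget and no objects the reward runs down to -1", {
  for (t in c(37, 50, 100)) {
    env <- make_env(empty_arena_cfg(time_limit = t),
                    observations = list(proprio = TRUE), seed = 1)
    env_reset(env)
    n <- 0
    repeat {
      r <- env_step(env, "NoAction")
      n <- n + 1
      if (r$terminated || r$truncated) break
    }
    expect_equal(n, t)
    expect_true(r$truncated)
    expect_equal(env$reward, -1, tolerance = 1e-9)
    expect_equal(env$cause, "timeout")
  }
})

test_that("death zones override hot zones where they overlap", {
  cfg <- arena_config(arena_spec(list(
    item_spec("Agent", positions = list(list(x = 20, y = 0, z = 20))),
    item_spec("HotZone", positions = list(list(x = 20, y = 0, z = 20)),
              sizes = list(list(x = 6, y = 2, z = 6))),
    item_spec("DeathZone", positions = list(list(x = 20, y = 0, z = 20)),
              sizes = list(list(x = 6, y = 2, z = 6)))
  ), time_limit = 100))
  env <- make_env(cfg, observations = list(proprio = TRUE), seed = 1)
  env_reset(env)
  r <- env_step(env, "NoAction")
  expect_true(r$terminated)
  expect_equal(env$cause, "deathzone")
  # -1 for the death zone plus the plain 1/t step decrement (not the hot rate)
  expect_equal(r$reward_delta, -1 - 1 / 100)
})
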