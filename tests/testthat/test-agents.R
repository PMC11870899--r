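test_that("default random-agent decisions are uniform over the nine actions", {
  params <- arenalab:::random_params(rep(1, 9),
                                     list(kind = "fixed", n = 1), 0)
  rng <- arenalab:::rng_new(123)
  n <- 90000
  counts <- setNames(numeric(9), actions())
  memory <- NULL
  for (k in seq_len(n)) {
    out <- random_action(params, rng, memory)
    memory <- out$memory
    counts[out$action] <- counts[out$action] + 1
  }
  freq <- counts / n
  expect_true(all(abs(freq - 1 / 9) <= 0.005))
  # goodness of fit at alpha = 0.01
  gof <- stats::chisq.test(counts, p = rep(1 / 9, 9))
  expect_gt(gof$p.value, 0.01)
})

test_that("repeat lengths have mean 5, sd about 1, and are never below 1", {
  draws <- random_repeat_lengths(10000, seed = 0)
  expect_equal(mean(draws), 5, tolerance = 0.01)     # within +-0.05
  expect_true(abs(mean(draws) - 5) <= 0.05)
  expect_true(abs(stats::sd(draws) - 1) <= 0.06)     # rounding widens sd slightly
  expect_equal(min(draws), 1)
  expect_true(all(draws == floor(draws)))
})

test_that("action weights and repeat kinds are honoured", {
  w <- rep(0, 9); w[2] <- 1   # all weight on Forwards
  params <- arenalab:::random_params(w, list(kind = "fixed", n = 3), 0)
  rng <- arenalab:::rng_new(1)
  memory <- NULL
  for (k in 1:30) {
    out <- random_action(params, rng, memory)
    memory <- out$memory
    expect_equal(out$action, "Forwards")
  }
  expect_error(arenalab:::random_params(rep(0, 9), list(kind = "fixed", n = 1), 0),
               "positive sum")
  geo <- random_repeat_lengths(1000, list(kind = "geometric", p = 0.5), seed = 2)
  expect_true(all(geo >= 1))
})

test_that("action correlation biases draws towards recent actions", {
  w <- rep(1, 9)
  rng <- arenalab:::rng_new(9)
  biased <- arenalab:::random_params(w, list(kind = "fixed", n = 1), 0.8)
  memory <- NULL
  acts <- character(3000)
  for (k in seq_along(acts)) {
    out <- random_action(biased, rng, memory)
    memory <- out$memory
    acts[k] <- out$action
  }
  # strong recency weighting produces runs: repeats far above the 1/9 base rate
  rep_rate <- mean(acts[-1] == acts[-length(acts)])
  expect_gt(rep_rate, 0.3)
})

test_that("the forager steers by ray index and recovers when stuck", {
  params <- list(variant = "forager", ray_count = 45, angle_span = 60,
                 stuck_speed = 0.01)
  mk_obs <- function(goal_col = NULL) {
    m <- matrix(0, 8, 45,
                dimnames = list(c(arenalab:::RAY_CATEGORIES, "no_hit", "distance"),
                                NULL))
    m["no_hit", ] <- 1; m["distance", ] <- 1
    if (!is.null(goal_col)) {
      m["no_hit", goal_col] <- 0
      m["goal_positive", goal_col] <- 1
      m["distance", goal_col] <- 0.2
    }
    structure(m, class = c("raycast_obs", "matrix", "array"))
  }
  rng <- arenalab:::rng_new(1)
  expect_equal(heuristic_action(mk_obs(23), 0.3, params, rng = rng)$action,
               "Forwards")
  expect_equal(heuristic_action(mk_obs(1), 0.3, params, rng = rng)$action,
               "ForwardsLeft")
  expect_equal(heuristic_action(mk_obs(45), 0.3, params, rng = rng)$action,
               "ForwardsRight")
  expect_equal(heuristic_action(mk_obs(), 0.3, params, rng = rng)$action, "Left")
  expect_error(heuristic_action(mk_obs()[, 1:10], 0.3, params, rng = rng),
               "8 x 45")
  # stuck: five slow steps, then ForwardsLeft/ForwardsRight at one half each
  stuck_mem <- list(speeds = rep(0, 5), prev = "Forwards")
  picks <- vapply(seq_len(10000), function(i) {
    heuristic_action(mk_obs(23), 0, params, stuck_mem, rng)$action
  }, character(1))
  expect_true(all(picks %in% c("ForwardsLeft", "ForwardsRight")))
  expect_equal(mean(picks == "ForwardsLeft"), 0.5, tolerance = 0.04)
  expect_true(abs(mean(picks == "ForwardsLeft") - 0.5) < 0.02)
})

test_that("the operant navigator repeats blind and turns when stationary", {
  params <- list(variant = "operant", ray_count = 5, angle_span = 60,
                 stuck_speed = 0.01)
  m <- matrix(0, 8, 5,
              dimnames = list(c(arenalab:::RAY_CATEGORIES, "no_hit", "distance"),
                              NULL))
  m["no_hit", ] <- 1; m["distance", ] <- 1
  rng <- arenalab:::rng_new(1)
  # nothing detected: repeats its previous action
  mem <- list(speeds = numeric(0), prev = "ForwardsRight")
  expect_equal(heuristic_action(m, 0.3, params, mem, rng)$action, "ForwardsRight")
  # stationary: moves forwards and left
  expect_equal(heuristic_action(m, 0, params, mem, rng)$action, "ForwardsLeft")
  # steers towards a button (dispenser category)
  m2 <- m; m2["no_hit", 4] <- 0; m2["dispenser", 4] <- 1; m2["distance", 4] <- 0.3
  expect_equal(heuristic_action(m2, 0.3, params, mem, rng)$action,
               "ForwardsRight")
})

test_that("scripted oracles solve their worked tasks", {
  log <- run_episode(oracle_policy("operant"),
                     build_operant_task(stage = 1, time_limit = 0),
                     seed = 2, max_steps = 600)
  expect_equal(attr(log, "final_reward"), 1)
  expect_equal(attr(log, "outcome"), "pass")   # passMark 0.5
  logF <- run_episode(oracle_policy("foraging"),
                      build_foraging_task(time_limit = 0),
                      seed = 3, max_steps = 1200)
  expect_equal(attr(logF, "final_reward"), 20)  # all ten size-2 goals
  # empty arena: NoAction forever
  logE <- run_episode(oracle_policy("foraging"), empty_arena_cfg(time_limit = 20),
                      seed = 1)
  expect_true(all(logE$action == "NoAction"))
})

test_that("the heuristic forager beats the random agent on the foraging task", {
  res <- run_battery(
    agents = list(random = random_policy(),
                  heuristic = heuristic_policy("forager")),
    configs = list(foraging = build_foraging_task()),
    episodes_per_config = 15, seed = 21, max_steps = 300)
  med <- chance_summary(res)
  expect_gt(med$median_reward[med$agent == "heuristic"],
            med$median_reward[med$agent == "random"])
})
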