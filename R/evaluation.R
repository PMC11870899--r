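#' Run an agent x configuration battery
#'
#' Every (agent, configuration) pair is run `episodes_per_config` times with
#' per-episode seeds derived from `seed`, so the whole sweep is reproducible.
#' Results come back as a tidy table, one row per episode.
#'
#' @param agents Named list of policies (see [random_policy()] and friends).
#' @param configs Named list of `arena_config` (names become `config_id`).
#' @param episodes_per_config Episodes per pair.
#' @param seed Integer master seed.
#' @param levels Optional named vector/list mapping `config_id` to a level
#'   label (defaults to the config id itself).
#' @param max_steps Per-episode safety cap (default 1000).
#' @return An `arena_battery` tibble with columns `agent`, `config_id`,
#'   `level`, `episode`, `final_reward`, `outcome`, `steps`, `seed`.
#' @export
run_battery <- function(agents, configs, episodes_per_config = 10,
                        seed = 0L, levels = NULL, max_steps = 1000L) {
  if (is.null(names(agents))) {
    names(agents) <- vapply(agents, function(a) a$name, character(1))
  }
  if (is.null(names(configs))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  rows <- purrr::imap(agents, function(agent, aname) {
    purrr::imap(configs, function(cfg, cname) {
      lvl <- if (!is.null(levels)) as.character(levels[[cname]]) else cname
      purrr::map(seq_len(episodes_per_config), function(ep) {
        ep_seed <- derive_seed(seed, match(aname, names(agents)),
                               match(cname, names(configs)), ep)
        log <- run_episode(agent, cfg, seed = ep_seed, max_steps = max_steps)
        tibble::tibble(agent = aname, config_id = cname, level = lvl,
                       episode = ep,
                       final_reward = attr(log, "final_reward"),
                       outcome = attr(log, "outcome") %||% NA_character_,
                       steps = nrow(log), seed = ep_seed)
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  structure(out, class = c("arena_battery", class(out)))
}

#' Pass rates by level
#'
#' The proportion of episodes passed per (agent, level); exact integer
#' arithmetic on the episode table. Levels with no episodes are absent.
#'
#' @param result An `arena_battery` from [run_battery()].
#' @return A tibble with columns `agent`, `level`, `episodes`, `passes`,
#'   `pass_rate`.
#' @export
pass_rate_by_level <- function(result) {
  stopifnot(nrow(result) > 0)
  result |>
    dplyr::group_by(.data$agent, .data$level) |>
    dplyr::summarise(episodes = dplyr::n(),
                     passes = sum(.data$outcome == "pass", na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(pass_rate = .data$passes / .data$episodes)
}

#' Chance-performance summary
#'
#' Median and interquartile range of final reward per agent; the random
#' agent's row is the conventional chance reference for the battery.
#'
#' @param result An `arena_battery`.
#' @return A tibble with `agent`, `episodes`, `median_reward`, `q25`, `q75`.
#' @export
chance_summary <- function(result) {
  result |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(episodes = dplyr::n(),
                     median_reward = stats::median(.data$final_reward),
                     q25 = stats::quantile(.data$final_reward, 0.25),
                     q75 = stats::quantile(.data$final_reward, 0.75),
                     .groups = "drop")
}
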