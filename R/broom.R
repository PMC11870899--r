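#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for episode logs and battery results
#'
#' `tidy()` returns the per-step (or per-episode) table as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x An `arena_episode_log` or `arena_battery`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy arena_episode_log
#' @export
tidy.arena_episode_log <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.arena_episode_log
#' @method glance arena_episode_log
#' @export
glance.arena_episode_log <- function(x, ...) {
  tibble::tibble(
    steps = nrow(x),
    final_reward = attr(x, "final_reward"),
    final_health = attr(x, "final_health"),
    outcome = attr(x, "outcome") %||% NA_character_,
    termination_cause = attr(x, "termination_cause") %||% NA_character_
  )
}

#' @rdname tidy.arena_episode_log
#' @method tidy arena_battery
#' @export
tidy.arena_battery <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.arena_episode_log
#' @method glance arena_battery
#' @export
glance.arena_battery <- function(x, ...) {
  chance_summary(x) |>
    dplyr::mutate(pass_rate = vapply(.data$agent, function(a) {
      mean(x$outcome[x$agent == a] == "pass", na.rm = TRUE)
    }, numeric(1)))
}

#' Plot an episode trajectory
#'
#' Bird's-eye view of the agent's path through the 40 x 40 arena, coloured by
#' step, with the start marked.
#'
#' @param object An `arena_episode_log`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot arena_episode_log
#' @export
autoplot.arena_episode_log <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, colour = .data$step)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = df[1, ], shape = 4, size = 3, colour = "red") +
    ggplot2::coord_fixed(xlim = c(0, 40), ylim = c(0, 40)) +
    ggplot2::labs(x = "x (units)", y = "z (units)", colour = "step",
                  title = "Agent trajectory",
                  subtitle = paste0("outcome: ", attr(object, "outcome") %||% "-",
                                    ", reward: ",
                                    signif(attr(object, "final_reward"), 3))) +
    ggplot2::theme_minimal()
}

#' Plot battery score distributions
#'
#' Final-reward distributions per agent (one box per agent and level),
#' mirroring the usual agent-comparison figures for arena batteries.
#'
#' @param object An `arena_battery`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot arena_battery
#' @export
autoplot.arena_battery <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$agent, y = .data$final_reward,
                                   fill = .data$agent)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = NULL, y = "final episode reward") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a raycast observation
#'
#' Distance profile across the fan with hit categories coloured; a compact
#' diagnostic for heuristic-agent debugging.
#'
#' @param object A `raycast_obs`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raycast_obs
#' @export
autoplot.raycast_obs <- function(object, ...) {
  r <- ncol(object)
  cat_ix <- apply(object[1:6, , drop = FALSE], 2, function(col) {
    i <- which(col == 1)
    if (length(i)) RAY_CATEGORIES[i[1]] else "none"
  })
  df <- tibble::tibble(ray = seq_len(r) - (r + 1) / 2,
                       distance = object["distance", ],
                       category = cat_ix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ray, y = .data$distance,
                                   colour = .data$category)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ray, yend = 0)) +
    ggplot2::labs(x = "ray (offset from centre)", y = "normalised distance") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
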