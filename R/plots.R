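#' Plot a self-esteem trajectory
#'
#' Self-esteem (solid) and need for admiration (dashed) over time, with
#' admiration and rivalry acts marked, one panel per agent.
#'
#' @param object A `ser_trajectory` tibble.
#' @param agents Agent ids to show (default: the focal agent).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ser_trajectory <- function(object, agents = 1L, ...) {
  d <- dplyr::filter(object, .data$agent_id %in% agents)
  acts <- dplyr::filter(d, .data$action %in% c("admiration", "rivalry"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$se), linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$nfa), linetype = "dashed",
                       linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(
      data = acts,
      ggplot2::aes(y = .data$se, colour = .data$action,
                   shape = .data$action),
      size = 1.6
    ) +
    ggplot2::scale_colour_manual(
      values = c(admiration = "#1b9e77", rivalry = "#d95f02")
    ) +
    ggplot2::scale_shape_manual(values = c(admiration = 17, rivalry = 16)) +
    ggplot2::facet_wrap(~agent_id, ncol = 1) +
    ggplot2::labs(x = "timestep", y = "self-esteem",
                  colour = "regulation", shape = "regulation") +
    ggplot2::theme_minimal()
}

#' Plot threshold learning time courses
#'
#' Admiration and rivalry thresholds of the learning agent over time, one
#' line per run.
#'
#' @param object A `ser_study2` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ser_study2 <- function(object, ...) {
  d <- object$time_course |>
    tidyr::pivot_longer(c("ts_admi", "ts_riva"), names_to = "threshold",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value,
                                  group = interaction(.data$run,
                                                      .data$threshold),
                                  colour = .data$threshold)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(ts_admi = "#1b9e77", ts_riva = "#d95f02"),
      labels = c(ts_admi = "admiration", ts_riva = "rivalry")
    ) +
    ggplot2::labs(x = "timestep", y = "behaviour-initiation threshold",
                  colour = NULL,
                  title = paste0("Threshold learning (",
                                 object$environment$name, " environment)")) +
    ggplot2::theme_minimal()
}

#' Plot z-scored group-level metrics
#'
#' Group means of the z-standardised trait proxies and self-esteem metrics.
#'
#' @param object A `ser_study4` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ser_study4 <- function(object, ...) {
  d <- object$group_summary |>
    tidyr::pivot_longer(c("agency_proxy_z", "antagonism_proxy_z",
                          "se_median_z", "se_variance_z"),
                        names_to = "metric", values_to = "z")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$z)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "z-scored group mean") +
    ggplot2::theme_minimal()
}
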