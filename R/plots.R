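#' Plot an opinion trajectory
#'
#' Per-step counts of negative, neutral and positive agents over the
#' opinion stage.
#'
#' @param object An `opinion_run` with a recorded trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot opinion_run
#' @export
autoplot.opinion_run <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("this run was executed without trajectory recording")
  }
  long <- tidyr::pivot_longer(object$trajectory,
    cols = dplyr::starts_with("n_"),
    names_to = "state", names_prefix = "n_", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$step, y = .data$count, colour = .data$state
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      negative = "#c0392b", neutral = "#7f8c8d", positive = "#27ae60"
    )) +
    ggplot2::labs(
      x = "opinion-diffusion step", y = "agents", colour = "opinion",
      title = "Opinion adoption over time"
    )
}

#' Plot an SIR time series
#'
#' @param object A `sir_run` with a recorded trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sir_run
#' @export
autoplot.sir_run <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("this run was executed without trajectory recording")
  }
  long <- tidyr::pivot_longer(object$trajectory,
    cols = c("S", "I", "R"),
    names_to = "compartment", values_to = "count"
  )
  long$compartment <- factor(long$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$step, y = .data$count, colour = .data$compartment
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "SIR step", y = "agents (unvaccinated subpopulation)",
      title = "Epidemic time series"
    )
}

#' Plot the replicate distribution of a scenario
#'
#' Epidemic sizes of all replicates, grouped by network, with the pooled
#' mean and its 95% confidence band.
#'
#' @param object A `vaxcamp_scenario`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vaxcamp_scenario
#' @export
autoplot.vaxcamp_scenario <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$replicates, ggplot2::aes(
    x = factor(.data$network), y = .data$size
  )) +
    ggplot2::geom_hline(
      yintercept = s$mean_size, colour = "#2c3e50", linetype = 2
    ) +
    ggplot2::geom_rect(
      xmin = -Inf, xmax = Inf,
      ymin = s$mean_size - s$ci95_halfwidth,
      ymax = s$mean_size + s$ci95_halfwidth,
      fill = "#2c3e50", alpha = 0.02, inherit.aes = FALSE
    ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = "replicate network", y = "final epidemic size",
      title = sprintf(
        "Epidemic size: mean %.1f (95%% CI half-width %.1f)",
        s$mean_size, s$ci95_halfwidth
      )
    )
}

#' Plot a parameter sweep
#'
#' Mean final epidemic size against the swept value with the 95% confidence
#' ribbon.
#'
#' @param object A `vaxcamp_sweep`.
#' @param log_x Use a log10 x axis (natural for rate sweeps).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vaxcamp_sweep
#' @export
autoplot.vaxcamp_sweep <- function(object, log_x = FALSE, ...) {
  p <- ggplot2::ggplot(object$summary, ggplot2::aes(
    x = .data$value, y = .data$mean_size
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_size - .data$ci95_halfwidth,
        ymax = .data$mean_size + .data$ci95_halfwidth
      ),
      fill = "#3498db", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "#2980b9") +
    ggplot2::geom_point(colour = "#2980b9") +
    ggplot2::labs(
      x = object$axis, y = "mean final epidemic size",
      title = sprintf("Epidemic size along the %s axis", object$axis)
    )
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a target-set neighbourhood histogram
#'
#' Tile plot of the (anti-vaccine neighbours) x (neutral neighbours)
#' profile of targeted agents, as produced by
#' [target_neighborhood_histogram()] or [aggregate_histograms()].
#'
#' @param hist Tibble with `n_minus`, `n_zero` and a count column
#'   (`n_agents` or `mean_agents`).
#' @return A ggplot.
#' @export
plot_target_histogram <- function(hist) {
  fill <- if ("mean_agents" %in% names(hist)) "mean_agents" else "n_agents"
  ggplot2::ggplot(hist, ggplot2::aes(
    x = .data$n_minus, y = .data$n_zero, fill = .data[[fill]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "anti-vaccine neighbours", y = "neutral neighbours",
      fill = "targeted\nagents",
      title = "Neighbourhood profile of the target set"
    )
}
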