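#' Plot individual and population preference functions
#'
#' One curve per female over the male trait grid, with the population-level
#' preference (the across-female average) overlaid as a heavy line.
#'
#' @param object A `"pref_response"` tibble from [response_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pref_response <- function(object, ...) {
  pop <- population_preference(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$trait, y = .data$response,
                               group = .data$female_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = pop,
                       ggplot2::aes(y = .data$preference, group = 1),
                       linewidth = 1.2, colour = "firebrick") +
    ggplot2::labs(x = "male trait value", y = "mating response",
                  title = "Individual (grey) and population (red) preference functions") +
    ggplot2::theme_minimal()
}

#' Plot preferences over attractiveness-ranked males
#'
#' Each female's responses re-indexed by the males' population
#' attractiveness ranks; crossing curves mean females disagree on the
#' rank order of males.
#'
#' @param object A `"pref_ranked"` tibble from [preference_by_rank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pref_ranked <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$attract_rank, y = .data$response,
                               group = .data$female_id,
                               colour = .data$female_id)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "male attractiveness rank (10 = most attractive)",
                  y = "mating response") +
    ggplot2::theme_minimal()
}

#' Plot the attractiveness-choosiness regression
#'
#' Scatter of female choosiness against (inverse) male attractiveness per
#' shared genotype, with the fitted least-squares line.
#'
#' @param object A [genetic_correlation()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genetic_correlation <- function(object, ...) {
  xlab <- if (object$transform == "inverse") {
    "male global attractiveness (1 / mean copulation latency, 1/s)"
  } else {
    "male global attractiveness (mean copulation latency, s)"
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x, y = .data$choosiness)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = xlab, y = "female choosiness (SD of cell means, s)",
      title = sprintf("r^2 = %.3f, p = %.3g (n = %d lines)",
                      object$r_squared, object$p_value, object$n_lines)) +
    ggplot2::theme_minimal()
}

#' Plot per-line preference functions from cell means
#'
#' Cell means (one panel per chooser line) over partner lines ordered by
#' global attractiveness, the empirical analogue of ranked preference
#' functions; error bars are the within-cell trial SDs.
#'
#' @param cells A [cell_means()] table.
#' @return A ggplot object.
#' @export
plot_line_preferences <- function(cells) {
  stopifnot(is.data.frame(cells))
  attract <- global_attractiveness(cells)
  ord <- attract$partner_line[order(attract$attractiveness, decreasing = TRUE)]
  dat <- dplyr::mutate(cells,
                       partner_line = factor(.data$partner_line, levels = ord))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$partner_line, y = .data$mean,
                                    group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
      ymax = .data$mean + dplyr::coalesce(.data$sd, 0)), size = 0.2) +
    ggplot2::facet_wrap(~chooser_line) +
    ggplot2::labs(x = "partner line (most attractive first)",
                  y = sprintf("%s (s)", dat$channel[1L])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
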