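# ggplot2 views of bias results.

#' Plot bias measures against correlation
#'
#' Draws the pooled bias measures (with 95% confidence ribbons) against the
#' confounder-treatment correlation, one line per varied-parameter value,
#' facetted by measure and event — the standard way to read a scenario's
#' results.
#'
#' @param object A `"scenario_result"` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      varied = factor(.data$varied_value),
                      event_lab = ifelse(.data$event == 1,
                                         "Event of interest", "Competing event"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$estimate,
                                   colour = .data$varied,
                                   fill = .data$varied, group = .data$varied)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$measure),
                        ggplot2::vars(.data$event_lab)) +
    ggplot2::labs(
      x = expression(rho ~ "(Corr(U, Z))"),
      y = "Bias (log hazard ratio scale)",
      colour = unique(df$varied_param), fill = unique(df$varied_param),
      title = sprintf("Scenario %s: %s",
                      paste(unique(df$scenario), collapse = ","),
                      paste(unique(df$name), collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scenario_result
#' @export
plot_bias <- function(object, ...) autoplot.scenario_result(object, ...)

#' Plot a single cell's bias table
#'
#' Point estimates with 95% error bars for the three measures by event.
#'
#' @param object A `"bias_table"` from [compute_bias_measures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_table
#' @export
autoplot.bias_table <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      event_lab = ifelse(.data$event == 1,
                                         "Event of interest", "Competing event"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$event_lab)) +
    ggplot2::labs(x = NULL, y = "Bias (log hazard ratio scale)") +
    ggplot2::theme_minimal()
}
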