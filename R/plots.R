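# ggplot2 visualisations for result objects.

#' Tornado plot of one-way sensitivity results
#'
#' Horizontal ICER ranges per perturbed parameter, ordered by influence,
#' with the base-case ICER as a reference line.
#'
#' @param object A `cea_dsa` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_dsa <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$path <- factor(df$path, levels = rev(df$path))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$path)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$path),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (EUR per QALY)", y = NULL,
                  title = "One-way sensitivity analysis",
                  subtitle = "dashed line: base-case ICER") +
    ggplot2::theme_minimal()
}

#' Price sweep plot
#'
#' ICER against the intervention drug price multiplier; dominant points
#' (cost-saving with a QALY gain) are highlighted.
#'
#' @param object A `cea_price_sweep` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_price_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$multiplier, y = .data$icer)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dominance), size = 2.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Intervention drug price multiplier",
                  y = "ICER (EUR per QALY)",
                  colour = NULL,
                  title = "Price sensitivity of the ICER") +
    ggplot2::theme_minimal()
}

#' Cost-breakdown plot for an arm
#'
#' Discounted mean lifetime cost per patient by component.
#'
#' @param object A `cea_arm` result (full mode).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_arm <- function(object, ...) {
  comp <- c("cost_art", "cost_care", "cost_tests", "cost_oi",
            "cost_death", "cost_switch")
  df <- dplyr::filter(object$summary, .data$outcome %in% comp)
  df$outcome <- factor(df$outcome, levels = comp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Discounted mean cost per patient (EUR)",
                  title = paste0("Lifetime cost breakdown, ",
                                 toupper(object$arm), " arm")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
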