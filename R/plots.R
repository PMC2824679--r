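#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   labs scale_colour_manual theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot yield and burden learning curves
#'
#' Draws the classic screening learning-curve figure: yield and burden as a
#' function of the number of labels provided, with thin per-run lines and a
#' thick mean line. Every stretch where yield sits at 1 while burden is
#' below 1 is workload saved relative to manual screening.
#'
#' @param object A `pal_curves` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pal_curves
#' @export
autoplot.pal_curves <- function(object, ...) {
  long_runs <- tidyr::pivot_longer(object$points, c("yield", "burden"),
                                   names_to = "metric", values_to = "value")
  long_mean <- tidyr::pivot_longer(object$mean, c("yield", "burden"),
                                   names_to = "metric", values_to = "value")
  ggplot(long_runs, aes(x = .data$labels, y = .data$value,
                        colour = .data$metric)) +
    geom_line(aes(group = interaction(.data$run, .data$metric)),
              linewidth = 0.25, alpha = 0.4) +
    geom_line(data = long_mean, linewidth = 1.1) +
    scale_colour_manual(values = c(yield = "#2166ac", burden = "#b2182b")) +
    labs(x = "labels provided", y = NULL, colour = NULL,
         title = paste0("Screening learning curves (", object$strategy, ")"),
         subtitle = "thin lines: individual runs; thick lines: mean over runs") +
    theme_minimal()
}

#' @rdname autoplot.pal_curves
#' @param curves A `pal_curves` object.
#' @export
plot_learning_curves <- function(curves, ...) autoplot(curves, ...)

#' Plot the diversity trajectory of a PAL run
#'
#' Shows the mean pairwise angle between labeled relevant citations at each
#' exploration batch, with the exploration-to-exploitation switch marked.
#'
#' @param object A `pal_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pal_run
#' @export
autoplot.pal_run <- function(object, ...) {
  df <- tibble(batch = seq_along(object$diversity_history),
               diversity = object$diversity_history)
  p <- ggplot(df, aes(x = .data$batch, y = .data$diversity)) +
    geom_line(colour = "#2166ac") + geom_point(size = 0.8) +
    labs(x = "batch", y = "mean pairwise angle (degrees)",
         title = "Diversity of labeled relevant citations") +
    theme_minimal()
  if (!is.na(object$switch_batch)) {
    p <- p + geom_vline(xintercept = object$switch_batch, linetype = "dashed")
  }
  p
}
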