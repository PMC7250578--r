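#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs facet_wrap
#' @export
ggplot2::autoplot

#' Plot a deterministic trajectory as per-type fractions over time
#'
#' @param object A `centro_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centro_trajectory <- function(object, ...) {
  fr <- population_fractions(object)
  long <- tidyr::pivot_longer(fr, dplyr::starts_with("f_"),
                              names_to = "type", names_prefix = "f_",
                              values_to = "fraction")
  ggplot(long, aes(x = .data$time, y = .data$fraction,
                   colour = .data$type)) +
    geom_line() +
    labs(x = "time (days)", y = "fraction of population", colour = "class")
}

#' Plot stochastic replicate counts with the class composition over time
#'
#' @param object A `centro_counts` tibble from [simulate_lineages()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centro_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::any_of(c("C2", "C4", "SC", "C6")),
                              names_to = "type", values_to = "count")
  ggplot(long, aes(x = .data$time, y = .data$count, colour = .data$type,
                   group = interaction(.data$replicate, .data$type))) +
    geom_line(alpha = 0.6) +
    labs(x = "time (days)", y = "cells", colour = "class")
}

#' Plot a sensitivity scan
#'
#' @param object A `centro_sensitivity` tibble from [sensitivity_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centro_sensitivity <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$metric)) +
    geom_line() + geom_point() +
    labs(x = object$parameter[1],
         y = paste0("extra-centrosome fraction (",
                    attr(object, "metric_kind"), ")"))
}

#' Plot observed vs fitted extra-centrosome time course
#'
#' @param object A `centro_fit` from [fit_time_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centro_fit <- function(object, ...) {
  ggplot(object$residuals, aes(x = .data$day)) +
    geom_point(aes(y = .data$observed)) +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "day", y = "fraction with extra centrosomes",
         title = sprintf("Model %s fit (loss %.3g)", object$model,
                         object$loss))
}

#' Plot per-day chromosome-count histograms
#'
#' @param histograms A tibble from [simulate_karyotype_evolution()].
#' @return A ggplot faceted by day.
#' @export
plot_karyotype_histograms <- function(histograms) {
  ggplot(histograms, aes(x = .data$chromosome_count, y = .data$n_cells)) +
    geom_col() +
    facet_wrap(~day, labeller = ggplot2::label_both) +
    labs(x = "chromosomes per cell", y = "cells")
}
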