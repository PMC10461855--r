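## ggplot2 quick-look methods for the result containers.

#' Plot a trajectory
#'
#' One facet per species (or the selected species), concentration
#' against time.
#'
#' @param object An `hm_trajectory`.
#' @param species Species subset (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hm_trajectory <- function(object, species = NULL, ...) {
  cols <- setdiff(names(object), "time")
  if (!is.null(species)) cols <- intersect(cols, species)
  long <- tidyr::pivot_longer(as.data.frame(object)[, c("time", cols)],
                              -"time", names_to = "species",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (au)", y = "concentration (au)")
}

#' Plot a per-cycle frequency series
#'
#' @param object An `hm_cycles` table.
#' @param ... Unused.
#' @return A ggplot of frequency against cycle peak time.
#' @export
autoplot.hm_cycles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_peak, .data$frequency)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (au)", y = "frequency (1/au)")
}

#' Plot a background/step sweep
#'
#' The classic presentation: response statistic against
#' `phase2 + background`, one line per background.  Parallel lines
#' indicate background compensation.
#'
#' @param object An `hm_sweep`.
#' @param statistic Column to plot (default: the sweep's statistic).
#' @param log10 Use log10 axes (the log presentation can make an
#'   uncompensated family look deceptively parallel; the compensation
#'   verdict is always computed on linear values).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hm_sweep <- function(object, statistic = NULL, log10 = FALSE,
                              ...) {
  if (is.null(statistic)) {
    statistic <- attr(object, "statistic") %||% "max_frequency"
    if (statistic == "both") statistic <- "max_frequency"
  }
  p <- ggplot2::ggplot(
    dplyr::filter(object, is.finite(.data[[statistic]])),
    ggplot2::aes(.data$abscissa, .data[[statistic]],
                 colour = factor(.data$background))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "phase-2 value + background", colour = "background")
  if (log10) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot an intensity-response family
#'
#' @param family Tibble from [intensity_response_family()].
#' @param log_x,log_y Logarithmic axes.
#' @return A ggplot, with a dashed guide at I = 1.
#' @export
plot_intensity_response <- function(family, log_x = TRUE, log_y = FALSE) {
  p <- ggplot2::ggplot(family,
                       ggplot2::aes(.data$I, .data$V,
                                    colour = factor(.data$sigma))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "intensity I", y = "response V",
                  colour = expression(sigma))
  if (log_x) p <- p + ggplot2::scale_x_log10()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
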