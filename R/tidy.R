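## broom-style tidiers for the report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a background-compensation report
#'
#' @param x An `hm_compensation` from [check_background_compensation()].
#' @param ... Unused.
#' @return The per-step spread tibble (`phase2`, `n_backgrounds`,
#'   `mean`, `spread`).
#' @export
tidy.hm_compensation <- function(x, ...) x$per_step

#' One-row summary of a background-compensation report
#'
#' @param x An `hm_compensation`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `max_spread`, `tolerance`, `pass`.
#' @export
glance.hm_compensation <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, max_spread = x$max_spread,
                 tolerance = x$tolerance, pass = x$pass)
}

#' Tidy a cycle table
#'
#' @param x An `hm_cycles`.
#' @param ... Unused.
#' @return The cycle tibble, untouched (already tidy).
#' @export
tidy.hm_cycles <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "hm_cycles")
  out
}

#' One-row summary of a cycle table
#'
#' @param x An `hm_cycles`.
#' @param ... Unused.
#' @return Tibble with `n_cycles`, `mean_period`, `mean_frequency`,
#'   `min_period`, `max_frequency`.
#' @export
glance.hm_cycles <- function(x, ...) {
  tibble::tibble(
    n_cycles = nrow(x),
    mean_period = if (nrow(x)) mean(x$period) else NA_real_,
    mean_frequency = if (nrow(x)) mean(x$frequency) else NA_real_,
    min_period = if (nrow(x)) min(x$period) else NA_real_,
    max_frequency = if (nrow(x)) max(x$frequency) else NA_real_
  )
}
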