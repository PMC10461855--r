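## Synthetic signals and sweep tables with known ground truth, for
## testing the analysis operators independently of the ODE engine.

#' Specify a synthetic test signal
#'
#' @param kind `"constant"`, `"ramp"`, `"sinusoid"`, `"damped"`
#'   (exponentially decaying sinusoid) or `"step_relaxation"` (constant
#'   baseline, then at `t_step` an excursion of size `amplitude` that
#'   relaxes back exponentially).
#' @param amplitude Waveform amplitude (for `step_relaxation`: the
#'   programmed excursion, i.e. the ground-truth delta_A).
#' @param period Oscillation period (oscillatory kinds).
#' @param decay Exponential decay rate (damped / step_relaxation).
#' @param offset Constant offset (the constant's value for
#'   `"constant"`, the baseline otherwise).
#' @param slope Ramp slope (`"ramp"`).
#' @param t_step Excursion time for `"step_relaxation"`.
#' @param dt Sampling interval; must be < period/20 for oscillatory
#'   kinds.
#' @param horizon Signal length (time units).
#' @param noise_sd Additive Gaussian noise amplitude (default 0: the
#'   reference pipeline is noise-free; nonzero values exist to
#'   stress-test the detectors).
#' @param seed RNG seed fixing the noise stream.
#' @param species Column name of the signal (default `"A"`).
#' @return An object of class `hm_signal_spec`.
#' @export
signal_spec <- function(kind = c("constant", "ramp", "sinusoid", "damped",
                                 "step_relaxation"),
                        amplitude = 1, period = 5, decay = 0.01,
                        offset = 0, slope = 1, t_step = NULL,
                        dt = 0.01, horizon = 100, noise_sd = 0,
                        seed = 1L, species = "A") {
  kind <- match.arg(kind)
  if (kind %in% c("sinusoid", "damped") && dt >= period / 20) {
    stop("sampling interval must be < period/20 for oscillatory signals",
         call. = FALSE)
  }
  if (horizon <= 0 || dt <= 0) stop("invalid horizon or dt", call. = FALSE)
  if (is.null(t_step)) t_step <- horizon / 2
  structure(list(kind = kind, amplitude = amplitude, period = period,
                 decay = decay, offset = offset, slope = slope,
                 t_step = t_step, dt = dt, horizon = horizon,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 species = species),
            class = "hm_signal_spec")
}

#' Generate a synthetic trajectory from a signal spec
#'
#' The returned single-species trajectory carries its programmed ground
#' truth (`true_period`, `true_delta_A`, `true_mean`) as the
#' `ground_truth` attribute; the same seed yields bit-identical output.
#'
#' @param spec An [signal_spec()].
#' @return An `hm_trajectory` tibble (`time` + one species column).
#' @export
make_signal <- function(spec) {
  stopifnot(inherits(spec, "hm_signal_spec"))
  tt <- seq(0, spec$horizon, by = spec$dt)
  x <- switch(spec$kind,
    constant = rep(spec$offset, length(tt)),
    ramp = spec$offset + spec$slope * tt,
    sinusoid = spec$offset + spec$amplitude * sin(2 * pi * tt / spec$period),
    damped = spec$offset + spec$amplitude * exp(-spec$decay * tt) *
      sin(2 * pi * tt / spec$period),
    step_relaxation = spec$offset + ifelse(
      tt < spec$t_step, 0,
      spec$amplitude * exp(-spec$decay * (tt - spec$t_step)))
  )
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    x <- x + stats::rnorm(length(x), sd = spec$noise_sd)
  }
  truth <- list(
    true_period = if (spec$kind %in% c("sinusoid", "damped")) spec$period
                  else NA_real_,
    true_delta_A = if (spec$kind == "step_relaxation") abs(spec$amplitude)
                   else NA_real_,
    true_mean = switch(spec$kind,
      constant = spec$offset,
      ramp = spec$offset + spec$slope * spec$horizon / 2,
      sinusoid = spec$offset,
      NA_real_)
  )
  out <- tibble::tibble(time = tt)
  out[[spec$species]] <- x
  class(out) <- c("hm_trajectory", class(out))
  attr(out, "model") <- "synthetic"
  attr(out, "ground_truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' Synthetic sweep table with programmed compensation behaviour
#'
#' Builds an `hm_sweep`-shaped table whose response statistic is either
#' background-invariant (`compensated = TRUE`, spread 0) or degrades
#' monotonically with the background by a programmed relative `spread`,
#' for testing [check_background_compensation()] and
#' [background_monotonicity()] in both directions.
#'
#' @param compensated Logical.
#' @param n_backgrounds,n_steps Grid size (both >= 2).
#' @param spread Total relative decrease of the statistic from the first
#'   to the last background (uncompensated case).
#' @param statistic Column to fill (`"max_frequency"` or `"delta_A"`).
#' @return An `hm_sweep` tibble.
#' @export
make_sweep_fixture <- function(compensated = TRUE, n_backgrounds = 4,
                               n_steps = 5, spread = 0.1,
                               statistic = c("max_frequency", "delta_A")) {
  stopifnot(n_backgrounds >= 2, n_steps >= 2)
  statistic <- match.arg(statistic)
  bgs <- 2^(seq_len(n_backgrounds) - 1) - 1
  steps <- seq(2, length.out = n_steps)
  base <- 0.1 * steps            # rising line in the step magnitude
  fac <- if (compensated) rep(1, n_backgrounds) else
    seq(1, 1 - spread, length.out = n_backgrounds)
  out <- tidyr::expand_grid(background = bgs, phase2 = steps) |>
    dplyr::mutate(
      abscissa = .data$phase2 + .data$background,
      value = base[match(.data$phase2, steps)] *
        fac[match(.data$background, bgs)],
      error = NA_character_)
  out[[statistic]] <- out$value
  out$value <- NULL
  class(out) <- c("hm_sweep", class(out))
  attr(out, "statistic") <- statistic
  out
}
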