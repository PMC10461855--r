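## Orchestration of the computational experiments: step-at-background
## sweeps, background-compensation verdicts, and the bundled reference
## scenarios.

#' Specify a background/step sweep
#'
#' A sweep runs one integration per (background, phase-2 step value)
#' cell: phase 1 at the perturbation parameter's `phase1` value and the
#' given background, then the step, then analysis of the post-step
#' response (maximum per-cycle frequency for oscillatory models,
#' response amplitude `delta_A` for non-oscillatory ones, or both).
#'
#' Pre-step states are resolved per background, in order of precedence:
#' an entry in `init_states`; for non-oscillatory models the analytic
#' [steady_state()] constructor at a common I2 reference; otherwise
#' `default_state` followed by a phase-1 burn-in of `t_burn` au
#' ([pre_equilibrate()]-style).  For oscillatory models the maximum
#' post-step frequency depends on the oscillation phase at which the
#' step lands (a measurement artifact, not a property of the network);
#' setting `phase_average = n > 1` applies the step at `n` offsets
#' spanning one pre-step cycle and averages the statistic, which
#' marginalises the phase out of the comparison.
#'
#' @param model An [hm_model()].
#' @param backgrounds Background parameter values (>= 1).
#' @param steps Phase-2 values of the perturbation parameter (>= 1).
#' @param phase1 Phase-1 value of the perturbation parameter.
#' @param t_step Step time (au).
#' @param t_post Post-step horizon (au).
#' @param init_states Optional named list (by background value) of
#'   initial states.
#' @param default_state Fallback initial state for backgrounds without
#'   an entry in `init_states`.
#' @param t_burn Extra phase-1 burn-in applied when falling back to
#'   `default_state` (au).
#' @param I2_ref Common I2 family coordinate for the analytic
#'   constructors of the non-oscillatory models (see [steady_state()]).
#' @param statistic `"max_frequency"`, `"delta_A"`, or `"both"`.
#' @param phase_average Number of step-phase offsets to average over
#'   (oscillatory models; 1 = plain single run at `t_step`).
#' @param dt Output grid spacing override.
#' @return An object of class `hm_sweep_spec`.
#' @export
sweep_spec <- function(model, backgrounds, steps, phase1 = 1,
                       t_step = 100, t_post = 60, init_states = NULL,
                       default_state = NULL, t_burn = 0, I2_ref = NULL,
                       statistic = c("max_frequency", "delta_A", "both"),
                       phase_average = 1, dt = NULL) {
  stopifnot(inherits(model, "hm_model"),
            length(backgrounds) >= 1, length(steps) >= 1,
            t_step > 0, t_post > 0)
  statistic <- match.arg(statistic)
  if (statistic == "max_frequency" && !model$oscillatory) {
    stop("max_frequency requires an oscillatory model", call. = FALSE)
  }
  structure(
    list(model = model, backgrounds = backgrounds, steps = steps,
         phase1 = phase1, t_step = t_step, t_post = t_post,
         init_states = init_states, default_state = default_state,
         t_burn = t_burn, I2_ref = I2_ref, statistic = statistic,
         phase_average = phase_average, dt = dt),
    class = "hm_sweep_spec")
}

.resolve_sweep_state <- function(spec, bg) {
  model <- spec$model
  key <- as.character(bg)
  if (!is.null(spec$init_states) && key %in% names(spec$init_states)) {
    return(list(state = spec$init_states[[key]], burn = 0))
  }
  if (!model$oscillatory) {
    m_bg <- hm_model(model$name, params = stats::setNames(
      c(spec$phase1, bg), c(model$pert_param, model$bg_param)))
    return(list(state = steady_state(m_bg, I2 = spec$I2_ref), burn = 0))
  }
  if (is.null(spec$default_state)) {
    stop("no initial state for background ", bg,
         " and no default_state given", call. = FALSE)
  }
  list(state = spec$default_state, burn = spec$t_burn)
}

#' Run a background/step sweep
#'
#' Executes one integration (or `phase_average` integrations) per
#' (background, step) cell of the spec and collects the response
#' statistics.  Cell failures are recorded in the `error` column rather
#' than aborting the sweep.
#'
#' @param spec An [sweep_spec()].
#' @return A tibble of class `hm_sweep` with one row per cell:
#'   `background`, `phase2`, `abscissa` (= phase2 + background),
#'   `max_frequency` and/or `delta_A`, `error`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "hm_sweep_spec"))
  model <- spec$model
  rows <- list()
  for (bg in spec$backgrounds) {
    res <- .resolve_sweep_state(spec, bg)
    pp_phase1 <- stats::setNames(c(spec$phase1, bg),
                                 c(model$pert_param, model$bg_param))
    ## shared phase-1 run for this background
    pre <- tryCatch({
      t_pre <- spec$t_step + res$burn
      tr1 <- simulate_model(model, res$state, t_end = t_pre,
                            params = pp_phase1, dt = spec$dt)
      tr1
    }, error = function(e) e)
    for (st in spec$steps) {
      row <- tibble::tibble(background = bg, phase2 = st,
                            abscissa = st + bg,
                            max_frequency = NA_real_,
                            delta_A = NA_real_, error = NA_character_)
      if (inherits(pre, "error")) {
        row$error <- conditionMessage(pre)
        rows[[length(rows) + 1]] <- row
        next
      }
      out <- tryCatch(
        .run_sweep_cell(spec, model, pre, bg, st),
        error = function(e) e)
      if (inherits(out, "error")) {
        row$error <- conditionMessage(out)
      } else {
        row$max_frequency <- out$max_frequency
        row$delta_A <- out$delta_A
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hm_sweep", class(out))
  attr(out, "model") <- model$name
  attr(out, "statistic") <- spec$statistic
  attr(out, "spec") <- spec
  out
}

.run_sweep_cell <- function(spec, model, pre, bg, st) {
  want_f <- spec$statistic %in% c("max_frequency", "both") &&
    model$oscillatory
  want_d <- spec$statistic %in% c("delta_A", "both")
  pp2 <- stats::setNames(c(st, bg), c(model$pert_param, model$bg_param))

  offsets <- 0
  if (want_f && spec$phase_average > 1) {
    cyc <- detect_cycles(pre, species = "A")
    if (nrow(cyc) >= 1) {
      per <- cyc$period[nrow(cyc)]
      offsets <- seq(0, per, length.out = spec$phase_average + 1)
      offsets <- offsets[-length(offsets)]
    }
  }

  t0 <- pre$time[nrow(pre)]
  fs <- numeric(0); ds <- numeric(0)
  for (off in offsets) {
    if (off > 0) {
      y <- .traj_last_state(pre, model$species)
      ext <- simulate_model(model, y, t_end = t0 + off, t_start = t0,
                            params = stats::setNames(
                              c(spec$phase1, bg),
                              c(model$pert_param, model$bg_param)),
                            dt = spec$dt)
      y <- .traj_last_state(ext, model$species)
      tstart <- t0 + off
    } else {
      y <- .traj_last_state(pre, model$species)
      tstart <- t0
    }
    tr2 <- simulate_model(model, y, t_end = tstart + spec$t_post,
                          t_start = tstart, params = pp2, dt = spec$dt)
    if (want_f) {
      cyc2 <- detect_cycles(tr2, species = "A")
      fs <- c(fs, max_post_step_frequency(cyc2, tstart))
    }
    if (want_d) {
      ref <- pre[[ "A" ]][nrow(pre)]
      ds <- c(ds, suppressWarnings(
        delta_A(tr2, t_step = tstart + 1e-9, reference = ref)))
    }
  }
  ## median over phase offsets: robust to the cycle-delimitation
  ## artifact when the step lands immediately before a peak
  list(max_frequency = if (want_f) stats::median(fs) else NA_real_,
       delta_A = if (want_d) stats::median(ds) else NA_real_)
}

#' Background-compensation verdict for a sweep table
#'
#' For each step value, computes the relative spread
#' `(max - min)/mean` of the response statistic across backgrounds.
#' The sweep passes when every spread is below `tolerance`.  With a
#' deterministic ODE pipeline, disagreement beyond integration error
#' indicates genuine absence of background compensation.
#'
#' @param table An `hm_sweep` (or any tibble with `background`,
#'   `phase2` and a statistic column).
#' @param tolerance Relative spread tolerance (default 1%).
#' @param statistic Statistic column; default: `max_frequency` when
#'   present with data, else `delta_A`.
#' @return An object of class `hm_compensation`: list with `per_step`
#'   (tibble of spreads), `max_spread`, `tolerance`, `pass`.
#' @export
check_background_compensation <- function(table, tolerance = 0.01,
                                          statistic = NULL) {
  if (is.null(statistic)) {
    statistic <- if ("max_frequency" %in% names(table) &&
                     any(is.finite(table$max_frequency))) {
      "max_frequency"
    } else "delta_A"
  }
  tab <- table[is.finite(table[[statistic]]), , drop = FALSE]
  if (nrow(tab) == 0) stop("no finite values of ", statistic, call. = FALSE)
  n_missing <- nrow(table) - nrow(tab)
  if (n_missing > 0) {
    message(n_missing, " cell(s) missing; spreads computed on the ",
            "available cells")
  }
  per_step <- tab |>
    dplyr::group_by(.data$phase2) |>
    dplyr::summarise(
      n_backgrounds = dplyr::n(),
      mean = mean(.data[[statistic]]),
      spread = (max(.data[[statistic]]) - min(.data[[statistic]])) /
        mean(.data[[statistic]]),
      .groups = "drop")
  if (any(per_step$n_backgrounds < 2)) {
    warning("some steps have fewer than 2 backgrounds; their spread is 0 ",
            "by construction", call. = FALSE)
  }
  out <- list(per_step = per_step,
              statistic = statistic,
              max_spread = max(per_step$spread),
              tolerance = tolerance,
              pass = all(per_step$spread < tolerance))
  class(out) <- "hm_compensation"
  out
}

#' @export
print.hm_compensation <- function(x, ...) {
  cat("<background compensation check> statistic:", x$statistic, "\n")
  cat(sprintf("  max relative spread: %.4g (tolerance %.4g) -> %s\n",
              x$max_spread, x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Is the response statistic monotone in the background?
#'
#' Returns, per step value, whether the statistic strictly decreases as
#' the background increases — the signature of an uncompensated
#' (incoherent-feedback) network.
#'
#' @inheritParams check_background_compensation
#' @return A tibble (`phase2`, `strictly_decreasing`).
#' @export
background_monotonicity <- function(table, statistic = "max_frequency") {
  table |>
    dplyr::filter(is.finite(.data[[statistic]])) |>
    dplyr::group_by(.data$phase2) |>
    dplyr::arrange(.data$background, .by_group = TRUE) |>
    dplyr::summarise(
      strictly_decreasing = all(diff(.data[[statistic]]) < 0),
      .groups = "drop")
}

#' Run a bundled reference scenario
#'
#' Reproduces one of the bundled protocols (see [figure_setup()]) at the
#' data level: trajectory scenarios return the trajectory plus summary
#' statistics; sweep scenarios return the sweep table plus the
#' compensation report.  Optionally writes tidy CSV outputs.
#'
#' @param id Scenario id (`"fig5"`, `"fig6"`, `"fig7"`, `"fig9"`,
#'   `"fig10"`, `"fig11"`, `"fig14"`, `"fig16"`, `"fig17"`).
#' @param dir Optional output directory for CSV exports.
#' @param scale_down Optional list with `backgrounds` and/or `steps` to
#'   subset the published grids (sweep scenarios), for quicker runs.
#' @param t_end Horizon override for trajectory scenarios.
#' @param phase_average Phase offsets for oscillatory sweeps (see
#'   [sweep_spec()]).
#' @return A list of results; class `hm_figure`.
#' @export
reproduce_figure <- function(id, dir = NULL, scale_down = NULL,
                             t_end = NULL, phase_average = 1) {
  fs <- figure_setup(id)
  model <- fs$model
  out <- switch(id,
    fig5 = ,
    fig6 = {
      te <- t_end %||% 2000
      sch <- step_schedule(model$pert_param, fs$t_step,
                           fs$step[1], fs$step[2])
      tr <- simulate_model(model, fs$state0, schedules = sch, t_end = te)
      list(trajectory = tr,
           A_average = asymptotic_average(tr, "A"),
           E_average = asymptotic_average(tr, "E"),
           cycles = detect_cycles(tr, "A"),
           setpoints = suppressWarnings(setpoints(model)))
    },
    fig16 = {
      te <- t_end %||% 1000
      sch <- step_schedule(model$pert_param, fs$t_step,
                           fs$step[1], fs$step[2])
      tr <- simulate_model(model, fs$state0, schedules = sch, t_end = te)
      list(trajectory = tr,
           cycles = detect_cycles(tr, "A"),
           setpoints = suppressWarnings(setpoints(model)))
    },
    fig9 = {
      te <- t_end %||% 300
      trs <- lapply(names(fs$states), function(bg) {
        pp <- stats::setNames(as.numeric(bg), model$bg_param)
        sch <- step_schedule(model$pert_param, fs$t_step,
                             fs$step[1], fs$step[2])
        simulate_model(model, fs$states[[bg]], schedules = sch,
                       t_end = te, params = pp)
      })
      names(trs) <- names(fs$states)
      maxf <- vapply(trs, function(tr) {
        max_post_step_frequency(detect_cycles(tr, "A"), fs$t_step)
      }, numeric(1))
      list(trajectories = trs, max_frequency = maxf,
           setpoints = setpoints(model))
    },
    fig7 = ,
    fig10 = ,
    fig17 = {
      bgs <- scale_down$backgrounds %||% fs$backgrounds
      sts <- scale_down$steps %||% fs$steps
      spec <- sweep_spec(model, backgrounds = bgs, steps = sts,
                         phase1 = 1, t_step = fs$t_step,
                         t_post = if (id == "fig17") 60 else 60,
                         init_states = fs$states,
                         default_state = fs$default_state,
                         t_burn = if (id == "fig7") 900 else 0,
                         statistic = "max_frequency",
                         phase_average = phase_average)
      tab <- run_sweep(spec)
      list(sweep = tab,
           compensation = check_background_compensation(tab),
           monotonicity = background_monotonicity(tab))
    },
    fig11 = ,
    fig14 = {
      bgs <- scale_down$backgrounds %||% fs$backgrounds
      sts <- scale_down$steps %||% fs$steps
      spec <- sweep_spec(model, backgrounds = bgs, steps = sts,
                         phase1 = 1, t_step = fs$t_step,
                         t_post = if (id == "fig11") 2500 else 500,
                         I2_ref = fs$I2_ref,
                         statistic = "delta_A")
      tab <- run_sweep(spec)
      list(sweep = tab,
           compensation = check_background_compensation(tab))
    },
    stop("unknown figure id: ", id, call. = FALSE)
  )
  class(out) <- c("hm_figure", class(out))
  attr(out, "id") <- id
  if (!is.null(dir)) .export_figure(out, id, dir)
  out
}

.export_figure <- function(out, id, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out)) {
    obj <- out[[nm]]
    if (inherits(obj, "tbl_df")) {
      utils::write.csv(obj, file.path(dir, paste0(id, "_", nm, ".csv")),
                       row.names = FALSE)
    } else if (nm == "trajectories") {
      for (bg in names(obj)) {
        utils::write.csv(obj[[bg]],
                         file.path(dir,
                                   paste0(id, "_trajectory_bg", bg, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(dir)
}
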