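## Simulation engine: stiff integration of a model under piecewise-
## constant parameter schedules, segmented at every breakpoint with a
## solver restart (stiff integrators interpolate poorly across jumps).

#' Piecewise-constant parameter schedule
#'
#' @param parameter Name of the scheduled parameter.
#' @param times Breakpoint times; the first must equal the simulation
#'   start (the value before the first breakpoint is the first value).
#' @param values Parameter value from each breakpoint onward (same
#'   length as `times`, all >= 0).
#' @return An object of class `hm_schedule`.
#' @seealso [step_schedule()], [constant_schedule()]
#' @export
schedule <- function(parameter, times, values) {
  stopifnot(is.character(parameter), length(parameter) == 1,
            length(times) == length(values), length(times) >= 1)
  if (any(diff(times) <= 0)) {
    stop("schedule breakpoints must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("schedule values must be nonnegative", call. = FALSE)
  }
  structure(list(parameter = parameter, times = as.numeric(times),
                 values = as.numeric(values)),
            class = "hm_schedule")
}

#' Two-phase step schedule
#'
#' The standard perturbation protocol: `from` (phase 1) before `t_step`,
#' `to` (phase 2) afterwards.
#'
#' @param parameter Name of the perturbed parameter.
#' @param t_step Step time.
#' @param from,to Phase-1 and phase-2 values.
#' @param t_start Simulation start time (default 0).
#' @return An `hm_schedule`.
#' @export
step_schedule <- function(parameter, t_step, from, to, t_start = 0) {
  schedule(parameter, c(t_start, t_step), c(from, to))
}

#' Constant background schedule
#'
#' @param parameter Name of the background parameter.
#' @param value Constant value.
#' @param t_start Simulation start time (default 0).
#' @return An `hm_schedule`.
#' @export
constant_schedule <- function(parameter, value, t_start = 0) {
  schedule(parameter, t_start, value)
}

#' @export
print.hm_schedule <- function(x, ...) {
  cat("<hm_schedule> ", x$parameter, ": ",
      paste(sprintf("%g@t>=%g", x$values, x$times), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.schedule_value <- function(sch, t) {
  sch$values[findInterval(t, sch$times)]
}

#' Integrate a homeostat model
#'
#' Integrates the model's ODEs with a stiff-capable solver (lsoda),
#' restarting the integrator at every schedule breakpoint so that the
#' piecewise-constant parameter jumps are handled exactly.  Within each
#' segment the parameters are constant and the compiled right-hand side
#' is used.
#'
#' Small negative solver excursions (down to `-neg_tol`) are clipped to
#' zero on output and counted in the diagnostics; larger negativity
#' aborts with an error, because the states are concentrations.
#'
#' @param model An [hm_model()].
#' @param state0 Named initial state covering every species of the
#'   model.
#' @param schedules A single `hm_schedule` or a list of them; each must
#'   reference a parameter in the model's schema.
#' @param t_end End time (au).
#' @param t_start Start time (default 0).
#' @param dt Output grid spacing; defaults to 0.01 for oscillatory
#'   models and 0.1 for non-oscillatory ones.  Output values are
#'   solver-interpolated, never naive fixed-step results.
#' @param params Optional parameter override applied before scheduling.
#' @param rtol,atol Relative/absolute solver tolerances.  The defaults
#'   (1e-8, 1e-10) are needed because Michaelis constants of order 1e-6
#'   make the saturated removals stiff near zero concentrations; looser
#'   tolerances visibly distort oscillation periods.
#' @param neg_tol Clip-to-zero threshold for negative excursions.
#' @param restart_at_breakpoints If `FALSE`, integrate straight through
#'   breakpoints using a time-dependent R-level right-hand side (mainly
#'   for testing the segmentation logic).
#' @param compiled Use the compiled right-hand side (default) or the
#'   R reference implementation.
#' @return A tibble of class `hm_trajectory`: a `time` column plus one
#'   column per species, with attributes `model`, `params` (per-segment
#'   snapshots), `schedules`, `solver` settings and `diagnostics`.
#' @examples
#' m <- hm_model("m2_firstorder")
#' tr <- simulate_model(m, state0 = steady_state(m), t_end = 50)
#' tail(tr)
#' @export
simulate_model <- function(model, state0, schedules = NULL, t_end,
                     t_start = 0, dt = NULL, params = NULL,
                     rtol = 1e-8, atol = 1e-10, neg_tol = 1e-6,
                     restart_at_breakpoints = TRUE, compiled = TRUE) {
  stopifnot(inherits(model, "hm_model"), t_end > t_start)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  p <- model$params
  if (!is.null(params)) {
    params <- unlist(params)
    unknown <- setdiff(names(params), names(p))
    if (length(unknown) > 0) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(params)] <- params
  }
  if (is.null(dt)) dt <- if (model$oscillatory) 0.01 else 0.1
  if (inherits(schedules, "hm_schedule")) schedules <- list(schedules)
  schedules <- schedules %||% list()
  for (sch in schedules) {
    if (!sch$parameter %in% names(p)) {
      stop("schedule references unknown parameter: ", sch$parameter,
           call. = FALSE)
    }
  }
  state0 <- .check_state(state0, model$species)

  breaks <- sort(unique(c(
    t_start,
    unlist(lapply(schedules, function(s) s$times)))))
  breaks <- breaks[breaks >= t_start & breaks < t_end]
  seg_bounds <- c(breaks, t_end)

  param_at <- function(t) {
    pp <- p
    for (sch in schedules) pp[sch$parameter] <- .schedule_value(sch, t)
    pp
  }

  if (!restart_at_breakpoints) {
    ## straight-through integration with a time-dependent RHS
    rhs_t <- function(t, y, parms) {
      list(unname(model$rhs(stats::setNames(y, model$species), param_at(t))))
    }
    times <- seq(t_start, t_end, by = dt)
    out <- deSolve::lsoda(state0, times, rhs_t, parms = NULL,
                          rtol = rtol, atol = atol)
    segs <- list(out)
    param_snaps <- list(param_at(t_start))
  } else {
    segs <- vector("list", length(seg_bounds) - 1)
    param_snaps <- vector("list", length(seg_bounds) - 1)
    y <- state0
    for (i in seq_along(segs)) {
      a <- seg_bounds[i]; b <- seg_bounds[i + 1]
      pp <- param_at(a)
      param_snaps[[i]] <- pp
      times <- seq(a, b, by = dt)
      if (times[length(times)] < b) times <- c(times, b)
      out <- .integrate_segment(model, y, times, pp, rtol, atol, compiled)
      y <- stats::setNames(as.numeric(out[nrow(out), -1]), model$species)
      segs[[i]] <- if (i > 1) out[-1, , drop = FALSE] else out
    }
  }

  mat <- do.call(rbind, segs)
  colnames(mat) <- c("time", model$species)
  ## negativity policy
  vals <- mat[, -1, drop = FALSE]
  neg_min <- min(vals)
  if (neg_min < -neg_tol) {
    stop(sprintf(paste0("integration produced a negative concentration ",
                        "(%.3g) beyond the clipping tolerance %.1g"),
                 neg_min, neg_tol), call. = FALSE)
  }
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) {
    vals[vals < 0] <- 0
    mat[, -1] <- vals
  }

  tr <- tibble::as_tibble(as.data.frame(mat))
  class(tr) <- c("hm_trajectory", class(tr))
  attr(tr, "model") <- model$name
  attr(tr, "params") <- param_snaps
  attr(tr, "schedules") <- schedules
  attr(tr, "solver") <- list(method = "lsoda", rtol = rtol, atol = atol,
                             dt = dt, segmented = restart_at_breakpoints)
  attr(tr, "diagnostics") <- list(n_clipped = n_clipped,
                                  min_value = neg_min,
                                  n_segments = length(segs))
  tr
}

.integrate_segment <- function(model, y, times, pp, rtol, atol, compiled) {
  if (compiled) {
    parms <- as.numeric(pp[model$param_order])
    out <- deSolve::lsoda(unname(y), times,
                          func = model$csym[["func"]],
                          parms = parms,
                          dllname = "homeostat",
                          initfunc = model$csym[["init"]],
                          rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, yy, parms) {
      list(unname(model$rhs(stats::setNames(yy, model$species), pp)))
    }
    out <- deSolve::lsoda(unname(y), times, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("solver failure near t = %.6g", out[nrow(out), 1]),
         call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pre-equilibrate a model onto its attractor
#'
#' For non-oscillatory models, integrates in chunks until the scaled
#' right-hand side falls below `tol`; for oscillatory models, integrates
#' a burn-in and extends it until the period of consecutive cycles of A
#' changes by less than 0.1%.
#'
#' @param model An [hm_model()].
#' @param state0 Starting guess.
#' @param params Optional parameter override (phase-1 values).
#' @param t_chunk Chunk length per convergence check (au).
#' @param max_chunks Chunk budget before giving up.
#' @param tol Residual tolerance for non-oscillatory models:
#'   max over species of |dy/dt| / (|y| + 1).
#' @param period_tol Relative period-change tolerance for oscillators.
#' @param ... Passed to [simulate_model()].
#' @return A list with `state` (the equilibrated state), `converged`,
#'   `t_used`, and either `residual` (non-oscillatory) or `period`
#'   (oscillatory).
#' @export
pre_equilibrate <- function(model, state0, params = NULL, t_chunk = NULL,
                            max_chunks = 20, tol = 1e-6,
                            period_tol = 1e-3, ...) {
  stopifnot(inherits(model, "hm_model"))
  p <- model$params
  if (!is.null(params)) p[names(unlist(params))] <- unlist(params)
  if (is.null(t_chunk)) t_chunk <- if (model$oscillatory) 200 else 500
  y <- .check_state(state0, model$species)
  t_used <- 0
  if (!model$oscillatory) {
    for (i in seq_len(max_chunks)) {
      tr <- simulate_model(model, y, t_end = t_chunk, params = p, ...)
      y <- .traj_last_state(tr, model$species)
      t_used <- t_used + t_chunk
      d <- model$rhs(y, p)
      resid <- max(abs(d) / (abs(y) + 1))
      if (resid < tol) {
        return(list(state = y, converged = TRUE, t_used = t_used,
                    residual = resid))
      }
    }
    return(list(state = y, converged = FALSE, t_used = t_used,
                residual = resid))
  }
  last_period <- NA_real_
  for (i in seq_len(max_chunks)) {
    tr <- simulate_model(model, y, t_end = t_chunk, params = p, ...)
    y <- .traj_last_state(tr, model$species)
    t_used <- t_used + t_chunk
    cyc <- detect_cycles(tr, species = "A")
    if (nrow(cyc) >= 3) {
      pers <- utils::tail(cyc$period, 3)
      if (max(abs(diff(pers))) / mean(pers) < period_tol) {
        return(list(state = y, converged = TRUE, t_used = t_used,
                    period = mean(pers)))
      }
      last_period <- mean(pers)
    }
  }
  list(state = y, converged = FALSE, t_used = t_used, period = last_period)
}

.traj_last_state <- function(tr, species) {
  stats::setNames(as.numeric(tr[nrow(tr), species]), species)
}
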