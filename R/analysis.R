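## Summary statistics of trajectories: cumulative time averages, per-cycle
## frequency series, maximum post-step frequency, response amplitude.

.get_signal <- function(trajectory, species) {
  if (!species %in% names(trajectory)) {
    stop("species '", species, "' not present in trajectory (columns: ",
         paste(setdiff(names(trajectory), "time"), collapse = ", "), ")",
         call. = FALSE)
  }
  list(t = trajectory$time, x = trajectory[[species]])
}

.cumtrapz <- function(t, x) {
  cumsum(c(0, diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2))
}

#' Cumulative (running) time average of a species
#'
#' Computes `<X>(t) = 1/(t - t0) * integral of X from t0 to t` by
#' cumulative trapezoid quadrature on the trajectory grid.  The value at
#' `t0` is defined as `X(t0)`.
#'
#' @param trajectory An `hm_trajectory` (or any tibble with a `time`
#'   column and species columns).
#' @param species Species name.
#' @param t0 Averaging origin (default: trajectory start, so that the
#'   average integrates from the beginning of the run; a step-anchored
#'   origin can be supplied instead).
#' @return A tibble (`time`, `average`) of class `hm_running_average`
#'   with attribute `t0`.
#' @export
running_average <- function(trajectory, species = "A", t0 = NULL) {
  s <- .get_signal(trajectory, species)
  if (is.null(t0)) t0 <- s$t[1]
  if (t0 < s$t[1] || t0 > s$t[length(s$t)]) {
    stop("t0 outside the trajectory span", call. = FALSE)
  }
  keep <- s$t >= t0
  tt <- s$t[keep]; xx <- s$x[keep]
  elapsed <- tt - tt[1]
  avg <- .cumtrapz(tt, xx)
  avg[elapsed > 0] <- avg[elapsed > 0] / elapsed[elapsed > 0]
  avg[elapsed == 0] <- xx[elapsed == 0]
  out <- tibble::tibble(time = tt, average = avg)
  class(out) <- c("hm_running_average", class(out))
  attr(out, "t0") <- t0
  attr(out, "species") <- species
  out
}

#' Asymptote of a cumulative time average
#'
#' The running average of Eq-style cumulative means converges like 1/t,
#' which is slow.  Two estimators are provided:
#'
#' * `"cycle"` (default for oscillatory signals): the trapezoid mean of
#'   the signal over the last `n_cycles` complete detected cycles.  For
#'   a periodic orbit this equals the exact limit of the cumulative
#'   average.  Falls back to `"tail"` when fewer than 2 cycles are found.
#' * `"tail"`: the cumulative average at the end of the horizon,
#'   with a convergence flag (relative change < `conv_tol` over the
#'   final 10% of the span).
#'
#' @param trajectory An `hm_trajectory`.
#' @param species Species name.
#' @param method `"cycle"` or `"tail"`.
#' @param n_cycles Number of trailing complete cycles for the cycle
#'   estimator.
#' @param t_min Only data at `time >= t_min` are used (e.g. to exclude a
#'   pre-step phase).
#' @param conv_tol Convergence threshold for the tail estimator.
#' @return A list with `value`, `method`, `converged`.
#' @export
asymptotic_average <- function(trajectory, species = "A",
                               method = c("cycle", "tail"),
                               n_cycles = 20, t_min = NULL,
                               conv_tol = 1e-3) {
  method <- match.arg(method)
  s <- .get_signal(trajectory, species)
  if (!is.null(t_min)) {
    keep <- s$t >= t_min
    trajectory <- trajectory[keep, , drop = FALSE]
    s <- list(t = s$t[keep], x = s$x[keep])
  }
  if (method == "cycle") {
    cyc <- detect_cycles(trajectory, species = species)
    if (nrow(cyc) >= 2) {
      k <- max(1, nrow(cyc) - n_cycles)
      t_a <- cyc$t_peak[k]; t_b <- cyc$t_peak[nrow(cyc)]
      keep <- s$t >= t_a & s$t <= t_b
      val <- .trapz_mean(s$t[keep], s$x[keep])
      return(list(value = val, method = "cycle", converged = TRUE))
    }
    method <- "tail"
  }
  ra <- running_average(trajectory, species)
  n <- nrow(ra)
  i90 <- which(ra$time >= ra$time[1] + 0.9 * (ra$time[n] - ra$time[1]))[1]
  rel <- abs(ra$average[n] - ra$average[i90]) /
    max(abs(ra$average[n]), .Machine$double.eps)
  list(value = ra$average[n], method = "tail", converged = rel < conv_tol)
}

.trapz_mean <- function(t, x) {
  sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2) /
    (t[length(t)] - t[1])
}

#' Detect oscillation cycles by peak timing
#'
#' Locates local maxima of the signal, refines each peak time by
#' parabolic (three-point) interpolation, discards peaks of prominence
#' below `prominence` times the running peak-to-trough range, and
#' returns one row per cycle (pair of successive qualifying peaks).
#' The frequency is the inverse of the period, matching a per-cycle
#' reading of an oscillation trace.
#'
#' @param trajectory An `hm_trajectory`.
#' @param species Species to analyse (default `"A"`, the plotted
#'   variable of the reference protocols).
#' @param prominence Minimum peak prominence as a fraction of the
#'   running peak-to-trough range (default 1%).
#' @return A tibble of class `hm_cycles` with columns `cycle`,
#'   `t_start`, `t_peak`, `period`, `frequency`, `peak`, `trough`.
#'   Empty (zero rows) when fewer than two qualifying peaks exist,
#'   which signals a non-oscillatory regime.
#' @export
detect_cycles <- function(trajectory, species = "A", prominence = 0.01) {
  s <- .get_signal(trajectory, species)
  tt <- s$t; x <- s$x
  empty <- tibble::tibble(cycle = integer(), t_start = numeric(),
                          t_peak = numeric(), period = numeric(),
                          frequency = numeric(), peak = numeric(),
                          trough = numeric())
  class(empty) <- c("hm_cycles", class(empty))
  if (length(x) < 5) return(empty)
  d <- diff(x)
  ipk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (length(ipk) < 2) return(empty)

  ## topographic prominence against the running peak-to-trough range:
  ## descend from each candidate to the lowest intervening level before
  ## a higher candidate is met on either side; the prominence is the
  ## peak height above the higher of the two bases.  Computed on the
  ## candidate-peak graph (trough minima between consecutive
  ## candidates) for linear total cost.
  run_range <- cummax(x) - cummin(x)
  k <- length(ipk)
  seg_min <- vapply(seq_len(k - 1), function(j) {
    min(x[ipk[j]:ipk[j + 1]])
  }, numeric(1))
  edge_l <- min(x[1:ipk[1]])
  edge_r <- min(x[ipk[k]:length(x)])
  hts <- x[ipk]
  keep <- logical(k)
  for (j in seq_len(k)) {
    ## walk left over candidates until one at least as high
    base_l <- Inf
    jj <- j - 1
    repeat {
      if (jj < 1) { base_l <- min(base_l, edge_l); break }
      base_l <- min(base_l, seg_min[jj])
      if (hts[jj] >= hts[j]) break
      jj <- jj - 1
    }
    base_r <- Inf
    jj <- j
    repeat {
      if (jj > k - 1) { base_r <- min(base_r, edge_r); break }
      base_r <- min(base_r, seg_min[jj])
      if (hts[jj + 1] >= hts[j]) break
      jj <- jj + 1
    }
    prom <- hts[j] - max(base_l, base_r)
    keep[j] <- prom >= prominence * max(run_range[ipk[j]],
                                        .Machine$double.eps)
  }
  ipk <- ipk[keep]
  if (length(ipk) < 2) return(empty)

  ## parabolic sub-sample refinement of peak times
  tpk <- vapply(ipk, function(i) {
    if (i <= 1 || i >= length(x)) return(tt[i])
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(tt[i])
    delta <- 0.5 * (y1 - y3) / den
    delta <- max(min(delta, 0.5), -0.5)
    tt[i] + delta * (tt[min(i + 1, length(tt))] - tt[i])
  }, numeric(1))

  per <- diff(tpk)
  troughs <- vapply(seq_len(length(ipk) - 1), function(j) {
    min(x[ipk[j]:ipk[j + 1]])
  }, numeric(1))
  out <- tibble::tibble(
    cycle = seq_along(per),
    t_start = tpk[-length(tpk)],
    t_peak = tpk[-1],
    period = per,
    frequency = 1 / per,
    peak = x[ipk[-1]],
    trough = troughs
  )
  class(out) <- c("hm_cycles", class(out))
  attr(out, "species") <- species
  attr(out, "prominence") <- prominence
  out
}

#' Maximum post-step oscillation frequency
#'
#' The largest per-cycle frequency among cycles whose defining interval
#' starts at or after the step time; this is the statistic whose
#' background-invariance defines frequency background compensation.
#' Ties resolve to the earliest cycle.
#'
#' @param cycles An `hm_cycles` table from [detect_cycles()].
#' @param t_step Step time.
#' @return The maximum frequency (1/au time).
#' @export
max_post_step_frequency <- function(cycles, t_step) {
  post <- cycles[cycles$t_start >= t_step, , drop = FALSE]
  if (nrow(post) == 0) {
    stop("no complete cycles after the step (overdamped or ",
         "non-oscillatory response)", call. = FALSE)
  }
  max(post$frequency)
}

#' Response amplitude of a step perturbation
#'
#' `delta_A` is the maximal absolute excursion of the species from its
#' pre-step reference after the step: `max over t >= t_step of
#' |X(t) - X_ref|`.  By default `X_ref` is the trajectory value just
#' before the step; a warning is raised when the pre-step state is not
#' settled (|dX/dt| above `settle_tol` just before the step), and the
#' statistic is computed anyway.
#'
#' @param trajectory An `hm_trajectory`.
#' @param t_step Step time.
#' @param reference Optional pre-step reference value; default: the
#'   trajectory value at the last grid point before `t_step`.
#' @param species Species name (default `"A"`).
#' @param settle_tol Threshold on the pre-step derivative estimate.
#' @return The excursion amplitude (au).
#' @export
delta_A <- function(trajectory, t_step, reference = NULL, species = "A",
                    settle_tol = 1e-4) {
  s <- .get_signal(trajectory, species)
  pre <- which(s$t < t_step)
  if (length(pre) == 0) stop("no pre-step samples", call. = FALSE)
  if (is.null(reference)) reference <- s$x[pre[length(pre)]]
  if (length(pre) >= 2) {
    i <- pre[length(pre)]
    slope <- (s$x[i] - s$x[i - 1]) / (s$t[i] - s$t[i - 1])
    if (abs(slope) > settle_tol) {
      warning(sprintf(paste0("pre-step state not settled ",
                             "(|dX/dt| = %.3g just before the step); ",
                             "delta_A computed anyway"), abs(slope)),
              call. = FALSE)
    }
  }
  post <- s$t >= t_step
  max(abs(s$x[post] - reference))
}

#' Verify the harmonic-average limit of the motif-8 scheme
#'
#' For the motif-8 oscillator the set-point of A has no closed form, but
#' averaging the e/E balance over the attractor predicts that the
#' long-time average of `1/(k10 + A)` equals `k7/(k6*k10)`.  This
#' computes the empirical average (cycle-aligned asymptote of the
#' cumulative mean of `1/(k10+A)`), the analytic prediction, and their
#' relative deviation.  A convergence warning is raised when the
#' cumulative average has not flattened (relative change above 0.1%
#' over the last 10% of the span) and no cycle estimate is available.
#'
#' @param trajectory An `hm_trajectory` of the `m8_coherent_osc` model.
#' @param params Parameter vector used for the run (needs `k6`, `k7`,
#'   `k10`).
#' @return A tibble with `empirical`, `predicted`, `rel_deviation`.
#' @export
harmonic_average_check <- function(trajectory, params) {
  p <- as.list(unlist(params))
  s <- .get_signal(trajectory, "A")
  h <- 1 / (p$k10 + s$x)
  htr <- tibble::tibble(time = s$t, A = s$x, h = h)
  est <- asymptotic_average(htr, species = "h", method = "cycle")
  if (!est$converged) {
    warning("running average of 1/(k10+A) has not converged over this ",
            "horizon", call. = FALSE)
  }
  predicted <- p$k7 / (p$k6 * p$k10)
  tibble::tibble(
    empirical = est$value,
    predicted = predicted,
    rel_deviation = abs(est$value - predicted) / predicted
  )
}
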