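#' @keywords internal
#' @useDynLib homeostat, .registration = TRUE
#' @importFrom rlang .data
"_PACKAGE"

## Canonical parameter orders.  These must match src/models.c exactly:
## the C initializers receive the parameter vector in this order.
.hm_param_order <- list(
  m2_coherent_osc = c("k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9", "k10",
                      "k11", "k12", "k13", "k14", "k15", "k16", "k17",
                      "kg", "kg3"),
  m8_coherent_osc = c("k1", "k3", "k4", "k5", "k6", "k7", "k8", "k9", "k10",
                      "k11", "k12", "k13", "k14", "k15", "k16", "k17", "k18",
                      "kg1", "kg2"),
  m2_firstorder = c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9",
                    "k10", "k11", "k12", "k13", "k14", "k15", "k16", "k17",
                    "kg", "kg3"),
  dual_e = c("k2", "k3", "k4", "k5", "k6", "k7", "k9", "k10", "k11", "k12",
             "k13", "k14", "k15", "k16", "k17", "k18", "k19", "k20",
             "kg", "kg3"),
  m2_incoherent_osc = c("k2", "k3", "k4", "k5", "k6", "k7", "k9", "k10",
                        "k11", "k12", "k13", "k14", "k15", "k16",
                        "kg", "kg3")
)

.hm_species <- list(
  m2_coherent_osc   = c("A", "e", "E", "I1", "I2"),
  m8_coherent_osc   = c("A", "e", "E", "I1", "I2"),
  m2_firstorder     = c("A", "e", "E", "I1", "I2"),
  dual_e            = c("A", "a", "E1", "E2", "I1", "I2"),
  m2_incoherent_osc = c("A", "a", "E", "I1", "I2")
)

## Michaelis-type constants that must be strictly positive (they sit in
## denominators of saturation terms).
.hm_michaelis <- list(
  m2_coherent_osc   = c("k5", "k7", "k8", "k13", "k16", "k17"),
  m8_coherent_osc   = c("k5", "k8", "k9", "k10", "k14", "k17", "k18"),
  m2_firstorder     = c("k5", "k7", "k13", "k16"),
  dual_e            = c("k5", "k7", "k14", "k17", "k20"),
  m2_incoherent_osc = c("k5", "k7", "k13", "k16")
)

## Designated perturbation / background parameters per network.
.hm_pert_bg <- list(
  m2_coherent_osc   = c(pert = "k2", bg = "k10"),
  m8_coherent_osc   = c(pert = "k1", bg = "k3"),
  m2_firstorder     = c(pert = "k2", bg = "k10"),
  dual_e            = c(pert = "k2", bg = "k10"),
  m2_incoherent_osc = c(pert = "k2", bg = "k10")
)

.hm_csym <- list(
  m2_coherent_osc   = c(func = "hm_d_m2_coherent",   init = "hm_init_m2_coherent"),
  m8_coherent_osc   = c(func = "hm_d_m8_coherent",   init = "hm_init_m8_coherent"),
  m2_firstorder     = c(func = "hm_d_m2_firstorder", init = "hm_init_m2_firstorder"),
  dual_e            = c(func = "hm_d_dual_e",        init = "hm_init_dual_e"),
  m2_incoherent_osc = c(func = "hm_d_m2_incoherent", init = "hm_init_m2_incoherent")
)

.hm_oscillatory <- c(m2_coherent_osc = TRUE, m8_coherent_osc = TRUE,
                     m2_firstorder = FALSE, dual_e = FALSE,
                     m2_incoherent_osc = TRUE)

#' Names of the available homeostat networks
#'
#' @return Character vector of model names accepted by [hm_model()].
#' @export
model_names <- function() names(.hm_param_order)

#' Retrieve a homeostat model definition
#'
#' A model definition bundles the ordered species layout, the parameter
#' schema, the R and compiled right-hand sides, the designated perturbation
#' and background parameters, and the analytic set-point calculator of one
#' of the five reference networks:
#'
#' * `m2_coherent_osc` — oscillatory inflow controller (motif 2) with the
#'   outer integral controllers I1/I2 feeding back coherently through the
#'   controlled variable A.  Zero-order removals of A make it a relaxation
#'   oscillator.
#' * `m8_coherent_osc` — oscillatory outflow controller (motif 8): A
#'   inhibits production of the controller E via the intermediate e, and E
#'   inhibits A's removal; I1/I2 again act directly on A.
#' * `m2_firstorder` — the motif-2 scheme with every A-removing reaction
#'   changed to first-order kinetics in A; non-oscillatory.
#' * `dual_e` — two inflow controllers E1/E2 with different set-points for
#'   A; only E2 is wrapped by the coherent I1/I2 layer.
#' * `m2_incoherent_osc` — negative control: E, I1 and I2 feed back to a
#'   precursor a of A instead of to A itself; frequency homeostasis
#'   survives but background compensation is lost.
#'
#' @param name One of [model_names()].
#' @param params Optional named parameter vector/list overriding the
#'   model's reference defaults (see [default_params()]).
#' @return An object of class `hm_model`.
#' @examples
#' m <- hm_model("m2_coherent_osc")
#' m$species
#' setpoints(m)
#' @export
hm_model <- function(name = model_names(), params = NULL) {
  name <- match.arg(name)
  p <- default_params(name)
  if (!is.null(params)) {
    params <- unlist(params)
    unknown <- setdiff(names(params), names(p))
    if (length(unknown) > 0) {
      stop("unknown parameter(s) for ", name, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[names(params)] <- params
  }
  validate_params(name, p)
  structure(
    list(
      name = name,
      species = .hm_species[[name]],
      params = p,
      param_order = .hm_param_order[[name]],
      rhs = .hm_rhs_fun(name),
      pert_param = .hm_pert_bg[[name]][["pert"]],
      bg_param = .hm_pert_bg[[name]][["bg"]],
      oscillatory = unname(.hm_oscillatory[name]),
      csym = .hm_csym[[name]]
    ),
    class = "hm_model"
  )
}

#' @export
print.hm_model <- function(x, ...) {
  cat("<hm_model> ", x$name,
      if (x$oscillatory) " (oscillatory)" else " (non-oscillatory)", "\n",
      sep = "")
  cat("  species:      ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  perturbation: ", x$pert_param, ",  background: ", x$bg_param,
      "\n", sep = "")
  cat("  parameters:   ", paste(names(x$params), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.hm_rhs_fun <- function(name) {
  switch(name,
    m2_coherent_osc   = rhs_m2_coherent,
    m8_coherent_osc   = rhs_m8_coherent,
    m2_firstorder     = rhs_m2_firstorder,
    dual_e            = rhs_dual_e,
    m2_incoherent_osc = rhs_m2_incoherent
  )
}

validate_params <- function(name, p) {
  need <- .hm_param_order[[name]]
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) {
    stop("missing parameter(s) for ", name, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- p[need]
  if (any(!is.finite(unlist(p)))) {
    stop("non-finite parameter value(s) for ", name, call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("negative parameter value(s) for ", name, ": rate constants are ",
         "nonnegative", call. = FALSE)
  }
  km <- .hm_michaelis[[name]]
  bad <- km[unlist(p[km]) <= 0]
  if (length(bad) > 0) {
    stop("Michaelis-type constant(s) must be > 0 for ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.check_state <- function(state, species) {
  state <- unlist(state)
  if (!all(species %in% names(state))) {
    stop("state must contain components ", paste(species, collapse = ", "),
         call. = FALSE)
  }
  state <- state[species]
  if (any(!is.finite(state))) stop("non-finite state component", call. = FALSE)
  state
}

## ---- R reference right-hand sides ------------------------------------

#' Right-hand side of the motif-2 coherent-feedback oscillator
#'
#' Time derivatives of the five species (A, e, E, I1, I2).  A receives a
#' derepression inflow k3*k5/(k5+E) plus a controller inflow kg3*I2, and
#' is removed by the controller outflow kg*A*I1/(k17+A) and by the
#' zero-order perturbation (k2) and background (k10) fluxes
#' k*A/(k8+A).  The e/E pair forms the inner oscillator; I1 and I2 are
#' the outer integral controllers with zero-order removals.
#'
#' @param state Named numeric vector with components A, e, E, I1, I2.
#' @param params Named parameter vector (see
#'   `hm_model("m2_coherent_osc")$params` for the schema).
#' @return Named numeric vector of time derivatives (au/time).
#' @export
rhs_m2_coherent <- function(state, params) {
  validate_params("m2_coherent_osc", params)
  s <- .check_state(state, .hm_species$m2_coherent_osc)
  k <- as.list(params)
  with(c(as.list(s), k), {
    c(A  = kg3 * I2 + k3 * k5 / (k5 + E) - kg * A * I1 / (k17 + A) -
           k2 * A / (k8 + A) - k10 * A / (k8 + A),
      e  = k4 * A - k9 * e,
      E  = k9 * e - k6 * E / (k7 + E),
      I1 = k11 * E - k12 * I1 / (k13 + I1),
      I2 = k14 - (k15 * I2 / (k16 + I2)) * E)
  })
}

#' Right-hand side of the motif-8 coherent-feedback oscillator
#'
#' The perturbation (k1) and background (k3) enter as zero-order inflows
#' to A; A is removed by the saturable flux (k4*A/(k5+A)) * (k9/(k9+E)),
#' which E inhibits, and by the controller outflow (kg2*A/(k18+A))*I2;
#' I1 feeds A's inflow.  A inhibits production of e
#' (k6*k10/(k10+A)); e matures into E.
#'
#' @inheritParams rhs_m2_coherent
#' @return Named numeric vector of time derivatives (au/time).
#' @export
rhs_m8_coherent <- function(state, params) {
  validate_params("m8_coherent_osc", params)
  s <- .check_state(state, .hm_species$m8_coherent_osc)
  with(c(as.list(s), as.list(params)), {
    c(A  = k1 + k3 - (kg2 * A / (k18 + A)) * I2 + kg1 * I1 -
           (k4 * A / (k5 + A)) * (k9 / (k9 + E)),
      e  = k6 * k10 / (k10 + A) - k11 * e,
      E  = k11 * e - k7 * E / (k8 + E),
      I1 = k12 * E - k13 * I1 / (k14 + I1),
      I2 = k15 - (k16 * I2 / (k17 + I2)) * E)
  })
}

#' Right-hand side of the first-order (non-oscillatory) motif-2 scheme
#'
#' As the coherent motif-2 network, but all A-removing reactions are
#' first order in A, which abolishes the oscillations.  A constant basal
#' inflow k1 is included with default 0.
#'
#' @inheritParams rhs_m2_coherent
#' @return Named numeric vector of time derivatives (au/time).
#' @export
rhs_m2_firstorder <- function(state, params) {
  validate_params("m2_firstorder", params)
  s <- .check_state(state, .hm_species$m2_firstorder)
  with(c(as.list(s), as.list(params)), {
    c(A  = k1 + kg3 * I2 + k3 * k5 / (k5 + E) - kg * A * I1 -
           k2 * A - k10 * A,
      e  = k4 * A - k9 * e,
      E  = k9 * e - k6 * E / (k7 + E),
      I1 = k11 * E - k12 * I1 / (k13 + I1),
      I2 = k14 - (k15 * I2 / (k16 + I2)) * E)
  })
}

#' Right-hand side of the dual inflow-controller scheme
#'
#' Two inflow controllers act on A: E1 (through the precursor a) with
#' set-point k6/k4, and E2 (direct inflow k11*E2) with the lower
#' set-point k12/k13, which therefore takes over control.  Only E2 is
#' held at its own set-point by the coherent I1/I2 layer acting directly
#' on A.
#'
#' @param state Named numeric vector with components A, a, E1, E2, I1, I2.
#' @inheritParams rhs_m2_coherent
#' @return Named numeric vector of time derivatives (au/time).
#' @export
rhs_dual_e <- function(state, params) {
  validate_params("dual_e", params)
  s <- .check_state(state, .hm_species$dual_e)
  with(c(as.list(s), as.list(params)), {
    c(A  = kg * I2 - kg3 * A * I1 - k2 * A - k10 * A + k9 * a + k11 * E2,
      a  = k3 * k5 / (k5 + E1) - k9 * a,
      E1 = k4 * A - k6 * E1 / (k7 + E1),
      E2 = k12 - A * (k13 * E2 / (k14 + E2)),
      I1 = k15 - (k16 * I1 / (k17 + I1)) * E2,
      I2 = k18 * E2 - k19 * I2 / (k20 + I2))
  })
}

#' Right-hand side of the incoherent-feedback motif-2 oscillator
#'
#' E, I1 and I2 feed back to the precursor a rather than to A itself
#' (incoherent wiring).  The perturbation (k2) and background (k10)
#' remove A by first-order kinetics.  This network retains frequency
#' homeostasis but loses background compensation.
#'
#' @param state Named numeric vector with components A, a, E, I1, I2.
#' @inheritParams rhs_m2_coherent
#' @return Named numeric vector of time derivatives (au/time).
#' @export
rhs_m2_incoherent <- function(state, params) {
  validate_params("m2_incoherent_osc", params)
  s <- .check_state(state, .hm_species$m2_incoherent_osc)
  with(c(as.list(s), as.list(params)), {
    c(A  = k9 * a - k2 * A - k10 * A,
      a  = (kg3 * I2 + k3 / (k5 + E)) * k5 - kg * a * I1 - k9 * a,
      E  = k4 * A - k6 * E / (k7 + E),
      I1 = k11 * E - k12 * I1 / (k13 + I1),
      I2 = k14 - (k15 * I2 / (k16 + I2)) * E)
  })
}

#' Evaluate a model's right-hand side
#'
#' @param model An [hm_model()].
#' @param state Named state vector.
#' @param params Optional parameter override (defaults to `model$params`).
#' @return Named numeric vector of derivatives.
#' @export
model_rhs <- function(model, state, params = NULL) {
  stopifnot(inherits(model, "hm_model"))
  p <- model$params
  if (!is.null(params)) p[names(unlist(params))] <- unlist(params)
  model$rhs(state, p)
}

## ---- analytic set-points ---------------------------------------------

#' Analytic set-points of a homeostat network
#'
#' Computes the steady-state set-points implied by the zero-order
#' (saturated-removal) limit of each integral controller:
#'
#' * motif-2 family (`m2_coherent_osc`, `m2_firstorder`,
#'   `m2_incoherent_osc`): `A_set = k6/k4`, `E_set_I1 = k12/k11`
#'   (outflow controller), `E_set_I2 = k14/k15` (inflow controller).
#'   A windup warning is raised when `E_set_I2 >= E_set_I1`, because the
#'   inflow controller's set-point must lie below the outflow
#'   controller's for the pair to cooperate.
#' * `m8_coherent_osc`: `E_set_I1 = k13/k12`, `E_set_I2 = k15/k16`, plus
#'   the only analytic handle on A: the long-time average of
#'   `1/(k10+A)` equals `k7/(k6*k10)` (`inv_shifted_A_average`).  `A_set`
#'   itself has no closed form (`A_set` is returned as `NA`); the
#'   m2-style ordering rule is deliberately not applied to this scheme.
#' * `dual_e`: `A_set_E1 = k6/k4`, `A_set_E2 = k12/k13` (must satisfy
#'   `A_set_E2 < A_set_E1` for E2 to take over; violation raises a
#'   windup warning), and the E2 set-points of the I-controller pair,
#'   `E2_set_I1 = k15/k16` and `E2_set_I2 = k19/k18`.
#'
#' @param model An [hm_model()] (or a model name).
#' @param params Optional parameter override.
#' @return A one-row tibble of set-points.
#' @examples
#' setpoints(hm_model("m2_coherent_osc"))  # A_set = 2, E sets 5.0 / 4.99
#' @export
setpoints <- function(model, params = NULL) {
  if (is.character(model)) model <- hm_model(model, params = params)
  else if (!is.null(params)) model <- hm_model(model$name, params = params)
  p <- as.list(model$params)
  switch(model$name,
    m2_coherent_osc   = .setpoints_m2(p),
    m2_firstorder     = .setpoints_m2(p),
    m2_incoherent_osc = .setpoints_m2(p),
    m8_coherent_osc   = .setpoints_m8(p),
    dual_e            = .setpoints_dual_e(p)
  )
}

.chk_pos <- function(p, keys) {
  bad <- keys[vapply(p[keys], function(x) x <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("set-point denominators must be > 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

.setpoints_m2 <- function(p) {
  .chk_pos(p, c("k4", "k11", "k15"))
  out <- tibble::tibble(
    A_set = p$k6 / p$k4,
    E_set_I1 = p$k12 / p$k11,
    E_set_I2 = p$k14 / p$k15
  )
  if (out$E_set_I2 >= out$E_set_I1) {
    warning("windup risk: E_set_I2 (", format(out$E_set_I2),
            ") is not below E_set_I1 (", format(out$E_set_I1),
            "); the I1/I2 controllers may work against each other",
            call. = FALSE)
  }
  out
}

.setpoints_m8 <- function(p) {
  .chk_pos(p, c("k12", "k16", "k6", "k10"))
  tibble::tibble(
    A_set = NA_real_,   # no closed form for this scheme
    E_set_I1 = p$k13 / p$k12,
    E_set_I2 = p$k15 / p$k16,
    inv_shifted_A_average = p$k7 / (p$k6 * p$k10)
  )
}

.setpoints_dual_e <- function(p) {
  .chk_pos(p, c("k4", "k13", "k16", "k18"))
  out <- tibble::tibble(
    A_set_E1 = p$k6 / p$k4,
    A_set_E2 = p$k12 / p$k13,
    E2_set_I1 = p$k15 / p$k16,
    E2_set_I2 = p$k19 / p$k18
  )
  if (out$A_set_E2 >= out$A_set_E1) {
    warning("windup risk: A_set_E2 (", format(out$A_set_E2),
            ") is not below A_set_E1 (", format(out$A_set_E1),
            "); E2 cannot take over control from E1", call. = FALSE)
  }
  out
}
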