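## Intensity-response algebra of retinal light adaptation: the Hill /
## Naka-Rushton description and the background-shift identity showing
## that parallel log-intensity response curves need no background
## compensation mechanism.

#' Hill intensity-response function
#'
#' `V = V_max * I^alpha / (I^alpha + sigma^alpha)`.  With `alpha = 1`
#' this is the Naka-Rushton (Michaelis-Menten) relation of rods and
#' cones; horizontal cells show alpha ~ 0.7-0.8, bipolar and sustained
#' ganglion cells 1.2-1.4, transient ganglion cells ~3.4.
#'
#' @param I Light intensity (>= 0; vectorised).
#' @param V_max Response-amplitude scale (> 0).
#' @param sigma Half-saturation intensity (> 0).
#' @param alpha Cooperativity (> 0, default 1).
#' @return Response amplitude(s) in `[0, V_max)`.
#' @examples
#' hill_response(1, V_max = 1, sigma = 1)  # half saturation: 0.5
#' @export
hill_response <- function(I, V_max = 1, sigma, alpha = 1) {
  if (any(I < 0)) stop("intensity must be nonnegative", call. = FALSE)
  stopifnot(V_max > 0, sigma > 0, alpha > 0)
  V_max * I^alpha / (I^alpha + sigma^alpha)
}

.check_alpha1 <- function(alpha) {
  if (alpha != 1) {
    stop("the background-shift identity holds for the single-pigment ",
         "case alpha = 1 only", call. = FALSE)
  }
}

#' Steady response to a background alone
#'
#' `V0 = V_max * I0 / (I0 + sigma)` (alpha = 1).
#'
#' @param I0 Background intensity (>= 0).
#' @inheritParams hill_response
#' @return Background response V0.
#' @export
background_response <- function(I0, V_max = 1, sigma, alpha = 1) {
  .check_alpha1(alpha)
  hill_response(I0, V_max, sigma, alpha = 1)
}

#' Incremental response to a perturbation on a background
#'
#' The response to a light perturbation `I_pert` applied on top of a
#' constant background `I0` is the total response minus the background
#' response, which factorises as
#' `V1 = V_max * (sigma/(I0+sigma)) * I_pert/(I0 + I_pert + sigma)`:
#' the same Naka-Rushton law with `sigma` shifted to `sigma + I0` and
#' `V_max` scaled by `sigma/(sigma + I0)`.
#'
#' @param I_pert Perturbation intensity (>= 0).
#' @inheritParams background_response
#' @return Incremental response V1.
#' @export
incremental_response <- function(I0, I_pert, V_max = 1, sigma, alpha = 1) {
  .check_alpha1(alpha)
  if (any(I_pert < 0)) stop("intensity must be nonnegative", call. = FALSE)
  V_max * (sigma / (I0 + sigma)) * I_pert / (I0 + I_pert + sigma)
}

#' Background-shifted effective parameters
#'
#' A background `I0` turns the alpha = 1 intensity-response curve into
#' the same law with `sigma1 = sigma + I0` and
#' `V_max1 = V_max * sigma/(sigma + I0)`; so increasing backgrounds
#' translate the curve along a log-intensity axis and compress its
#' amplitude, with no compensation mechanism required.
#'
#' @inheritParams background_response
#' @return One-row tibble (`V_max1`, `sigma1`, `I0`).
#' @export
effective_params <- function(I0, V_max = 1, sigma, alpha = 1) {
  .check_alpha1(alpha)
  if (any(I0 < 0)) stop("intensity must be nonnegative", call. = FALSE)
  tibble::tibble(V_max1 = V_max * sigma / (sigma + I0),
                 sigma1 = sigma + I0,
                 I0 = I0)
}

#' Family of intensity-response curves
#'
#' Evaluates the alpha = 1 response over an intensity grid for several
#' half-saturation values (each sigma mimicking a different adaptation
#' state / background level).  On a logarithmic intensity axis the
#' curves are horizontal translates of one another.
#'
#' @param sigmas Half-saturation intensities (> 0).
#' @param V_max Response-amplitude scale.
#' @param I Intensity grid; default: 400 points log-spaced on
#'   `[1e-6, 1e2]`.
#' @return A tibble (`sigma`, `I`, `V`).
#' @export
intensity_response_family <- function(sigmas = 10^(-4:1), V_max = 1,
                                      I = NULL) {
  if (is.null(I)) I <- 10^seq(-6, 2, length.out = 400)
  if (any(I < 0)) stop("intensity must be nonnegative", call. = FALSE)
  stopifnot(all(sigmas > 0))
  tidyr::expand_grid(sigma = sigmas, I = I) |>
    dplyr::mutate(V = hill_response(.data$I, V_max = V_max,
                                    sigma = .data$sigma))
}
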