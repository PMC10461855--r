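## Independent oracles used across the test files.

## Term-by-term flux tables: each model's RHS written as a signed sum of
## individually evaluated reaction fluxes, assembled independently of
## the packaged implementations (both the R reference and the C code).
flux_table_m2_coherent <- function(s, p) {
  with(c(as.list(s), as.list(p)), list(
    A = c(+kg3 * I2,
          +k3 * k5 / (k5 + E),
          -kg * A * I1 / (k17 + A),
          -k2 * A / (k8 + A),
          -k10 * A / (k8 + A)),
    e = c(+k4 * A, -k9 * e),
    E = c(+k9 * e, -k6 * E / (k7 + E)),
    I1 = c(+k11 * E, -k12 * I1 / (k13 + I1)),
    I2 = c(+k14, -(k15 * I2 / (k16 + I2)) * E)
  ))
}

flux_table_m8_coherent <- function(s, p) {
  with(c(as.list(s), as.list(p)), list(
    A = c(+k1, +k3,
          -(kg2 * A / (k18 + A)) * I2,
          +kg1 * I1,
          -(k4 * A / (k5 + A)) * (k9 / (k9 + E))),
    e = c(+k6 * k10 / (k10 + A), -k11 * e),
    E = c(+k11 * e, -k7 * E / (k8 + E)),
    I1 = c(+k12 * E, -k13 * I1 / (k14 + I1)),
    I2 = c(+k15, -(k16 * I2 / (k17 + I2)) * E)
  ))
}

flux_table_m2_firstorder <- function(s, p) {
  with(c(as.list(s), as.list(p)), list(
    A = c(+k1, +kg3 * I2, +k3 * k5 / (k5 + E),
          -kg * A * I1, -k2 * A, -k10 * A),
    e = c(+k4 * A, -k9 * e),
    E = c(+k9 * e, -k6 * E / (k7 + E)),
    I1 = c(+k11 * E, -k12 * I1 / (k13 + I1)),
    I2 = c(+k14, -(k15 * I2 / (k16 + I2)) * E)
  ))
}

flux_table_dual_e <- function(s, p) {
  with(c(as.list(s), as.list(p)), list(
    A = c(+kg * I2, -kg3 * A * I1, -k2 * A, -k10 * A, +k9 * a, +k11 * E2),
    a = c(+k3 * k5 / (k5 + E1), -k9 * a),
    E1 = c(+k4 * A, -k6 * E1 / (k7 + E1)),
    E2 = c(+k12, -A * (k13 * E2 / (k14 + E2))),
    I1 = c(+k15, -(k16 * I1 / (k17 + I1)) * E2),
    I2 = c(+k18 * E2, -k19 * I2 / (k20 + I2))
  ))
}

flux_table_m2_incoherent <- function(s, p) {
  with(c(as.list(s), as.list(p)), list(
    A = c(+k9 * a, -k2 * A, -k10 * A),
    a = c(+kg3 * I2 * k5, +k3 * k5 / (k5 + E), -kg * a * I1, -k9 * a),
    E = c(+k4 * A, -k6 * E / (k7 + E)),
    I1 = c(+k11 * E, -k12 * I1 / (k13 + I1)),
    I2 = c(+k14, -(k15 * I2 / (k16 + I2)) * E)
  ))
}

flux_oracle <- function(name, s, p) {
  tab <- switch(name,
    m2_coherent_osc = flux_table_m2_coherent(s, p),
    m8_coherent_osc = flux_table_m8_coherent(s, p),
    m2_firstorder = flux_table_m2_firstorder(s, p),
    dual_e = flux_table_dual_e(s, p),
    m2_incoherent_osc = flux_table_m2_incoherent(s, p))
  vapply(tab, sum, numeric(1))
}

## Random positive state/parameter draws around a model's defaults.
random_draw <- function(model, seed) {
  set.seed(seed)
  p <- model$params * exp(stats::runif(length(model$params), -0.3, 0.3))
  s <- stats::setNames(exp(stats::runif(length(model$species), -2, 2)),
                       model$species)
  list(state = s, params = p)
}

## High-resolution trapezoid quadrature oracle for running averages.
quad_mean_oracle <- function(f, t0, t1, n = 20001) {
  tt <- seq(t0, t1, length.out = n)
  x <- f(tt)
  sum(diff(tt) * (head(x, -1) + tail(x, -1)) / 2) / (t1 - t0)
}
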