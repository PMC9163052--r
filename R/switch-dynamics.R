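# Deterministic dynamics of the regulatory switches: drift fields, the
# signal-effect coefficient, signal reaction terms and the density-dependent
# stem synthesis rate.

#' Drift of the stem-cell bistable switch
#'
#' Right-hand side of the mutual-repression ODE at determinant counts
#' `(x, y)`.  Vectorised over `x` and `y`.
#'
#' @param x,y Determinant counts (non-negative).
#' @param params A [bistable_params()] object.
#' @return A tibble with columns `x`, `y`, `rate_x`, `rate_y`.
#' @examples
#' stem_drift(0, 0, bistable_params()) # (85, 100) at the defaults
#' @export
stem_drift <- function(x, y, params = bistable_params()) {
  stopifnot(inherits(params, "bistable_params"))
  check_state(x, y)
  d <- cpp_drift(as_switch(params), as.double(x), as.double(y))
  tibble(x = x, y = y, rate_x = d[, 1], rate_y = d[, 2])
}

#' Drift of the progenitor tristable switch
#'
#' Right-hand side of the self-activation + mutual-repression ODE at
#' determinant counts `(x, y)`, including the additive signal-effect
#' increments carried in `params`.
#'
#' @inheritParams stem_drift
#' @param params A [tristable_params()] object.
#' @return A tibble with columns `x`, `y`, `rate_x`, `rate_y`.
#' @export
progenitor_drift <- function(x, y, params = tristable_params()) {
  stopifnot(inherits(params, "tristable_params"))
  check_state(x, y)
  d <- cpp_drift(as_switch(params), as.double(x), as.double(y))
  tibble(x = x, y = y, rate_x = d[, 1], rate_y = d[, 2])
}

check_state <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    abort("determinant counts must be finite and non-negative")
  }
}

#' Signal-effect coefficient
#'
#' Converts a local signal count into the additive increment of the
#' progenitor self-activation rate: linear in `s` up to the threshold `b`,
#' saturating at `a` beyond it.  Continuous and non-decreasing, bounded by
#' `a`.
#'
#' @param s Signal molecule count(s), non-negative.
#' @param params A [signal_effect_params()] object.
#' @return Numeric vector of increments in `[0, a]`.
#' @examples
#' signal_effect(30) # saturated: equals a = 10
#' @export
signal_effect <- function(s, params = signal_effect_params()) {
  stopifnot(inherits(params, "signal_effect_params"))
  if (any(!is.finite(s)) || any(s < 0)) abort("`s` must be non-negative")
  ifelse(s <= params$b, params$a * s / params$b, params$a)
}

#' Reaction terms of the signalling layer
#'
#' Per-mesh production and decay rates of the two signal species (the
#' diffusion term is handled by the lattice engine as hop events).
#'
#' @param s1,s2 Signal counts, non-negative.
#' @param params A [signal_params()] object.
#' @return A tibble with columns `prod1`, `deg1`, `prod2`, `deg2`.
#' @export
signal_reaction_rates <- function(s1, s2, params = signal_params()) {
  stopifnot(inherits(params, "signal_params"))
  if (any(s1 < 0) || any(s2 < 0)) abort("signal counts must be non-negative")
  bn <- params$beta^params$hill_n
  tibble(
    prod1 = params$alpha_1 * bn / (bn + s2^params$hill_n),
    deg1 = params$k * s1,
    prod2 = params$alpha_2 * bn / (bn + s1^params$hill_n),
    deg2 = params$k * s2
  )
}

#' Density-dependent stem synthesis rate
#'
#' The synthesis rate of the stem determinant X is a strictly decreasing
#' function of the number of dividing cells `n_total`, anchored so that it
#' equals `base` at the calibration density `n0`:
#' `base * n0 / (n0 + max(0, n_total - n0))`.  This negative feedback is
#' what stabilises the dividing-cell density in the mean-field analysis
#' (the determinant of the reduced Jacobian is proportional to the slope).
#'
#' @param n_total Current number of dividing (S + P) cells.
#' @param base Synthesis rate at (and below) the calibration density.
#' @param n0 Calibration density (the initial dividing-cell census in a
#'   simulation).
#' @return Numeric rate(s), `<= base`, strictly decreasing for
#'   `n_total > n0`.
#' @export
iota_xs_of_n <- function(n_total, base = 85, n0 = 100) {
  if (any(n_total < 0)) abort("`n_total` must be >= 0")
  check_positive(base, "base"); check_positive(n0, "n0")
  base * n0 / (n0 + pmax(0, n_total - n0))
}
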