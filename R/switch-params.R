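# Parameter bundles for the three two-variable regulatory circuits and the
# signalling layer.  Defaults are the model's reference rates.

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite positive number", what))
  }
  invisible(x)
}

#' Parameters of the mutual-repression bistable switch
#'
#' The stem-cell fate switch: two determinants X and Y repress each other's
#' synthesis through a Hill function and degrade linearly,
#' \deqn{dx/dt = \iota_x \beta^n / (\beta^n + y^n) - \gamma x,}
#' and symmetrically for y.  The default values give two stable fixed points,
#' one X-dominant (the stem, S, fate) and one Y-dominant (the progenitor, P,
#' fate).
#'
#' @param iota_x,iota_y Synthesis (inhibition) rates, molecules per unit time.
#' @param beta Half-saturation constant of the Hill terms, molecules.
#' @param hill_n Hill coefficient (dimensionless, >= 1).
#' @param gamma First-order degradation rate, per unit time.
#' @return An object of class `bistable_params`.
#' @examples
#' p <- bistable_params()
#' stem_drift(0, 0, p) # both Hill terms are 1 at zero repressor
#' @export
bistable_params <- function(iota_x = 85, iota_y = 100, beta = 45,
                            hill_n = 4, gamma = 1) {
  check_positive(iota_x, "iota_x"); check_positive(iota_y, "iota_y")
  check_positive(beta, "beta"); check_positive(gamma, "gamma")
  check_positive(hill_n, "hill_n")
  if (hill_n < 1) abort("`hill_n` must be >= 1")
  structure(list(iota_x = iota_x, iota_y = iota_y, beta = beta,
                 hill_n = hill_n, gamma = gamma),
            class = c("bistable_params", "switch_params"))
}

#' Parameters of the self-activating tristable switch
#'
#' The progenitor fate switch: each determinant activates its own synthesis
#' and represses the other's,
#' \deqn{dx/dt = (\alpha_x + \varepsilon_x) x^n/(\beta^n + x^n) +
#'   \iota_x \beta^n/(\beta^n + y^n) - \gamma x,}
#' and symmetrically for y.  At the defaults with `eps_x = eps_y = 0` the
#' system has three stable fixed points: a balanced one (P fate) and two
#' dominant ones (A: x wins, B: y wins).  `eps_x`/`eps_y` are the additive
#' signal-effect increments computed from local signal counts by
#' [signal_effect()].
#'
#' @param alpha_x,alpha_y Self-activation rates.
#' @param iota_x,iota_y Mutual-inhibition synthesis rates.
#' @param beta Half-saturation constant, molecules.
#' @param hill_n Hill coefficient.
#' @param gamma Degradation rate, per unit time.
#' @param eps_x,eps_y Signal-effect increments (in `[0, a]`, see
#'   [signal_effect_params()]).
#' @return An object of class `tristable_params`.
#' @export
tristable_params <- function(alpha_x = 30, alpha_y = 30, iota_x = 30,
                             iota_y = 30, beta = 47.5, hill_n = 4,
                             gamma = 0.38, eps_x = 0, eps_y = 0) {
  check_positive(alpha_x, "alpha_x"); check_positive(alpha_y, "alpha_y")
  check_positive(iota_x, "iota_x"); check_positive(iota_y, "iota_y")
  check_positive(beta, "beta"); check_positive(gamma, "gamma")
  check_positive(hill_n, "hill_n")
  if (eps_x < 0 || eps_y < 0) abort("`eps_x`/`eps_y` must be >= 0")
  structure(list(alpha_x = alpha_x, alpha_y = alpha_y, iota_x = iota_x,
                 iota_y = iota_y, beta = beta, hill_n = hill_n,
                 gamma = gamma, eps_x = eps_x, eps_y = eps_y),
            class = c("tristable_params", "switch_params"))
}

#' Saturation parameters of the signal-effect coefficient
#'
#' The local signal count s is converted into an additive increment of the
#' progenitor self-activation rate: `a * s / b` for `s <= b`, saturating at
#' `a` above the threshold.
#'
#' @param a Saturation value of the increment (rate units).
#' @param b Saturation threshold (molecule count).
#' @return An object of class `signal_effect_params`.
#' @export
signal_effect_params <- function(a = 10, b = 15) {
  check_positive(a, "a"); check_positive(b, "b")
  structure(list(a = a, b = b), class = "signal_effect_params")
}

#' Parameters of the signalling reaction-diffusion layer
#'
#' Two signal species produced by the terminal cell types repress each
#' other's production (Hill kinetics), decay at first order and hop between
#' adjacent meshes,
#' \deqn{ds_1/dt = D \nabla^2 s_1 + \alpha_1 \beta^n/(\beta^n + s_2^n) - k s_1,}
#' and symmetrically for s2.
#'
#' @param D Diffusion coefficient, area per unit time.
#' @param k First-order decay rate, per unit time.
#' @param alpha_1,alpha_2 Maximal production rates.
#' @param beta Half-saturation constant of the mutual repression, molecules.
#' @param hill_n Hill coefficient.
#' @param h Mesh spacing, length units.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(D = 110, k = 0.5, alpha_1 = 220, alpha_2 = 220,
                          beta = 2, hill_n = 4, h = 1) {
  for (nm in c("D", "k", "alpha_1", "alpha_2", "beta", "hill_n", "h")) {
    check_positive(get(nm), nm)
  }
  structure(list(D = D, k = k, alpha_1 = alpha_1, alpha_2 = alpha_2,
                 beta = beta, hill_n = hill_n, h = h),
            class = c("signal_params", "switch_params"))
}

# Canonical generic-switch representation consumed by the compiled code:
# dx = (ax+ex) act(x) + ix rep(y) - g x.
as_switch <- function(p) {
  if (inherits(p, "bistable_params")) {
    list(ax = 0, ay = 0, ex = 0, ey = 0, ix = p$iota_x, iy = p$iota_y,
         beta = p$beta, hill_n = p$hill_n, gamma = p$gamma)
  } else if (inherits(p, "tristable_params")) {
    list(ax = p$alpha_x, ay = p$alpha_y, ex = p$eps_x, ey = p$eps_y,
         ix = p$iota_x, iy = p$iota_y, beta = p$beta, hill_n = p$hill_n,
         gamma = p$gamma)
  } else if (inherits(p, "signal_params")) {
    list(ax = 0, ay = 0, ex = 0, ey = 0, ix = p$alpha_1, iy = p$alpha_2,
         beta = p$beta, hill_n = p$hill_n, gamma = p$k)
  } else {
    abort("not a switch parameter object")
  }
}

default_params_for <- function(system) {
  switch(system,
         stem = bistable_params(),
         progenitor = tristable_params(),
         signal = signal_params(),
         abort(sprintf("unknown system '%s'", system)))
}
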