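# Deterministic population-level (mean-field) model: ODE right-hand side
# for the four cell-type densities, closed-form steady state, the
# parameter-regime conditions, and the reduced-Jacobian stability
# criteria, plus recovery of effective rates from simulation event tallies.

#' Mean-field rate parameters
#'
#' Per-capita rates of the population-level reactions: three stem division
#' types (`eta`: S -> S+P, `eta_S`: S -> S+S, `eta_P`: S -> P+P),
#' reversible S/P transformation (`w_P`: S -> P, `w_S`: P -> S), dividing
#' cell death (`gamma_S`, `gamma_P`), six progenitor division types
#' (`lambda_P`: P+P, `lambda_A`: A+P, `lambda_B`: B+P, `mu_d`: A+B,
#' `mu_A`: A+A, `mu_B`: B+B) and terminal death (`gamma_A`, `gamma_B`).
#' `eta_S_slope` is the derivative of the density-dependent `eta_S(n)` at
#' the evaluation point; it must be <= 0 (negative feedback) for the
#' dividing-cell fixed point to be strictly stable.
#'
#' @param eta,eta_S,eta_P Stem division-type rates.
#' @param w_S,w_P Transformation rates (P->S and S->P).
#' @param gamma_S,gamma_P Dividing-cell death rates.
#' @param lambda_P,lambda_A,lambda_B,mu_d,mu_A,mu_B Progenitor
#'   division-type rates.
#' @param gamma_A,gamma_B Terminal-cell death rates.
#' @param eta_S_slope d(eta_S)/dn at the evaluation point (<= 0).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(eta = 0.2, eta_S = 0.1, eta_P = 0.25, w_S = 0.1645,
                        w_P = 0.329, gamma_S = 0.0423, gamma_P = 0.01504,
                        lambda_P = 0.5, lambda_A = 0.3, lambda_B = 0.3,
                        mu_d = 0.4, mu_A = 0.2, mu_B = 0.2,
                        gamma_A = 0.003, gamma_B = 0.0034,
                        eta_S_slope = -0.001) {
  vals <- list(eta = eta, eta_S = eta_S, eta_P = eta_P, w_S = w_S,
               w_P = w_P, gamma_S = gamma_S, gamma_P = gamma_P,
               lambda_P = lambda_P, lambda_A = lambda_A, lambda_B = lambda_B,
               mu_d = mu_d, mu_A = mu_A, mu_B = mu_B, gamma_A = gamma_A,
               gamma_B = gamma_B, eta_S_slope = eta_S_slope)
  for (k in setdiff(names(vals), "eta_S_slope")) {
    if (vals[[k]] < 0 || !is.finite(vals[[k]])) {
      abort(sprintf("rate `%s` must be finite and >= 0", k))
    }
  }
  if (eta_S_slope > 0) abort("`eta_S_slope` must be <= 0")
  structure(vals, class = "rate_params")
}

#' Mean-field ODE right-hand side
#'
#' Time derivatives of the average densities (n_S, n_P, n_A, n_B):
#' \deqn{\partial_t n_S = n_S \eta_S - n_S \eta_P + n_P w_S - n_S w_P - n_S \gamma_S}
#' \deqn{\partial_t n_P = n_S \eta + 2 n_S \eta_P + n_S w_P - n_P w_S -
#'   n_P \gamma_P - n_P(-\lambda_P + \mu_d + \mu_A + \mu_B)}
#' \deqn{\partial_t n_A = n_P(\lambda_A + \mu_d + 2\mu_A) - n_A \gamma_A}
#' \deqn{\partial_t n_B = n_P(\lambda_B + \mu_d + 2\mu_B) - n_B \gamma_B}
#'
#' @param state Named numeric vector or tibble row with `n_S`, `n_P`,
#'   `n_A`, `n_B` (non-negative).
#' @param params A [rate_params()] object.
#' @return A tibble with `dn_S`, `dn_P`, `dn_A`, `dn_B`.
#' @export
mf_ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "rate_params"))
  s <- as.list(state)
  if (any(unlist(s[c("n_S", "n_P", "n_A", "n_B")]) < 0)) {
    abort("densities must be non-negative")
  }
  p <- params
  with(s, tibble(
    dn_S = n_S * p$eta_S - n_S * p$eta_P + n_P * p$w_S - n_S * p$w_P -
      n_S * p$gamma_S,
    dn_P = n_S * p$eta + 2 * n_S * p$eta_P + n_S * p$w_P - n_P * p$w_S -
      n_P * p$gamma_P - n_P * (-p$lambda_P + p$mu_d + p$mu_A + p$mu_B),
    dn_A = n_P * (p$lambda_A + p$mu_d + 2 * p$mu_A) - n_A * p$gamma_A,
    dn_B = n_P * (p$lambda_B + p$mu_d + 2 * p$mu_B) - n_B * p$gamma_B
  ))
}

#' Closed-form steady state of the mean-field model
#'
#' The steady state fixes ratios, not absolute densities, so it is scaled
#' to a reference progenitor density `n_P_ref`:
#' \deqn{n_S^* = n_P^* (-w_S) / (\eta_S - \eta_P - \gamma_S - w_P)}
#' \deqn{n_A^* = n_P^* (\lambda_A + \mu_d + 2\mu_A) / \gamma_A}
#' \deqn{n_B^* = n_P^* (\lambda_B + \mu_d + 2\mu_B) / \gamma_B}
#' together with the transformation rate that balances the progenitor
#' equation,
#' \deqn{w_S^* = (\eta_S - \eta_P - w_P - \gamma_S)
#'   (-\gamma_P + \lambda_P - \mu_d - \mu_A - \mu_B) /
#'   (\eta + \eta_P + \eta_S - \gamma_S).}
#' Substituting the returned state into [mf_ode_rhs()] with `w_S = w_S*`
#' gives zero derivatives.
#'
#' @param params A [rate_params()] object.
#' @param n_P_ref Reference progenitor density (> 0).
#' @return A list with `state` (one-row tibble: n_S, n_P, n_A, n_B),
#'   `w_S_star`, and `params_star` (the input rates with `w_S` replaced by
#'   `w_S_star`).
#' @export
mf_steady_state <- function(params, n_P_ref = 1) {
  stopifnot(inherits(params, "rate_params"))
  p <- params
  den_S <- p$eta_S - p$eta_P - p$gamma_S - p$w_P
  den_w <- p$eta + p$eta_P + p$eta_S - p$gamma_S
  if (abs(den_S) < 1e-300 || abs(den_w) < 1e-300) {
    abort("degenerate parameters: zero denominator in the steady state")
  }
  if (p$gamma_A <= 0 || p$gamma_B <= 0) {
    abort("terminal death rates must be > 0 for a finite steady state")
  }
  w_S_star <- (p$eta_S - p$eta_P - p$w_P - p$gamma_S) *
    (-p$gamma_P + p$lambda_P - p$mu_d - p$mu_A - p$mu_B) / den_w
  n_S <- n_P_ref * (-w_S_star) / den_S
  state <- tibble(
    n_S = n_S, n_P = n_P_ref,
    n_A = n_P_ref * (p$lambda_A + p$mu_d + 2 * p$mu_A) / p$gamma_A,
    n_B = n_P_ref * (p$lambda_B + p$mu_d + 2 * p$mu_B) / p$gamma_B
  )
  params_star <- params
  params_star$w_S <- w_S_star
  list(state = state, w_S_star = w_S_star, params_star = params_star)
}

#' Parameter-regime conditions of the mean-field model
#'
#' Positivity of the steady state requires
#' `cond9`: eta_S - eta_P - gamma_S - w_P < 0, and positivity of `w_S*`
#' then requires exactly one of
#' `cond10`: eta + eta_P + eta_S < gamma_S and
#' lambda_P > gamma_P + mu_d + mu_A + mu_B, or
#' `cond11`: eta + eta_P + eta_S > gamma_S and
#' lambda_P < gamma_P + mu_d + mu_A + mu_B.
#' The modelled tissue operates under `cond9 & cond11`, the regime in
#' which progenitors have a limited capacity of proliferation.
#'
#' @param params A [rate_params()] object.
#' @return A one-row tibble with logical `cond9`, `cond10`, `cond11` and
#'   `model_regime` (= cond9 & cond11).
#' @export
mf_check_conditions <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  p <- params
  cond9 <- (p$eta_S - p$eta_P - p$gamma_S - p$w_P) < 0
  left <- p$eta + p$eta_P + p$eta_S
  prolif <- p$gamma_P + p$mu_d + p$mu_A + p$mu_B
  cond10 <- (left < p$gamma_S) && (p$lambda_P > prolif)
  cond11 <- (left > p$gamma_S) && (p$lambda_P < prolif)
  tibble(cond9 = cond9, cond10 = cond10, cond11 = cond11,
         model_regime = cond9 && cond11)
}

#' Stability of the mean-field fixed point
#'
#' Evaluates the reduced-Jacobian criteria at the steady state.  In the
#' (n_P, n) coordinates (n = n_S + n_P) the Jacobian determinant collapses
#' to `det(J') = zeta * n * eta_S'(n)` and the trace to
#' `tr(J') = -w_S* + (eta_S - eta_P - gamma_S - w_P) +
#' (lambda_P - gamma_P - mu_d - mu_A - mu_B)`, with
#' `zeta = -w_S* - gamma_P - w_P - eta + lambda_P - mu_d - mu_A - mu_B -
#' 2 eta_P`.  The terminal block is diagonal with eigenvalues
#' `-gamma_A`, `-gamma_B`.  The fixed point is stable iff `det > 0`,
#' `tr < 0` and both terminal rates are positive — which holds whenever
#' `eta_S'(n) < 0` and the regime conditions are satisfied.  A numerically
#' differentiated 4x4 Jacobian (with the density feedback embedded) and
#' its eigenvalues are returned alongside as a cross-check.
#'
#' @param params A [rate_params()] object (`w_S` is replaced by the
#'   balancing `w_S*` internally).
#' @param n_P_ref Scaling of the fixed point.
#' @return An object of class `mf_stability`: a list with `fixed_point`,
#'   `det_J`, `tr_J`, `conditions`, `terminal_eigenvalues`, `eigenvalues`
#'   (numeric 4x4 cross-check), and `stable`.
#' @export
mf_stability <- function(params, n_P_ref = 1) {
  stopifnot(inherits(params, "rate_params"))
  ss <- mf_steady_state(params, n_P_ref)
  p <- ss$params_star
  w_S <- ss$w_S_star
  zeta <- -w_S - p$gamma_P - p$w_P - p$eta + p$lambda_P - p$mu_d - p$mu_A -
    p$mu_B - 2 * p$eta_P
  n_star <- ss$state$n_S + ss$state$n_P
  det_J <- zeta * n_star * p$eta_S_slope
  tr_J <- (-w_S) + (p$eta_S - p$eta_P - p$gamma_S - p$w_P) +
    (p$lambda_P - p$gamma_P - p$mu_d - p$mu_A - p$mu_B)
  conds <- mf_check_conditions(p)
  stable <- det_J > 0 && tr_J < 0 && p$gamma_A > 0 && p$gamma_B > 0

  # residual sanity: the closed form really is a fixed point of the rhs
  resid <- max(abs(unlist(mf_ode_rhs(ss$state, p))))
  if (resid > 1e-8 * max(1, n_star)) {
    abort("steady state does not zero the ODE: degenerate parameters")
  }

  structure(list(
    fixed_point = ss$state, w_S_star = w_S, det_J = det_J, tr_J = tr_J,
    zeta = zeta, conditions = conds,
    terminal_eigenvalues = c(-p$gamma_A, -p$gamma_B),
    eigenvalues = mf_numeric_eigen(p, ss$state),
    residual = resid, stable = stable
  ), class = "mf_stability")
}

# Numeric 4x4 Jacobian of the rhs with eta_S(n) = eta_S + slope * (n - n*),
# central differences; the independent cross-check of the closed form.
mf_numeric_eigen <- function(p, state) {
  n_star <- state$n_S + state$n_P
  f <- function(z) {
    pp <- p
    pp$eta_S <- p$eta_S + p$eta_S_slope * ((z[1] + z[2]) - n_star)
    st <- list(n_S = z[1], n_P = z[2], n_A = z[3], n_B = z[4])
    unlist(mf_ode_rhs(st, pp))
  }
  z0 <- unlist(state[1, c("n_S", "n_P", "n_A", "n_B")])
  J <- matrix(0, 4, 4)
  hstep <- pmax(1e-6 * abs(z0), 1e-8)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- hstep[j]
    J[, j] <- (f(z0 + e) - f(pmax(z0 - e, 0))) / (z0 + e - pmax(z0 - e, 0))[j]
  }
  eigen(J, only.values = TRUE)$values
}

#' @export
print.mf_stability <- function(x, ...) {
  cat(sprintf("<mf_stability: det(J') = %.4g, tr(J') = %.4g, %s>\n",
              x$det_J, x$tr_J, if (x$stable) "stable" else "not stable"))
  print(x$fixed_point)
  invisible(x)
}

#' @method tidy mf_stability
#' @export
tidy.mf_stability <- function(x, ...) {
  tibble(term = c("det_J", "tr_J", "w_S_star", "eig_max_re_numeric"),
         value = c(x$det_J, x$tr_J, x$w_S_star, max(Re(x$eigenvalues))))
}

#' @method glance mf_stability
#' @export
glance.mf_stability <- function(x, ...) {
  tibble(stable = x$stable, det_J = x$det_J, tr_J = x$tr_J,
         cond9 = x$conditions$cond9, cond11 = x$conditions$cond11,
         eig_max_re = max(Re(x$eigenvalues)))
}

#' Integrate the mean-field ODE
#'
#' @param state0 Initial densities (named: n_S, n_P, n_A, n_B).
#' @param params A [rate_params()].
#' @param times Output time grid.
#' @param density_feedback If `TRUE`, `eta_S` varies with total dividing
#'   density as `eta_S + slope * (n - n_ref)` around `n_ref`.
#' @param n_ref Reference density for the feedback.
#' @return A tibble: time, n_S, n_P, n_A, n_B.
#' @export
mf_integrate <- function(state0, params, times, density_feedback = FALSE,
                         n_ref = NULL) {
  stopifnot(inherits(params, "rate_params"))
  rhs <- function(t, y, parms) {
    pp <- params
    if (density_feedback) {
      pp$eta_S <- max(0, params$eta_S +
                        params$eta_S_slope * ((y[1] + y[2]) - n_ref))
    }
    st <- list(n_S = y[1], n_P = y[2], n_A = y[3], n_B = y[4])
    list(unlist(mf_ode_rhs(st, pp)))
  }
  y0 <- unlist(state0[c("n_S", "n_P", "n_A", "n_B")])
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL)
  tibble(time = out[, 1], n_S = out[, 2], n_P = out[, 3], n_A = out[, 4],
         n_B = out[, 5])
}

#' Effective mean-field rates from simulation tallies
#'
#' Maximum-likelihood constant-rate estimates for each population-level
#' channel: event count divided by the integrated cell-time of the
#' compartment the channel acts on (S divisions and their daughter-fate
#' split, S/P transformation, deaths, and the six progenitor division
#' outcomes).  Standard errors are `sqrt(count) / exposure`.
#'
#' @param x A `dish_sim` or a list with `division_outcomes` (named counts
#'   S_SS, S_SP, S_PP, P_PP, P_PA, P_PB, P_AB, P_AA, P_BB),
#'   `event_counts` (channel tibble with a `count` column) and `exposure`
#'   (named S, P, A, B cell-time integrals).
#' @return A tibble: `rate` (mean-field symbol), `count`, `exposure`,
#'   `estimate`, `se`.
#' @export
measure_effective_rates <- function(x) {
  dv <- x$division_outcomes
  ec <- x$event_counts
  expo <- x$exposure
  if (any(expo[c("S", "P")] <= 0)) {
    warn("zero exposure time: rates for that compartment are undefined")
  }
  chan_count <- function(id) ec$count[ec$id == id]
  spec <- tibble(
    rate = c("eta_S", "eta", "eta_P", "w_P", "gamma_S",
             "lambda_P", "lambda_A", "lambda_B", "mu_d", "mu_A", "mu_B",
             "w_S", "gamma_P", "gamma_A", "gamma_B"),
    count = c(dv[["S_SS"]], dv[["S_SP"]], dv[["S_PP"]], chan_count(7),
              chan_count(6), dv[["P_PP"]], dv[["P_PA"]], dv[["P_PB"]],
              dv[["P_AB"]], dv[["P_AA"]], dv[["P_BB"]], chan_count(15),
              chan_count(14), chan_count(17), chan_count(18)),
    exposure = c(rep(expo[["S"]], 5), rep(expo[["P"]], 8),
                 expo[["A"]], expo[["B"]])
  )
  dplyr::mutate(spec,
                estimate = ifelse(.data$exposure > 0,
                                  .data$count / .data$exposure, NA_real_),
                se = ifelse(.data$exposure > 0,
                            sqrt(pmax(.data$count, 1)) / .data$exposure,
                            NA_real_))
}

#' Effective rates as a `rate_params` object
#'
#' Convenience bridge: packs [measure_effective_rates()] estimates into
#' [rate_params()] (slope taken from the density-feedback form of the
#' stem synthesis rate, scaled by the run's mean dividing census).
#'
#' @param sim A `dish_sim`.
#' @return A [rate_params()] object.
#' @export
effective_rate_params <- function(sim) {
  est <- measure_effective_rates(sim)
  g <- function(nm) {
    v <- est$estimate[est$rate == nm]
    if (!is.finite(v)) 0 else v
  }
  # slope of eta_S(n) via the iota_xs(n) anchor: d/dn [n0/(n0+n-n0)] at n0
  n0 <- max(mean(sim$trajectory$n_S + sim$trajectory$n_P), 1)
  slope <- -g("eta_S") / n0
  rate_params(eta = g("eta"), eta_S = g("eta_S"), eta_P = g("eta_P"),
              w_S = g("w_S"), w_P = g("w_P"), gamma_S = g("gamma_S"),
              gamma_P = g("gamma_P"), lambda_P = g("lambda_P"),
              lambda_A = g("lambda_A"), lambda_B = g("lambda_B"),
              mu_d = g("mu_d"), mu_A = g("mu_A"), mu_B = g("mu_B"),
              gamma_A = max(g("gamma_A"), 1e-6),
              gamma_B = max(g("gamma_B"), 1e-6),
              eta_S_slope = slope)
}
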