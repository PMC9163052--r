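# Mean-field population model: ODE terms, closed-form steady state,
# regime conditions, reduced-Jacobian stability and effective-rate
# recovery.

random_regime_params <- function() {
  # draw until the model regime (cond9 & cond11) holds with w_S* > 0
  repeat {
    p <- tryCatch(rate_params(
      eta = runif(1, 0.05, 0.5), eta_S = runif(1, 0.01, 0.3),
      eta_P = runif(1, 0.01, 0.5), w_S = runif(1, 0.05, 0.5),
      w_P = runif(1, 0.05, 0.5), gamma_S = runif(1, 0.01, 0.2),
      gamma_P = runif(1, 0.005, 0.1), lambda_P = runif(1, 0.05, 0.4),
      lambda_A = runif(1, 0.05, 0.4), lambda_B = runif(1, 0.05, 0.4),
      mu_d = runif(1, 0.1, 0.5), mu_A = runif(1, 0.1, 0.5),
      mu_B = runif(1, 0.1, 0.5), gamma_A = runif(1, 0.002, 0.05),
      gamma_B = runif(1, 0.002, 0.05),
      eta_S_slope = -runif(1, 1e-4, 1e-2)), error = function(e) NULL)
    if (is.null(p)) next
    cond <- mf_check_conditions(p)
    if (!cond$model_regime) next
    ss <- mf_steady_state(p)
    if (ss$w_S_star > 0 && ss$state$n_S > 0) return(p)
  }
}

test_that("the ODE right-hand side has the model's term structure", {
  p <- rate_params()
  z <- mf_ode_rhs(c(n_S = 0, n_P = 0, n_A = 0, n_B = 0), p)
  expect_true(all(unlist(z) == 0)) # linear system, no constant term
  # with no A-producing divisions, A decays at gamma_A
  p2 <- rate_params(lambda_A = 0, mu_d = 0, mu_A = 0)
  z2 <- mf_ode_rhs(c(n_S = 0, n_P = 5, n_A = 2, n_B = 0), p2)
  expect_equal(z2$dn_A, -p2$gamma_A * 2)
  expect_error(mf_ode_rhs(c(n_S = -1, n_P = 0, n_A = 0, n_B = 0), p),
               "non-negative")
})

test_that("closed-form steady state zeroes the ODE", {
  set.seed(21)
  for (k in 1:20) {
    p <- random_regime_params()
    ss <- mf_steady_state(p, n_P_ref = 3)
    resid <- unlist(mf_ode_rhs(ss$state, ss$params_star))
    expect_lt(max(abs(resid)), 1e-10)
  }
  # structural identities
  p <- rate_params(lambda_A = 0, mu_d = 0, mu_A = 0)
  expect_equal(mf_steady_state(p)$state$n_A, 0)
  p1 <- rate_params(gamma_A = 0.01)
  p2 <- rate_params(gamma_A = 0.02)
  expect_equal(mf_steady_state(p1)$state$n_A,
               2 * mf_steady_state(p2)$state$n_A)
})

test_that("forward integration converges to the closed-form fixed point", {
  set.seed(4)
  p <- random_regime_params()
  ss <- mf_steady_state(p, n_P_ref = 5)
  start <- as.list(unlist(ss$state) * c(1.1, 0.9, 1.1, 0.9)) # +-10%
  traj <- mf_integrate(start, ss$params_star,
                       times = seq(0, 4000, by = 50),
                       density_feedback = TRUE,
                       n_ref = ss$state$n_S + ss$state$n_P)
  fin <- traj[nrow(traj), ]
  expect_equal(fin$n_S, ss$state$n_S, tolerance = 0.02)
  expect_equal(fin$n_P, ss$state$n_P, tolerance = 0.02)
  expect_equal(fin$n_A, ss$state$n_A, tolerance = 0.02)
  expect_equal(fin$n_B, ss$state$n_B, tolerance = 0.02)
})

test_that("regime conditions behave at references and boundaries", {
  p <- rate_params(eta_S = 0.1, eta_P = 0.1, w_P = 0.3, gamma_S = 0.05)
  expect_true(mf_check_conditions(p)$cond9)
  # exact boundary: neither strict inequality holds
  pb <- rate_params(lambda_P = 0.5, gamma_P = 0.1, mu_d = 0.2, mu_A = 0.1,
                    mu_B = 0.1)
  cb <- mf_check_conditions(pb)
  expect_false(cb$cond10 || cb$cond11)
  # strict draws: exactly one of cond10/cond11
  set.seed(8)
  for (k in 1:200) {
    p <- rate_params(eta = runif(1, 0, 1), eta_S = runif(1, 0, 1),
                     eta_P = runif(1, 0, 1), gamma_S = runif(1, 0, 1),
                     lambda_P = runif(1, 0, 1), gamma_P = runif(1, 0, 1),
                     mu_d = runif(1, 0, 1), mu_A = runif(1, 0, 1),
                     mu_B = runif(1, 0, 1))
    cc <- mf_check_conditions(p)
    left <- p$eta + p$eta_P + p$eta_S
    if (abs(left - p$gamma_S) > 1e-9 &&
        abs(p$lambda_P - (p$gamma_P + p$mu_d + p$mu_A + p$mu_B)) > 1e-9) {
      expect_lte(cc$cond10 + cc$cond11, 1)
    }
  }
})

test_that("closed-form stability agrees with the numeric eigensolver", {
  # zero density feedback: determinant degenerates, not strictly stable
  p0 <- rate_params(eta_S_slope = 0)
  s0 <- mf_stability(p0)
  expect_equal(s0$det_J, 0)
  expect_false(s0$stable)
  expect_true(all(s0$terminal_eigenvalues < 0))
  set.seed(13)
  n_stable <- 0
  for (k in 1:100) {
    p <- random_regime_params()
    s <- mf_stability(p, n_P_ref = 2)
    closed <- s$det_J > 0 && s$tr_J < 0
    numeric_stable <- max(Re(s$eigenvalues)) < -1e-12
    expect_equal(closed, numeric_stable,
                 info = sprintf("draw %d: det=%g tr=%g eig=%g", k, s$det_J,
                                s$tr_J, max(Re(s$eigenvalues))))
    if (s$stable) n_stable <- n_stable + 1
  }
  # in the model regime with negative feedback the point is always stable
  expect_equal(n_stable, 100)
})

test_that("effective-rate recovery hits known constant rates within 3 SE", {
  truth <- list(eta_S = 0.08, eta = 0.1, eta_P = 0.12, w_P = 0.3,
                w_S = 0.16, gamma_S = 0.04, gamma_P = 0.02, lambda_P = 0.15,
                lambda_A = 0.2, lambda_B = 0.2, mu_d = 0.35, mu_A = 0.18,
                mu_B = 0.18, gamma_A = 0.05, gamma_B = 0.05)
  log <- synthetic_rate_log(truth, t_max = 60, seed = 42)
  est <- measure_effective_rates(log)
  for (i in seq_len(nrow(est))) {
    expect_lt(abs(est$estimate[i] - truth[[est$rate[i]]]), 3 * est$se[i] + 1e-9)
  }
  # absent events estimate to zero
  truth0 <- truth; truth0$mu_d <- 0
  log0 <- synthetic_rate_log(truth0, t_max = 20, seed = 3)
  est0 <- measure_effective_rates(log0)
  expect_equal(est0$estimate[est0$rate == "mu_d"], 0)
})

test_that("signal-free ensembles track the mean-field ODE", {
  # 24 replicates on a small dish, rates measured from the pooled event
  # tallies, ensemble means compared with the ODE at five checkpoints
  n_rep <- 24
  runs <- lapply(seq_len(n_rep), function(k) {
    d <- build_dish(pattern_spec("circle", 6, 3), seed = 100 + k)
    cfg <- sim_config(signals_on = FALSE, termination_divisions = 1e6,
                      max_time = 60, n_shots = 60)
    simulate_dish(d, cfg, seed = 200 + k)
  })
  pool <- list(
    division_outcomes = Reduce(`+`, lapply(runs, `[[`, "division_outcomes")),
    event_counts = {
      ec <- runs[[1]]$event_counts
      ec$count <- Reduce(`+`, lapply(runs, function(r) r$event_counts$count))
      ec
    },
    exposure = Reduce(`+`, lapply(runs, `[[`, "exposure")),
    trajectory = runs[[1]]$trajectory)
  p <- effective_rate_params(pool)
  d0 <- build_dish(pattern_spec("circle", 6, 3), seed = 100)
  cen <- dish_census(d0)
  times <- c(0, 15, 30, 45, 60)
  ode <- mf_integrate(list(n_S = cen$n_S, n_P = cen$n_P, n_A = cen$n_A,
                           n_B = cen$n_B), p, times)
  for (tt in times[-1]) {
    idx <- vapply(runs, function(r) which.min(abs(r$trajectory$time - tt)),
                  integer(1))
    o <- unlist(ode[ode$time == tt, -1])
    for (col in c("n_S", "n_P", "n_A", "n_B")) {
      v <- mapply(function(r, i) r$trajectory[[col]][i], runs, idx)
      se <- max(sd(v) / sqrt(n_rep), 0.3) # floor for near-discrete counts
      expect_lt(abs(mean(v) - o[[paste0(col)]]), 3 * se,
                label = sprintf("%s at t=%g (z=%.2f)", col, tt,
                                (mean(v) - o[[col]]) / se))
    }
  }
})

test_that("rates measured from a simulation satisfy the model regime", {
  sim <- tiny_run()
  p <- effective_rate_params(sim)
  cond <- mf_check_conditions(p)
  expect_true(cond$cond9)
  expect_true(cond$cond11)
  expect_true(mf_stability(p, n_P_ref = 2)$stable)
})
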