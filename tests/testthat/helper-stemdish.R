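# Shared fixtures: small dishes, cached short runs, and a tiny well-mixed
# constant-rate event generator used as the independent oracle for
# effective-rate recovery.

run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (!exists(key, envir = run_cache)) assign(key, fn(), envir = run_cache)
  get(key, envir = run_cache)
}

tiny_dish <- function(radius = 8, inner = 4, seed = 11) {
  build_dish(pattern_spec("circle", radius, inner), seed = seed)
}

# A short signal-off run on a small dish, reused across tests.
tiny_run <- function() {
  cached_run("tiny_run", function() {
    d <- tiny_dish()
    cfg <- sim_config(signals_on = FALSE, termination_divisions = 3,
                      n_shots = 50, log_max = 2e4)
    simulate_dish(d, cfg, seed = 7)
  })
}

# Well-mixed constant-rate birth/death/transform generator: the
# independent oracle for measure_effective_rates().  Simulates the
# population-level channels exactly (no space, no switches) and returns
# tallies in the same shape as the engine's.
synthetic_rate_log <- function(rates, n0 = c(S = 40, P = 80, A = 50, B = 50),
                               t_max = 30, seed = 1) {
  set.seed(seed)
  n <- n0
  t <- 0
  counts <- c(S_SS = 0, S_SP = 0, S_PP = 0, P_PP = 0, P_PA = 0, P_PB = 0,
              P_AB = 0, P_AA = 0, P_BB = 0, S_death = 0, P_death = 0,
              A_death = 0, B_death = 0, S_to_P = 0, P_to_S = 0)
  expo <- c(S = 0, P = 0, A = 0, B = 0)
  ch <- tibble::tibble(
    name = names(counts),
    rate = c(rates$eta_S, rates$eta, rates$eta_P, rates$lambda_P,
             rates$lambda_A, rates$lambda_B, rates$mu_d, rates$mu_A,
             rates$mu_B, rates$gamma_S, rates$gamma_P, rates$gamma_A,
             rates$gamma_B, rates$w_P, rates$w_S),
    pop = c("S", "S", "S", "P", "P", "P", "P", "P", "P", "S", "P", "A",
            "B", "S", "P"))
  repeat {
    prop <- ch$rate * n[ch$pop]
    tot <- sum(prop)
    if (tot <= 0) break
    dt <- rexp(1, tot)
    if (t + dt > t_max) {
      expo <- expo + n * (t_max - t)
      break
    }
    expo <- expo + n * dt
    t <- t + dt
    ev <- ch$name[sample.int(nrow(ch), 1, prob = prop)]
    counts[ev] <- counts[ev] + 1
    n <- n + switch(ev,
      S_SS = c(1, 0, 0, 0), S_SP = c(0, 1, 0, 0), S_PP = c(-1, 2, 0, 0),
      P_PP = c(0, 1, 0, 0), P_PA = c(0, 0, 1, 0), P_PB = c(0, 0, 0, 1),
      P_AB = c(0, -1, 1, 1), P_AA = c(0, -1, 2, 0), P_BB = c(0, -1, 0, 2),
      S_death = c(-1, 0, 0, 0), P_death = c(0, -1, 0, 0),
      A_death = c(0, 0, -1, 0), B_death = c(0, 0, 0, -1),
      S_to_P = c(-1, 1, 0, 0), P_to_S = c(1, -1, 0, 0))
  }
  ec <- reaction_channels()
  ec$count <- 0
  ec$count[ec$id == 6] <- counts[["S_death"]]
  ec$count[ec$id == 7] <- counts[["S_to_P"]]
  ec$count[ec$id == 14] <- counts[["P_death"]]
  ec$count[ec$id == 15] <- counts[["P_to_S"]]
  ec$count[ec$id == 17] <- counts[["A_death"]]
  ec$count[ec$id == 18] <- counts[["B_death"]]
  list(division_outcomes = counts[1:9], event_counts = ec, exposure = expo)
}
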