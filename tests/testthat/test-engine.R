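# Stochastic engine: propensity table, event drawing, single-event
# operations, conservation laws and whole-run behaviour.

test_that("propensity table matches hand-computed reference cases", {
  # empty dish: nothing can happen
  lm <- matrix(2L, 5, 5)
  d0 <- build_dish(pattern_spec("labelfile", label_matrix = lm,
                                dividing_fraction_S = 0,
                                dividing_fraction_P = 0, signal_init = 0),
                   seed = 1)
  d0$occ[] <- 0L
  expect_equal(total_propensity(d0)$total, 0)

  # one A cell, no signal molecules: exactly A-death and S1-production
  dA <- d0
  dA$occ[13] <- 3L
  pr <- total_propensity(dA)
  expect_setequal(pr$table$channel, c(17L, 19L))
  expect_equal(pr$channel_totals[["17"]], 0.003)
  expect_equal(pr$channel_totals[["19"]], 220)

  # one S cell with zero determinants at the calibration density:
  # synthesis at 85/100, division at 56.4
  dS <- d0
  dS$occ[13] <- 1L
  prS <- total_propensity(dS)
  expect_equal(prS$channel_totals[["1"]], 85)
  expect_equal(prS$channel_totals[["3"]], 100)
  expect_equal(prS$channel_totals[["5"]], 56.4)
  expect_equal(prS$channel_totals[["6"]], 0.0423)
  expect_equal(prS$channel_totals[["7"]], 0.329)
})

test_that("reference propensities equal the engine's initial totals", {
  d <- build_dish(pattern_spec("circle", 8, 4), seed = 19)
  for (on in c(TRUE, FALSE)) {
    cfg <- sim_config(signals_on = on, termination_divisions = 2,
                      n_shots = 5, max_events = 10)
    sim <- simulate_dish(d, cfg, seed = 1)
    dref <- d
    if (!on) { dref$s1[] <- 0L; dref$s2[] <- 0L }
    pr <- total_propensity(dref, cfg)
    expect_equal(unname(pr$channel_totals),
                 as.numeric(sim$initial_propensity$channel_totals),
                 tolerance = 1e-10)
    expect_equal(pr$total, sim$initial_propensity$total, tolerance = 1e-10)
  }
})

test_that("event drawing follows the propensities", {
  lm <- matrix(2L, 3, 3)
  d <- build_dish(pattern_spec("labelfile", label_matrix = lm,
                               dividing_fraction_S = 0,
                               dividing_fraction_P = 0, signal_init = 0),
                  seed = 1)
  d$occ[] <- 0L
  d$s1[5] <- 2L # decay propensity 1.0 at the centre
  d$s2[5] <- 6L # decay propensity 3.0
  cfg <- sim_config(signals_on = FALSE) # diffusion off: two channels only
  pr <- total_propensity(d, cfg)
  expect_equal(pr$total, 4)
  set.seed(77)
  draws <- replicate(10000, draw_event(pr)$channel)
  tab <- table(draws)
  expect_gt(chisq.test(tab, p = c(0.25, 0.75))$p.value, 0.01)
  set.seed(78)
  waits <- replicate(10000, draw_event(pr)$wait)
  expect_equal(mean(waits), 1 / 4, tolerance = 0.05)
  # single active channel is always selected
  d1 <- d; d1$s2[5] <- 0L
  pr1 <- total_propensity(d1, cfg)
  expect_true(all(replicate(50, draw_event(pr1)$channel) == 20L))
})

test_that("division conserves determinants and splits binomially", {
  sq <- build_dish(pattern_spec("square", 5, 2, dividing_fraction_S = 0,
                                dividing_fraction_P = 0, signal_init = 0),
                   seed = 1)
  sq$occ[] <- 0L
  set.seed(12)
  halves <- integer(0)
  for (k in 1:200) {
    d <- sq
    d$occ[13] <- 2L
    d$x[13] <- 80L; d$y[13] <- 80L; d$div[13] <- 3L
    out <- divide_cell(d, c(3, 3))
    d2 <- out$dish
    expect_equal(sum(d2$occ > 0L), 2L)
    if (all(out$fates == "P")) {
      # both daughters keep their binomial shares: partition conserved
      expect_equal(sum(d2$x), 80L)
      expect_equal(sum(d2$y), 80L)
      halves <- c(halves, d2$x[13])
    }
    # surviving P daughters carry the incremented counter
    expect_true(all(d2$div[d2$occ == 2L] == 4L))
  }
  # a balanced mother renews P + P often (the rest differentiate: the
  # daughters' binomial spread straddles the basin boundary)
  expect_gt(length(halves), 40)
  expect_equal(mean(halves), 40, tolerance = 0.05) # Binomial(80, 1/2)
  # a zero-determinant P mother yields two zero daughters (the origin
  # flows to the balanced attractor, so both stay P and keep their split)
  d <- sq; d$occ[13] <- 2L
  out0 <- divide_cell(d, c(3, 3))
  expect_true(all(out0$fates == "P"))
  expect_true(all(out0$dish$x == 0L))
})

test_that("S mothers deep in the S basin mostly renew symmetrically", {
  sq <- build_dish(pattern_spec("square", 5, 2, dividing_fraction_S = 0,
                                dividing_fraction_P = 0, signal_init = 0),
                   seed = 1)
  sq$occ[] <- 0L
  set.seed(3)
  outcomes <- replicate(300, {
    d <- sq
    d$occ[13] <- 1L
    d$x[13] <- 140L; d$y[13] <- 5L
    paste(sort(as.character(divide_cell(d, c(3, 3))$fates)), collapse = "")
  })
  expect_gt(mean(outcomes == "SS"), 0.9)
  expect_equal(sum(outcomes == "PP"), 0)
})

test_that("transformation flips fate in place and resamples the switch", {
  sq <- build_dish(pattern_spec("square", 5, 2, dividing_fraction_S = 0,
                                dividing_fraction_P = 0, signal_init = 0),
                   seed = 1)
  sq$occ[] <- 0L
  sq$occ[13] <- 1L
  sq$x[13] <- 85L; sq$y[13] <- 7L; sq$div[13] <- 2L
  set.seed(2)
  d2 <- transform_cell(sq, c(3, 3))
  expect_equal(d2$occ[13], 2L)
  expect_equal(sum(d2$occ > 0L), 1L)
  expect_equal(d2$div[13], 2L) # counter travels with the lineage
  expect_equal(as.character(classify_fate(d2$x[13], d2$y[13], "progenitor")),
               "P")
  d3 <- transform_cell(d2, c(3, 3))
  expect_equal(d3$occ[13], 1L)
  expect_error(transform_cell(d0 <- {sq$occ[13] <- 3L; sq}, c(3, 3)),
               "transform")
})

test_that("diffusion moves single molecules and conserves their number", {
  sq <- build_dish(pattern_spec("square", 5, 2, dividing_fraction_S = 0,
                                dividing_fraction_P = 0, signal_init = 0),
                   seed = 1)
  sq$occ[] <- 0L
  sq$s1[13] <- 1L
  set.seed(1)
  d2 <- diffuse_signal(sq, c(3, 3), species = 1)
  expect_equal(sum(d2$s1), 1L)
  expect_equal(d2$s1[13], 0L)
  nb <- neighbors(sq, c(3, 3), "orthogonal4")
  expect_equal(sum(d2$s1[nb]), 1L)
})

test_that("free diffusion spreads with mean-square displacement ~ D t", {
  # mass-action variant: per-molecule hop rate D/h^2 to a uniform
  # orthogonal neighbour gives MSD slope D (h = 1)
  lm <- matrix(2L, 41, 41)
  msd_at <- function(t_max, seed) {
    d <- build_dish(pattern_spec("labelfile", label_matrix = lm,
                                 dividing_fraction_S = 0,
                                 dividing_fraction_P = 0, signal_init = 0),
                    seed = 1)
    d$occ[] <- 0L
    d$s1[21, 21] <- 800L
    cfg <- sim_config(alpha_s1 = 1e-12, alpha_s2 = 1e-12, k_sig = 1e-12,
                      diffusion_scales_with_count = TRUE, max_time = t_max,
                      termination_divisions = 2, n_shots = 2)
    sim <- simulate_dish(d, cfg, seed = seed)
    s1 <- sim$final$s1
    r2 <- outer((seq_len(41) - 21)^2, (seq_len(41) - 21)^2, `+`)
    sum(s1 * r2) / sum(s1)
  }
  t1 <- 0.02; t2 <- 0.05
  m1 <- msd_at(t1, 5); m2 <- msd_at(t2, 6)
  slope <- (m2 - m1) / (t2 - t1)
  expect_equal(slope, 110, tolerance = 0.2)
  expect_equal(m1 / t1, 110, tolerance = 0.2)
})

test_that("runs are reproducible and respect structural invariants", {
  d <- tiny_dish(6, 3, seed = 2)
  cfg <- sim_config(signals_on = FALSE, termination_divisions = 2,
                    n_shots = 20, log_max = 1e4)
  a <- simulate_dish(d, cfg, seed = 31)
  b <- simulate_dish(d, cfg, seed = 31)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final$occ, b$final$occ)
  expect_identical(a$event_counts$count, b$event_counts$count)
  # occupancy and count invariants on the final state
  expect_true(all(a$final$occ[!a$final$valid] == 0L))
  expect_true(all(a$final$x >= 0) && all(a$final$y >= 0))
  expect_true(all(a$final$s1 >= 0) && all(a$final$s2 >= 0))
  # event log times strictly increase
  expect_true(all(diff(a$event_log$time) > 0))
})

test_that("with movement and division disabled the census never grows", {
  d <- tiny_dish(6, 3, seed = 8)
  cfg <- sim_config(signals_on = FALSE, r_s = 0, r_p = 0, m_s = 0, m_p = 0,
                    termination_divisions = 2, n_shots = 40, max_time = 150)
  sim <- simulate_dish(d, cfg, seed = 4)
  tot <- sim$trajectory$n_S + sim$trajectory$n_P + sim$trajectory$n_A +
    sim$trajectory$n_B
  expect_true(all(diff(tot) <= 0))
})

test_that("a dish with no cells and no activity terminates cleanly", {
  lm <- matrix(2L, 4, 4)
  d <- build_dish(pattern_spec("labelfile", label_matrix = lm,
                               dividing_fraction_S = 0,
                               dividing_fraction_P = 0, signal_init = 0),
                  seed = 1)
  d$occ[] <- 0L
  cfg <- sim_config(termination_divisions = 2, n_shots = 3)
  sim <- simulate_dish(d, cfg, seed = 1)
  expect_equal(sim$status, "exhausted")
  expect_equal(sim$n_events, 0)
})

test_that("event-count ratios track constant-rate propensity ratios", {
  # S death (0.0423) vs S transformation (0.329) share the S exposure
  sim <- tiny_run()
  ec <- sim$event_counts
  n_death <- ec$count[ec$id == 6]
  n_trans <- ec$count[ec$id == 7]
  expect_gt(n_trans, 0)
  ratio <- n_death / n_trans
  se <- ratio * sqrt(1 / n_death + 1 / n_trans)
  expect_lt(abs(ratio - 0.0423 / 0.329), 3 * se + 0.05)
})

test_that("injuries fire at their trigger and empty the region", {
  d <- tiny_dish(8, 4, seed = 6)
  inj <- injury_spec("circle", center = c(9, 9), size = 5, trigger = 1.5)
  cfg <- sim_config(signals_on = FALSE, termination_divisions = 2,
                    n_shots = 60)
  sim <- simulate_dish(d, cfg, injuries = inj, seed = 9)
  expect_true(sim$injury_fired[1])
  tr <- sim$trajectory
  tot <- tr$n_S + tr$n_P + tr$n_A + tr$n_B
  k <- which(tr$mean_div >= 1.5)[1]
  expect_lt(min(tot[k:length(tot)]), 0.6 * max(tot[1:k])) # visible crash
  expect_equal(sim$status, "divisions")
})
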