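# Whole-run simulation wrapper around the compiled Gillespie engine, and
# broom-style accessors for the result object.

#' Simulate a dish
#'
#' Runs the exact stochastic simulation (direct-method Gillespie over the
#' 24 reaction channels) from an initialised dish until the living
#' progenitor cells have gone through `termination_divisions` divisions on
#' average (or a safety cap fires).  `n_shots` occupancy snapshots, evenly
#' spaced over the simulated time span, are kept for pattern scoring, along
#' with the abundance series of the four cell types.
#'
#' @param dish A [build_dish()] dish.
#' @param config A [sim_config()].
#' @param injuries A single [injury_spec()] or a list of them; each fires
#'   once when the mean progenitor division count reaches its trigger.
#' @param seed Integer seed; a seeded run is bit-reproducible.
#' @return An object of class `dish_sim` with components:
#'   `trajectory` (tibble: shot, time, n_S, n_P, n_A, n_B, mean_div),
#'   `snapshots` (list of occupancy matrices aligned with `trajectory`),
#'   `initial` / `final` (dishes), `status`, `t_end`, `n_events`,
#'   `event_counts` (tibble by channel), `division_outcomes`,
#'   `exposure`, `event_log` (tibble, when `log_max > 0`), and
#'   `initial_propensity` (total and per-channel, for cross-checks).
#' @export
simulate_dish <- function(dish, config = sim_config(), injuries = NULL,
                          seed = NULL) {
  stopifnot(inherits(dish, "dish"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!config$signals_on) {
    dish$s1[] <- 0L
    dish$s2[] <- 0L
  }
  if (inherits(injuries, "injury_spec")) injuries <- list(injuries)
  inj <- lapply(injuries, function(sp) {
    list(trigger = sp$trigger,
         meshes = as.integer(which(injury_region(dish, sp)) - 1L))
  })
  d <- list(height = dish$height, width = dish$width,
            valid = as.integer(dish$valid), occ = as.integer(dish$occ),
            x = as.integer(dish$x), y = as.integer(dish$y),
            div = as.integer(dish$div), s1 = as.integer(dish$s1),
            s2 = as.integer(dish$s2))
  res <- cpp_simulate(d, unclass(config), inj)

  # thin the adaptive snapshot ring to n_shots evenly spaced times
  times <- res$snap_times
  t_end <- res$t_end
  n_shots <- config$n_shots
  targets <- t_end * seq_len(n_shots) / n_shots
  sel <- vapply(targets, function(tt) {
    which.max(times[times <= tt + 1e-12]) # last stored time before target
  }, integer(1))
  sel[length(sel)] <- length(times) # final shot is the final state
  H <- dish$height; W <- dish$width
  snaps <- lapply(sel, function(k) matrix(res$snapshots[, k], H, W))
  counts <- as_tibble(res$snap_counts)[sel, ]
  trajectory <- tibble(shot = seq_len(n_shots), time = targets,
                       n_S = counts$n_S, n_P = counts$n_P,
                       n_A = counts$n_A, n_B = counts$n_B,
                       mean_div = counts$mean_div)

  final <- dish
  final$occ <- matrix(res$final$occ, H, W)
  final$x <- matrix(res$final$x, H, W)
  final$y <- matrix(res$final$y, H, W)
  final$div <- matrix(res$final$div, H, W)
  final$s1 <- matrix(res$final$s1, H, W)
  final$s2 <- matrix(res$final$s2, H, W)

  structure(list(
    trajectory = trajectory,
    snapshots = snaps,
    initial = dish,
    final = final,
    status = res$status,
    t_end = t_end,
    n_events = res$n_events,
    mean_divisions = res$mean_divisions,
    event_counts = dplyr::mutate(reaction_channels(),
                                 count = as.numeric(res$event_counts)),
    division_outcomes = res$division_outcomes,
    exposure = res$exposure,
    event_log = as_tibble(res$event_log),
    initial_propensity = list(total = res$initial_total,
                              channel_totals = res$initial_channel_totals),
    injury_fired = res$injury_fired,
    config = config,
    seed = seed
  ), class = "dish_sim")
}

#' @export
print.dish_sim <- function(x, ...) {
  cat(sprintf(
    "<dish_sim: %s after %.4g time units, %.3g events, mean P divisions %.2f>\n",
    x$status, x$t_end, x$n_events, x$mean_divisions))
  print(tail(x$trajectory, 3))
  invisible(x)
}

#' Tidy the abundance trajectory of a simulation
#'
#' @param x A `dish_sim`.
#' @param ... Unused.
#' @return A long tibble: `shot`, `time`, `cell_type`, `count`.
#' @method tidy dish_sim
#' @export
tidy.dish_sim <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, cols = c("n_S", "n_P", "n_A", "n_B"),
                      names_to = "cell_type", names_prefix = "n_",
                      values_to = "count")
}

#' One-row summary of a simulation
#'
#' @inheritParams tidy.dish_sim
#' @return A one-row tibble: status, end time, events, mean divisions and
#'   the final census.
#' @method glance dish_sim
#' @export
glance.dish_sim <- function(x, ...) {
  cens <- dish_census(x$final)
  tibble(status = x$status, t_end = x$t_end, n_events = x$n_events,
         mean_divisions = x$mean_divisions, n_S = cens$n_S, n_P = cens$n_P,
         n_A = cens$n_A, n_B = cens$n_B)
}

#' Export the abundance series of a run
#'
#' @param sim A `dish_sim`.
#' @param path Output file (tab-separated: time, n_S, n_P, n_A, n_B).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  write.table(sim$trajectory[, c("time", "n_S", "n_P", "n_A", "n_B")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
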