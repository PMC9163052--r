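# Reference (pure-R) propensity evaluation and single-event operations.
# These mirror the compiled engine channel by channel; the engine is the
# fast path for whole runs, the functions here are the inspectable path
# used for unit tests and for stepping through single events.

basin_cache <- new.env(parent = emptyenv())

cached_map <- function(system, params = NULL) {
  if (is.null(params)) params <- default_params_for(system)
  key <- paste0(system, ":", paste(unlist(unclass(params)), collapse = ","))
  if (!exists(key, envir = basin_cache)) {
    assign(key, basin_map(system, params), envir = basin_cache)
  }
  get(key, envir = basin_cache)
}

dish_eps <- function(dish, m, cfg) {
  if (!cfg$signals_on) return(c(0, 0))
  sep <- signal_effect_params(cfg$eps_a, cfg$eps_b)
  c(signal_effect(dish$s1[m], sep), signal_effect(dish$s2[m], sep))
}

has_empty8 <- function(dish, m) {
  H <- dish$height
  r <- (m - 1) %% H + 1; c <- (m - 1) %/% H + 1
  nb <- neighbors(dish, c(r, c), "full8")
  any(dish$occ[nb] == 0L)
}

#' Total propensity of a dish
#'
#' Evaluates all 24 reaction channels over every cell and mesh of the dish
#' and returns the per-site table and channel totals.  This is the
#' reference implementation the compiled engine is checked against: both
#' follow [reaction_channels()] row by row, including division gating (a
#' dividing cell with no empty 8-neighbour contributes zero division
#' propensity), the density-dependent stem synthesis rate, the local
#' signal-effect increments of the progenitor production channels, and the
#' per-mesh diffusion propensity `D/h^2` for meshes holding at least one
#' molecule.
#'
#' @param dish A dish.
#' @param config A [sim_config()].
#' @return A list with `total`, `channel_totals` (named length-24 vector)
#'   and `table` (tibble: `channel`, `row`, `col`, `propensity`; nonzero
#'   entries only).
#' @export
total_propensity <- function(dish, config = sim_config()) {
  cfg <- config
  H <- dish$height
  n_div <- sum(dish$occ %in% c(1L, 2L))
  n0 <- if (cfg$iota_n0 > 0) cfg$iota_n0 else max(n_div, 1)
  iota_now <- iota_xs_of_n(max(n_div, 0), cfg$iota_xs, n0)
  bs <- cfg$beta_s^cfg$hill_s
  bp <- cfg$beta_p^cfg$hill_p
  bg <- cfg$beta_sig^cfg$hill_sig
  any_empty <- any(dish$valid & dish$occ == 0L)

  rows <- list()
  add <- function(channel, m, p) {
    if (p > 0) {
      rows[[length(rows) + 1]] <<- tibble(
        channel = channel, row = (m - 1) %% H + 1, col = (m - 1) %/% H + 1,
        propensity = p)
    }
  }
  for (m in which(dish$valid)) {
    o <- dish$occ[m]
    x <- dish$x[m]; y <- dish$y[m]
    if (o == 1L) {
      add(1L, m, iota_now * bs / (bs + y^cfg$hill_s))
      add(2L, m, cfg$gamma_det_s * x)
      add(3L, m, cfg$iota_ys * bs / (bs + x^cfg$hill_s))
      add(4L, m, cfg$gamma_det_s * y)
      add(5L, m, if (has_empty8(dish, m)) cfg$r_s else 0)
      add(6L, m, cfg$gamma_s)
      add(7L, m, cfg$w_p)
      add(8L, m, if (any_empty) cfg$m_s else 0)
    } else if (o == 2L) {
      eps <- dish_eps(dish, m, cfg)
      add(9L, m, (cfg$alpha_xp + eps[1]) * x^cfg$hill_p / (bp + x^cfg$hill_p) +
                   cfg$iota_xp * bp / (bp + y^cfg$hill_p))
      add(10L, m, cfg$gamma_det_p * x)
      add(11L, m, (cfg$alpha_yp + eps[2]) * y^cfg$hill_p / (bp + y^cfg$hill_p) +
                    cfg$iota_yp * bp / (bp + x^cfg$hill_p))
      add(12L, m, cfg$gamma_det_p * y)
      add(13L, m, if (has_empty8(dish, m)) cfg$r_p else 0)
      add(14L, m, cfg$gamma_p)
      add(15L, m, cfg$w_s)
      add(16L, m, if (any_empty) cfg$m_p else 0)
    } else if (o == 3L) {
      add(17L, m, cfg$gamma_A)
      if (cfg$signals_on) add(19L, m, cfg$alpha_s1 * bg / (bg + dish$s2[m]^cfg$hill_sig))
    } else if (o == 4L) {
      add(18L, m, cfg$gamma_B)
      if (cfg$signals_on) add(21L, m, cfg$alpha_s2 * bg / (bg + dish$s1[m]^cfg$hill_sig))
    }
    add(20L, m, cfg$k_sig * dish$s1[m])
    add(22L, m, cfg$k_sig * dish$s2[m])
    if (cfg$signals_on && dish$s1[m] > 0) {
      add(23L, m, if (cfg$diffusion_scales_with_count)
        dish$s1[m] * cfg$D / cfg$h^2 else cfg$D / cfg$h^2)
    }
    if (cfg$signals_on && dish$s2[m] > 0) {
      add(24L, m, if (cfg$diffusion_scales_with_count)
        dish$s2[m] * cfg$D / cfg$h^2 else cfg$D / cfg$h^2)
    }
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(channel = integer(), row = integer(), col = integer(),
           propensity = double())
  totals <- setNames(numeric(24), as.character(1:24))
  if (nrow(tab)) {
    agg <- tapply(tab$propensity, tab$channel, sum)
    totals[names(agg)] <- agg
  }
  if (any(totals < 0)) abort("negative propensity: internal invariant violated")
  list(total = sum(totals), channel_totals = totals, table = tab)
}

#' Draw the next stochastic event
#'
#' Standard direct-method draw: waiting time exponential in the total
#' propensity, event identity proportional to the per-site propensities.
#'
#' @param prop Output of [total_propensity()].
#' @return A list with `wait` and the selected `channel`, `row`, `col`.
#' @export
draw_event <- function(prop) {
  if (prop$total <= 0) {
    abort("total propensity is zero: the simulation is dead-locked")
  }
  wait <- rexp(1, prop$total)
  i <- sample.int(nrow(prop$table), 1, prob = prop$table$propensity)
  list(wait = wait, channel = prop$table$channel[i],
       row = prop$table$row[i], col = prop$table$col[i])
}

#' Execute a division event
#'
#' Splits the mother's determinant counts binomially (p = 1/2,
#' independently for X and Y) between two daughters; one daughter keeps
#' the mother's mesh, the other takes a uniformly chosen empty
#' 8-neighbour.  Each daughter's fate is the basin classification of its
#' own counts (stem switch for S mothers, progenitor switch with the local
#' signal effect for P mothers); a daughter that changes switch system has
#' its determinants re-sampled from its new basin.  P-mother divisions
#' increment the surviving P daughters' division counters.
#'
#' @param dish A dish.
#' @param mesh `c(row, col)` of an S or P cell with at least one empty
#'   8-neighbour.
#' @param config A [sim_config()].
#' @return A list with the updated `dish`, the two daughter `fates`
#'   (factor) and the `placed` mesh of the second daughter.
#' @export
divide_cell <- function(dish, mesh, config = sim_config()) {
  m <- mesh_index(dish, mesh)
  o <- dish$occ[m]
  if (!o %in% c(1L, 2L)) abort("occupant is not a dividing cell")
  nb <- neighbors(dish, mesh, "full8")
  nb <- nb[dish$occ[nb] == 0L, , drop = FALSE]
  if (nrow(nb) == 0) abort("no empty neighbour: division is gated")
  pick <- nb[sample.int(nrow(nb), 1), ]
  e <- (pick[2] - 1) * dish$height + pick[1]
  x1 <- rbinom(1, dish$x[m], 0.5); x2 <- dish$x[m] - x1
  y1 <- rbinom(1, dish$y[m], 0.5); y2 <- dish$y[m] - y1
  divm <- dish$div[m]
  meshes <- c(m, e); xs <- c(x1, x2); ys <- c(y1, y2)
  fates <- character(2)
  for (d in 1:2) {
    mm <- meshes[d]
    if (o == 1L) {
      sp <- bistable_params(iota_x = config$iota_xs, iota_y = config$iota_ys,
                            beta = config$beta_s, hill_n = config$hill_s,
                            gamma = config$gamma_det_s)
      sm <- cached_map("stem", sp)
      lab <- fate_labels[sm$grid[map_idx(sm, xs[d]), map_idx(sm, ys[d])]]
      if (lab == "P") {
        st <- sample_from_basin(1, "P", map = prog_map_for(dish, mm, config, need_P = TRUE))
        xs[d] <- st$x; ys[d] <- st$y
      }
      dish$div[mm] <- divm
    } else {
      eps <- dish_eps(dish, mm, config)
      pm <- prog_map_for(dish, mm, config)
      lab <- fate_labels[pm$grid[map_idx(pm, xs[d]), map_idx(pm, ys[d])]]
      dish$div[mm] <- if (lab == "P") divm + 1L else 0L
      if (lab %in% c("A", "B")) { xs[d] <- 0L; ys[d] <- 0L }
    }
    fates[d] <- lab
    dish$occ[mm] <- occ_codes[[lab]]
    dish$x[mm] <- as.integer(xs[d]); dish$y[mm] <- as.integer(ys[d])
  }
  list(dish = dish, fates = factor(fates, levels = fate_labels),
       placed = pick)
}

map_idx <- function(map, v) {
  min(round(v / (map$xs[2] - map$xs[1])) + 1, length(map$xs))
}

prog_map_for <- function(dish, m, cfg, need_P = FALSE) {
  eps <- dish_eps(dish, m, cfg)
  pars <- function(e1, e2) {
    tristable_params(alpha_x = cfg$alpha_xp, alpha_y = cfg$alpha_yp,
                     iota_x = cfg$iota_xp, iota_y = cfg$iota_yp,
                     beta = cfg$beta_p, hill_n = cfg$hill_p,
                     gamma = cfg$gamma_det_p, eps_x = e1, eps_y = e2)
  }
  map <- cached_map("progenitor", pars(eps[1], eps[2]))
  if (need_P && !any(map$grid == 2L)) {
    # strong one-sided signalling can delete the balanced attractor;
    # resampling then falls back to the signal-free basin
    map <- cached_map("progenitor", pars(0, 0))
  }
  map
}

mesh_index <- function(dish, mesh) {
  (mesh[2] - 1) * dish$height + mesh[1]
}

#' Execute a transformation event
#'
#' Flips the occupant's fate between S and P and re-samples its
#' determinants from the matching basin of the target switch system.  The
#' division counter travels with the lineage (transformation does not
#' reset it; see the methods vignette).
#'
#' @inheritParams divide_cell
#' @return The updated dish.
#' @export
transform_cell <- function(dish, mesh, config = sim_config()) {
  m <- mesh_index(dish, mesh)
  o <- dish$occ[m]
  if (!o %in% c(1L, 2L)) abort("only S and P cells transform")
  if (o == 1L) {
    st <- sample_from_basin(1, "P", map = prog_map_for(dish, m, config, need_P = TRUE))
    dish$occ[m] <- occ_codes[["P"]]
  } else {
    st <- sample_from_basin(1, "S", map = cached_map("stem"))
    dish$occ[m] <- occ_codes[["S"]]
  }
  dish$x[m] <- st$x; dish$y[m] <- st$y
  dish
}

#' Execute a signal diffusion event
#'
#' Moves one molecule of the given species from `mesh` to an orthogonal
#' in-dish neighbour (uniform by default; the `"weighted"` rule selects
#' neighbours with probability proportional to `1 + `their count).  Total
#' molecule number is conserved; a mesh with no valid neighbour yields a
#' no-op.
#'
#' @inheritParams divide_cell
#' @param species 1 or 2.
#' @return The updated dish.
#' @export
diffuse_signal <- function(dish, mesh, species = 1, config = sim_config()) {
  m <- mesh_index(dish, mesh)
  field <- if (species == 1) "s1" else "s2"
  if (dish[[field]][m] < 1) abort("no molecule to move at this mesh")
  nb <- neighbors(dish, mesh, "orthogonal4")
  if (nrow(nb) == 0) return(dish)
  if (config$diffusion_neighbor_rule == "weighted") {
    w <- 1 + dish[[field]][nb]
    i <- sample.int(nrow(nb), 1, prob = w)
  } else {
    i <- sample.int(nrow(nb), 1)
  }
  tgt <- (nb[i, 2] - 1) * dish$height + nb[i, 1]
  dish[[field]][m] <- dish[[field]][m] - 1L
  dish[[field]][tgt] <- dish[[field]][tgt] + 1L
  dish
}
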