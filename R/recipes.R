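# Experiment recipes: the study protocols (signal on/off, inner-disk and
# dish-radius sweeps, polygonal dishes, complex label patterns, injuries)
# wrapped as reproducible multi-replicate runs with manifests.

#' Define an experiment recipe
#'
#' Named protocols over the circular/polygonal dishes: `"signal_off"` and
#' `"signal_on"` (pattern loss vs maintenance on one dish),
#' `"inner_sweep"` (fixed dish radius, varying inner-disk sizes),
#' `"radius_sweep"` (varying dish radius, inner always half),
#' `"polygons"` (square/rectangle/triangle side-length sweep),
#' `"complex"` (user label matrices) and `"injury"` (an injury fired at
#' the division-count trigger, run on to recovery).  `scale = 1` uses the
#' full-scale geometry (radius 50, termination at 50 mean divisions —
#' hours of compute); smaller scales shrink the dish and the division
#' horizon proportionally.
#'
#' @param name Protocol name (see above).
#' @param scale Linear scale factor applied to dish radius and the
#'   division horizon.
#' @param replicates Replicates per condition.
#' @param seed Master seed; replicate seeds are `seed + 0:(replicates-1)`.
#' @param sizes Size vector for the sweep protocols (defaults follow the
#'   protocol: inner disks 5, 15, 25, 35, 45; radii 10, 30, 50, 70, 100,
#'   both times `scale`).
#' @param geometry Polygon family for `"polygons"`.
#' @param label_matrices Named list of 0/1/2 matrices for `"complex"`.
#' @param injury An [injury_spec()] for `"injury"` (default: a disk of
#'   half the dish radius, centred mid-ring, triggered at the division
#'   horizon, run on for 10 more mean divisions).
#' @param overrides Config overrides applied to every run.
#' @return An object of class `experiment_recipe`.
#' @export
experiment_recipe <- function(name = c("signal_off", "signal_on",
                                       "inner_sweep", "radius_sweep",
                                       "polygons", "complex", "injury"),
                              scale = 1, replicates = 3, seed = 1,
                              sizes = NULL, geometry = "square",
                              label_matrices = NULL, injury = NULL,
                              overrides = list()) {
  name <- match.arg(name)
  if (replicates < 0) abort("`replicates` must be >= 0")
  structure(list(name = name, scale = scale, replicates = replicates,
                 seed = seed, sizes = sizes, geometry = geometry,
                 label_matrices = label_matrices, injury = injury,
                 overrides = overrides),
            class = "experiment_recipe")
}

recipe_conditions <- function(recipe) {
  s <- recipe$scale
  base_r <- max(4, round(50 * s))
  term <- max(2, round(50 * s))
  cond <- switch(recipe$name,
    signal_off = tibble(condition = "signal_off",
                        dish_size = base_r, inner_size = round(base_r / 2),
                        geometry = "circle", signals_on = FALSE),
    signal_on = tibble(condition = "signal_on",
                       dish_size = base_r, inner_size = round(base_r / 2),
                       geometry = "circle", signals_on = TRUE),
    inner_sweep = {
      sizes <- recipe$sizes %||% pmax(1, round(c(5, 15, 25, 35, 45) * s))
      tibble(condition = paste0("inner_", sizes), dish_size = base_r,
             inner_size = sizes, geometry = "circle", signals_on = TRUE)
    },
    radius_sweep = {
      sizes <- recipe$sizes %||% pmax(4, round(c(10, 30, 50, 70, 100) * s))
      tibble(condition = paste0("radius_", sizes), dish_size = sizes,
             inner_size = pmax(1, round(sizes / 2)), geometry = "circle",
             signals_on = TRUE)
    },
    polygons = {
      sizes <- recipe$sizes %||% pmax(4, round(c(10, 30, 50, 70, 100) * s))
      tibble(condition = paste0(recipe$geometry, "_", sizes),
             dish_size = sizes, inner_size = pmax(1, round(sizes / 2)),
             geometry = recipe$geometry, signals_on = TRUE)
    },
    complex = {
      if (is.null(recipe$label_matrices)) {
        abort("`complex` recipe needs `label_matrices`")
      }
      tibble(condition = names(recipe$label_matrices),
             dish_size = NA_real_, inner_size = NA_real_,
             geometry = "labelfile", signals_on = TRUE)
    },
    injury = tibble(condition = "injury",
                    dish_size = base_r, inner_size = round(base_r / 2),
                    geometry = "circle", signals_on = TRUE)
  )
  dplyr::mutate(cond, termination = term)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an experiment recipe
#'
#' Executes build -> simulate -> score for every condition and replicate,
#' writes trajectories, score series and dish snapshots under `out_dir`
#' (when given), and returns the manifest.  A failed replicate is recorded
#' in the manifest (column `error`) without stopping the others.
#'
#' @param recipe An [experiment_recipe()].
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param config Base [sim_config()] (recipe overrides are applied on
#'   top).
#' @return A tibble manifest: condition, replicate, seed, status, end
#'   time, final score, output paths (when written), and a list-column
#'   `scores` with each score series.
#' @export
run_recipe <- function(recipe, out_dir = NULL, config = sim_config()) {
  stopifnot(inherits(recipe, "experiment_recipe"))
  conds <- recipe_conditions(recipe)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (rep in seq_len(recipe$replicates)) {
      seed <- recipe$seed + (ci - 1) * recipe$replicates + (rep - 1)
      tag <- sprintf("%s_r%d", conds$condition[ci], rep)
      row <- tryCatch({
        cfg_over <- c(list(signals_on = conds$signals_on[ci],
                           termination_divisions = conds$termination[ci]),
                      recipe$overrides)
        cfg <- do.call(sim_config, modifyList(unclass(config), cfg_over))
        spec <- if (conds$geometry[ci] == "labelfile") {
          pattern_spec(geometry = "labelfile",
                       label_matrix = recipe$label_matrices[[conds$condition[ci]]])
        } else {
          pattern_spec(geometry = conds$geometry[ci],
                       dish_size = conds$dish_size[ci],
                       inner_size = conds$inner_size[ci])
        }
        dish <- build_dish(spec, seed = seed)
        injuries <- if (recipe$name == "injury") {
          recipe$injury %||% injury_spec(
            "circle",
            center = c(round(dish$height / 2), round(dish$width * 0.3)),
            size = round(conds$dish_size[ci] / 2),
            trigger = conds$termination[ci])
        }
        cfg2 <- if (recipe$name == "injury") {
          do.call(sim_config, modifyList(unclass(cfg), list(
            termination_divisions = conds$termination[ci] +
              max(2, round(10 * recipe$scale)))))
        } else cfg
        sim <- simulate_dish(dish, cfg2, injuries = injuries, seed = seed)
        sc <- score_trajectory(sim)
        paths <- list(trajectory = NA_character_, scores = NA_character_)
        if (!is.null(out_dir)) {
          paths$trajectory <- file.path(out_dir, paste0(tag, "_trajectory.tsv"))
          paths$scores <- file.path(out_dir, paste0(tag, "_scores.tsv"))
          write_trajectory(sim, paths$trajectory)
          write_scores(sc, paths$scores)
          write_dish_snapshot(sim$final, file.path(out_dir, paste0(tag, "_final.txt")))
        }
        tibble(condition = conds$condition[ci], replicate = rep, seed = seed,
               status = sim$status, t_end = sim$t_end,
               mean_divisions = sim$mean_divisions,
               final_score = sc$normalized[nrow(sc)],
               trajectory_path = paths$trajectory,
               scores_path = paths$scores,
               scores = list(sc), error = NA_character_)
      }, error = function(e) {
        tibble(condition = conds$condition[ci], replicate = rep, seed = seed,
               status = "error", t_end = NA_real_, mean_divisions = NA_real_,
               final_score = NA_real_, trajectory_path = NA_character_,
               scores_path = NA_character_, scores = list(NULL),
               error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
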