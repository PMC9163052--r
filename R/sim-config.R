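# Simulation configuration: the model's reference rates as defaults, engine
# options, validation, and the 24-channel registry shared by the reference
# propensity code, the compiled engine and the documentation.

sim_defaults <- function() {
  list(
    # stem-cell channels
    iota_xs = 85, iota_ys = 100, beta_s = 45, hill_s = 4, gamma_det_s = 1,
    r_s = 56.4, gamma_s = 0.0423, w_p = 0.329, m_s = 2.82,
    # progenitor channels
    alpha_xp = 30, alpha_yp = 30, iota_xp = 30, iota_yp = 30,
    beta_p = 47.5, hill_p = 4, gamma_det_p = 0.38,
    r_p = 32.9, gamma_p = 0.01504, w_s = 0.1645, m_p = 0.94,
    # terminal cells
    gamma_A = 0.003, gamma_B = 0.0034,
    # signalling
    alpha_s1 = 220, alpha_s2 = 220, beta_sig = 2, hill_sig = 4,
    k_sig = 0.5, D = 110, h = 1,
    eps_a = 10, eps_b = 15,
    # behaviour switches
    signals_on = TRUE,
    diffusion_scales_with_count = FALSE,
    diffusion_neighbor_rule = "uniform",
    # density feedback calibration (<= 0: use the initial dividing census)
    iota_n0 = -1,
    # run control
    termination_divisions = 50, n_shots = 500,
    max_time = 1e9, max_events = 2e9, log_max = 0,
    snapshot_dt0 = 0.05,
    # fate-map numerics
    eps_levels = 6, prog_map_step = 2, prog_map_max = 200,
    stem_map_step = 1, stem_map_max = 150,
    classify_dt = 0.05, classify_max_steps = 1e5,
    classify_speed_tol = 1e-6, classify_capture_r = 1
  )
}

rate_keys <- function() {
  c("iota_xs", "iota_ys", "beta_s", "hill_s", "gamma_det_s", "r_s",
    "gamma_s", "w_p", "m_s", "alpha_xp", "alpha_yp", "iota_xp", "iota_yp",
    "beta_p", "hill_p", "gamma_det_p", "r_p", "gamma_p", "w_s", "m_p",
    "gamma_A", "gamma_B", "alpha_s1", "alpha_s2", "beta_sig", "hill_sig",
    "k_sig", "D", "h", "eps_a", "eps_b")
}

#' Simulation configuration
#'
#' All rate parameters default to the model's reference values
#' (stem determinant synthesis 85/100, division 56.4, death 0.0423,
#' transformation 0.329, movement 2.82; progenitor synthesis 30 + 30,
#' division 32.9, death 0.01504, transformation 0.1645, movement 0.94;
#' terminal death 0.003/0.0034; signal production 220, decay 0.5,
#' diffusion 110).  Overrides are given by name; unknown names error.
#'
#' @param ... Named overrides of the defaults (see `sim_config()$...` for
#'   the full key set).  Notable keys: `signals_on` (FALSE removes the
#'   signalling layer entirely), `termination_divisions` (mean progenitor
#'   division count at which the run stops), `n_shots` (snapshots kept for
#'   scoring), `max_time`/`max_events` (safety caps), `log_max` (cap on the
#'   per-event log; 0 disables logging), `diffusion_scales_with_count` and
#'   `diffusion_neighbor_rule` (`"uniform"` or `"weighted"`).
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  cfg <- sim_defaults()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s): %s\nvalid keys: %s",
                    paste(unknown, collapse = ", "),
                    paste(names(cfg), collapse = ", ")))
    }
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  for (k in rate_keys()) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(sprintf("config key `%s` must be a finite non-negative number", k))
    }
  }
  if (cfg$termination_divisions < 1) {
    abort("`termination_divisions` must be >= 1")
  }
  if (cfg$n_shots < 1) abort("`n_shots` must be >= 1")
  if (!cfg$diffusion_neighbor_rule %in% c("uniform", "weighted")) {
    abort("`diffusion_neighbor_rule` must be 'uniform' or 'weighted'")
  }
  if (!is.logical(cfg$signals_on) || !is.logical(cfg$diffusion_scales_with_count)) {
    abort("`signals_on` and `diffusion_scales_with_count` must be logical")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  defs <- sim_defaults()
  changed <- names(x)[!mapply(identical, x, defs[names(x)])]
  if (length(changed) == 0) {
    cat("  all keys at reference defaults\n")
  } else {
    for (k in changed) cat(sprintf("  %s = %s (default %s)\n", k,
                                   format(x[[k]]), format(defs[[k]])))
  }
  invisible(x)
}

#' Load / save a configuration as YAML
#'
#' Unspecified keys take the package defaults; unknown keys raise an
#' error listing the valid set.  `load_config(write_config(cfg, p))` is the
#' identity.
#'
#' @param path YAML file path.
#' @param cfg A [sim_config()].
#' @return `load_config()` returns a `sim_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  sim_config(vals)
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' The 24 reaction channels
#'
#' The registry of reaction-channel kinds of the stochastic model: per-cell
#' determinant synthesis/degradation, division, death, transformation and
#' movement for S and P cells, terminal-cell death, and per-mesh signal
#' production, decay and diffusion.  The reference propensity evaluator
#' ([total_propensity()]) and the compiled engine both follow this table.
#'
#' @return A 24-row tibble with columns `id`, `scope`, `name`, `rate_key`.
#' @export
reaction_channels <- function() {
  tibble(
    id = 1:24,
    scope = c(rep("per-S-cell", 8), rep("per-P-cell", 8), "per-A-cell",
              "per-B-cell", rep("per-mesh", 6)),
    name = c("X_s production", "X_s degradation", "Y_s production",
             "Y_s degradation", "S division", "S death",
             "S transformation (S->P)", "S movement",
             "X_p production", "X_p degradation", "Y_p production",
             "Y_p degradation", "P division", "P death",
             "P transformation (P->S)", "P movement",
             "A death", "B death",
             "S1 production", "S1 degradation", "S2 production",
             "S2 degradation", "S1 diffusion", "S2 diffusion"),
    rate_key = c("iota_xs", "gamma_det_s", "iota_ys", "gamma_det_s",
                 "r_s", "gamma_s", "w_p", "m_s",
                 "alpha_xp", "gamma_det_p", "alpha_yp", "gamma_det_p",
                 "r_p", "gamma_p", "w_s", "m_p",
                 "gamma_A", "gamma_B",
                 "alpha_s1", "k_sig", "alpha_s2", "k_sig", "D", "D")
  )
}
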