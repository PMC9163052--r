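# Fixed points, attractor basins and fate classification for the regulatory
# switches.  Attractors are found by forward integration (compiled); the
# full fixed-point set including saddles comes from damped Newton iteration
# started on a grid, with the analytic 2x2 Jacobian.

switch_jacobian <- function(sw, x, y) {
  bn <- sw$beta^sw$hill_n
  n <- sw$hill_n
  dact <- function(v) if (v <= 0 && n > 1) 0 else n * bn * v^(n - 1) / (bn + v^n)^2
  drep <- function(v) if (v <= 0 && n > 1) 0 else -n * bn * v^(n - 1) / (bn + v^n)^2
  matrix(c((sw$ax + sw$ex) * dact(x) - sw$gamma, sw$iy * drep(x),
           sw$ix * drep(y), (sw$ay + sw$ey) * dact(y) - sw$gamma),
         nrow = 2) # column-major: [ dfx/dx, dfy/dx ; dfx/dy, dfy/dy ]
}

switch_drift_raw <- function(sw, x, y) {
  bn <- sw$beta^sw$hill_n
  xn <- x^sw$hill_n; yn <- y^sw$hill_n
  c((sw$ax + sw$ex) * xn / (bn + xn) + sw$ix * bn / (bn + yn) - sw$gamma * x,
    (sw$ay + sw$ey) * yn / (bn + yn) + sw$iy * bn / (bn + xn) - sw$gamma * y)
}

#' Fixed points of a regulatory switch
#'
#' Finds all fixed points (stable nodes and saddles) of the two-variable
#' deterministic switch by Newton iteration from a grid of starting points,
#' and classifies each by the eigenvalues of the analytic Jacobian.
#'
#' @param system One of `"stem"`, `"progenitor"`, `"signal"`.
#' @param params Matching parameter object; defaults to the reference
#'   values for that system.
#' @param extent Upper bound of the square search window (molecule counts).
#' @param grid_n Starts per axis for the Newton sweep.
#' @return A tibble with columns `x`, `y`, `stable` (logical) and
#'   `eig_max_re` (largest eigenvalue real part).
#' @examples
#' find_fixed_points("stem")        # 2 stable + 1 saddle at the defaults
#' find_fixed_points("progenitor")  # 3 stable at the defaults (eps = 0)
#' @export
find_fixed_points <- function(system = c("stem", "progenitor", "signal"),
                              params = NULL, extent = NULL, grid_n = 12) {
  system <- match.arg(system)
  if (is.null(params)) params <- default_params_for(system)
  sw <- as_switch(params)
  if (is.null(extent)) extent <- default_extent(system, sw)
  starts <- expand.grid(x = seq(0, extent, length.out = grid_n),
                        y = seq(0, extent, length.out = grid_n))
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    z <- c(starts$x[i], starts$y[i])
    ok <- FALSE
    for (it in 1:80) {
      f <- switch_drift_raw(sw, z[1], z[2])
      if (max(abs(f)) < 1e-10) { ok <- TRUE; break }
      J <- switch_jacobian(sw, z[1], z[2])
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) break
      if (max(abs(step)) > extent) step <- step * extent / max(abs(step))
      z <- pmax(z - step, 0)
    }
    if (ok && all(z >= -1e-8) && all(z <= 2 * extent)) sols[[length(sols) + 1]] <- z
  }
  if (length(sols) == 0) return(tibble(x = double(), y = double(),
                                       stable = logical(), eig_max_re = double()))
  pts <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j <= i || !keep[j]) next
      if (sum((pts[i, ] - pts[j, ])^2) < 0.25) keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(pts)), function(i) {
    J <- switch_jacobian(sw, pts[i, 1], pts[i, 2])
    ev <- eigen(J, only.values = TRUE)$values
    tibble(x = pts[i, 1], y = pts[i, 2],
           stable = all(Re(ev) < 0), eig_max_re = max(Re(ev)))
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, dplyr::desc(.data$stable), .data$x)
}

default_extent <- function(system, sw) {
  # generous bound on attainable determinant levels: max production / gamma
  switch(system,
         stem = 1.5 * max(sw$ix, sw$iy) / sw$gamma,
         progenitor = 1.3 * (max(sw$ax + sw$ex, sw$ay + sw$ey) +
                               max(sw$ix, sw$iy)) / sw$gamma,
         signal = 1.5 * max(sw$ix, sw$iy) / sw$gamma)
}

fate_labels <- c("S", "P", "A", "B")

label_attractors_r <- function(att, system) {
  if (system == "stem") {
    ifelse(att[, 1] > att[, 2], 1L, 2L)
  } else if (system == "progenitor") {
    ifelse(att[, 1] > 2 * att[, 2] + 1, 3L,
           ifelse(att[, 2] > 2 * att[, 1] + 1, 4L, 2L))
  } else {
    # signal layer: species-1-dominant vs species-2-dominant
    ifelse(att[, 1] > att[, 2], 1L, 2L)
  }
}

stable_attractors <- function(system, params, extent = NULL) {
  sw <- as_switch(params)
  if (is.null(extent)) extent <- default_extent(system, sw)
  att <- cpp_find_attractors(sw, extent)
  if (nrow(att) == 0) abort("no stable fixed point found")
  list(points = att, labels = label_attractors_r(att, system), extent = extent)
}

#' Classify a determinant state into a fate
#'
#' Integrates the deterministic switch dynamics from `(x, y)` (fixed-step
#' RK4) until the trajectory is captured within `capture_r` of a stable
#' fixed point, and returns that attractor's fate label.  The stem system
#' yields S (x-dominant) or P (y-dominant); the progenitor system yields P
#' (balanced), A (x-dominant) or B (y-dominant).  States on the separatrix
#' (non-convergent or equidistant) are assigned P, favouring the dividing
#' compartment.
#'
#' @param x,y Determinant counts (vectorised).
#' @param system `"stem"` or `"progenitor"`.
#' @param params Matching parameter object (tristable `eps_x`/`eps_y` carry
#'   the local signal effect).
#' @param dt RK4 step, model-time units.
#' @param max_steps Iteration cap before the tie rule applies.
#' @param capture_r Capture radius around an attractor.
#' @return A factor with levels S, P, A, B.
#' @examples
#' classify_fate(200, 0, "stem")      # deep inside the S basin
#' classify_fate(0, 200, "progenitor") # deep inside the B basin
#' @export
classify_fate <- function(x, y, system = c("stem", "progenitor"),
                          params = NULL, dt = 0.01, max_steps = 1e5,
                          capture_r = 1) {
  system <- match.arg(system)
  if (is.null(params)) params <- default_params_for(system)
  check_state(x, y)
  att <- stable_attractors(system, params)
  lab <- cpp_classify(as_switch(params), as.double(x), as.double(y),
                      att$points, att$labels, dt, max_steps, 1e-6,
                      capture_r, 2L)
  factor(fate_labels[lab], levels = fate_labels)
}

#' Attractor-basin map of a switch
#'
#' Classifies every point of a regular grid over `[0, extent]^2` and
#' returns the labelled map together with the stable attractors that define
#' it.  The map doubles as a cache: [sample_from_basin()] accepts it
#' directly, and the simulation engine maintains its own equivalents.
#'
#' @inheritParams classify_fate
#' @param extent Upper bound of the grid (molecule counts); defaults to 150
#'   for the stem system and 200 for the progenitor system (the x-dominant
#'   progenitor attractor sits near x = 158 at the default parameters).
#' @param resolution Grid points per axis (>= 2).
#' @return An object of class `basin_map`: a list with `grid` (integer
#'   matrix of fate codes, rows indexing x), `xs`, `ys`, `attractors`,
#'   `system`, `params`.  `as_tibble()` gives the long form.
#' @export
basin_map <- function(system = c("stem", "progenitor", "signal"),
                      params = NULL, extent = NULL, resolution = NULL) {
  system <- match.arg(system)
  if (is.null(params)) params <- default_params_for(system)
  if (is.null(extent)) extent <- if (system == "progenitor") 200 else 150
  if (is.null(resolution)) resolution <- extent + 1
  if (resolution < 2) abort("`resolution` must be >= 2")
  att <- stable_attractors(system, params, extent)
  step <- extent / (resolution - 1)
  grid <- cpp_basin_map(as_switch(params), att$points, att$labels,
                        extent, step, 2L)
  structure(list(grid = grid, xs = seq(0, extent, by = step),
                 ys = seq(0, extent, by = step),
                 attractors = tibble(x = att$points[, 1], y = att$points[, 2],
                                     fate = factor(fate_labels[att$labels],
                                                   levels = fate_labels)),
                 system = system, params = params),
            class = "basin_map")
}

#' @method as_tibble basin_map
#' @export
as_tibble.basin_map <- function(x, ...) {
  g <- expand.grid(x = x$xs, y = x$ys)
  tibble(x = g$x, y = g$y,
         fate = factor(fate_labels[as.vector(x$grid)], levels = fate_labels))
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("<basin_map: %s system, %d x %d grid over [0, %g]^2>\n",
              x$system, nrow(x$grid), ncol(x$grid), max(x$xs)))
  print(table(factor(fate_labels[as.vector(x$grid)], levels = fate_labels)))
  invisible(x)
}

#' Sample determinant states from an attractor basin
#'
#' Draws integer `(x, y)` states uniformly from the grid points of a basin
#' map carrying the requested fate label.  Used to (re)initialise
#' determinants when a cell enters a switch system (dish construction,
#' S/P transformation, cross-system daughters).
#'
#' @param n Number of draws.
#' @param label Fate label: "S"/"P" for the stem system, "P"/"A"/"B" for
#'   the progenitor system.
#' @param map A precomputed [basin_map()]; built on the fly from `system`
#'   and `params` when omitted.
#' @inheritParams classify_fate
#' @return A tibble with integer columns `x`, `y`.
#' @export
sample_from_basin <- function(n, label, system = c("stem", "progenitor"),
                              params = NULL, map = NULL) {
  if (is.null(map)) {
    system <- match.arg(system)
    map <- basin_map(system, params)
  }
  code <- match(label, fate_labels)
  if (is.na(code)) abort("unknown fate label")
  idx <- which(map$grid == code)
  if (length(idx) == 0) {
    abort(sprintf("basin '%s' is empty in the sampling extent", label))
  }
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  i <- (pick - 1) %% nrow(map$grid) + 1
  j <- (pick - 1) %/% nrow(map$grid) + 1
  tibble(x = as.integer(round(map$xs[i])), y = as.integer(round(map$ys[j])))
}
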