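# Dish geometry, pattern initialisation, occupancy bookkeeping and injuries.
# A dish is a matrix-backed S3 object: height x width integer matrices for
# occupancy (0 empty, 1 S, 2 P, 3 A, 4 B), determinant counts, division
# counters and the two signal species, plus a validity mask and the target
# region labels (1 = A region, 2 = B region).

occ_codes <- c(empty = 0L, S = 1L, P = 2L, A = 3L, B = 4L)

#' Specify a dish geometry and initial pattern
#'
#' Built-in geometries place an inner region (target fate A) inside an
#' outer region (target fate B): concentric disks, centred squares,
#' rectangles (height half the width) and isoceles triangles.  Arbitrary
#' patterns come from an integer label matrix (0 outside the dish, 1 A
#' region, 2 B region), see [read_label_matrix()].
#'
#' @param geometry One of `"circle"`, `"square"`, `"rectangle"`,
#'   `"triangle"`, `"labelfile"`.
#' @param dish_size Dish radius (circle) or side length (polygons), in
#'   meshes.
#' @param inner_size Inner-region radius/side; defaults to half of
#'   `dish_size`.
#' @param dividing_fraction_S,dividing_fraction_P Fractions of valid meshes
#'   initially occupied by S and P cells, scattered uniformly over the dish
#'   (they overwrite the terminal occupant of the meshes they land on).
#'   Defaults: 10% dividing cells in total, S:P = 1:2 (the balance of the
#'   S/P transformation rates).
#' @param label_matrix Integer matrix for `geometry = "labelfile"`.
#' @param signal_init Initial signal load of the region meshes (s1 in the A
#'   region, s2 in the B region).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(geometry = c("circle", "square", "rectangle",
                                      "triangle", "labelfile"),
                         dish_size = 50, inner_size = NULL,
                         dividing_fraction_S = 1 / 30,
                         dividing_fraction_P = 2 / 30,
                         label_matrix = NULL, signal_init = 100) {
  geometry <- match.arg(geometry)
  if (geometry == "labelfile") {
    if (is.null(label_matrix)) abort("labelfile geometry needs `label_matrix`")
    if (!all(label_matrix %in% 0:2)) abort("label matrix codes must be 0/1/2")
  } else {
    if (is.null(inner_size)) inner_size <- dish_size / 2
    if (dish_size < 2) abort("`dish_size` must be >= 2 meshes")
    if (inner_size <= 0 || inner_size >= dish_size) {
      abort("`inner_size` must lie strictly inside the dish")
    }
  }
  if (dividing_fraction_S < 0 || dividing_fraction_P < 0 ||
      dividing_fraction_S + dividing_fraction_P > 1) {
    abort("dividing fractions must be in [0, 1] and sum to at most 1")
  }
  structure(list(geometry = geometry, dish_size = dish_size,
                 inner_size = inner_size,
                 dividing_fraction_S = dividing_fraction_S,
                 dividing_fraction_P = dividing_fraction_P,
                 label_matrix = label_matrix, signal_init = signal_init),
            class = "pattern_spec")
}

region_masks <- function(spec) {
  g <- spec$geometry
  if (g == "labelfile") {
    lm <- spec$label_matrix
    return(list(valid = lm > 0, region = matrix(as.integer(lm), nrow(lm))))
  }
  R <- spec$dish_size
  inner <- spec$inner_size
  if (g == "circle") {
    n <- 2L * ceiling(R) + 1L
    c0 <- ceiling(R) + 1L
    d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
    valid <- d <= R
    region <- matrix(0L, n, n)
    region[valid] <- ifelse(d[valid] <= inner, 1L, 2L)
  } else if (g == "square") {
    L <- round(R)
    valid <- matrix(TRUE, L, L)
    region <- matrix(2L, L, L)
    o <- floor((L - inner) / 2)
    rows <- seq.int(o + 1, o + round(inner))
    region[rows, rows] <- 1L
  } else if (g == "rectangle") {
    W <- round(R); H <- max(2L, round(R / 2))
    valid <- matrix(TRUE, H, W)
    region <- matrix(2L, H, W)
    iw <- round(inner); ih <- max(1L, round(inner / 2))
    or <- floor((H - ih) / 2); oc <- floor((W - iw) / 2)
    region[seq.int(or + 1, or + ih), seq.int(oc + 1, oc + iw)] <- 1L
  } else { # triangle, apex up
    L <- round(R)
    cx <- (L + 1) / 2
    valid <- matrix(FALSE, L, L)
    for (r in seq_len(L)) {
      hw <- (r / L) * (L / 2)
      valid[r, abs(seq_len(L) - cx) <= hw] <- TRUE
    }
    region <- matrix(0L, L, L)
    region[valid] <- 2L
    i <- round(inner)
    r0 <- round(2 * L / 3 - 2 * i / 3) # align centroids
    for (rr in seq_len(i)) {
      r <- r0 + rr
      if (r < 1 || r > L) next
      hw <- (rr / i) * (i / 2)
      cols <- which(abs(seq_len(L) - cx) <= hw)
      region[r, cols][valid[r, cols]] <- 1L
    }
  }
  list(valid = valid, region = region)
}

#' Build an initialised dish
#'
#' Places terminal cells according to the target regions (A inside, B
#' outside), scatters S and P cells uniformly over the dish at the spec
#' fractions (overwriting the terminal occupant where they land), draws
#' their determinants from the matching attractor basins, and loads the
#' region meshes with the initial signal counts (s1 = 100 in the A region,
#' s2 = 100 in the B region by default).
#'
#' @param spec A [pattern_spec()].
#' @param seed Integer seed; the build is reproducible given the seed.
#' @return An object of class `dish`.
#' @export
build_dish <- function(spec = pattern_spec(), seed = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (!is.null(seed)) set.seed(seed)
  mk <- region_masks(spec)
  valid <- mk$valid; region <- mk$region
  H <- nrow(valid); W <- ncol(valid)
  occ <- matrix(0L, H, W)
  occ[region == 1L] <- occ_codes[["A"]]
  occ[region == 2L] <- occ_codes[["B"]]
  x <- matrix(0L, H, W); y <- matrix(0L, H, W); div <- matrix(0L, H, W)
  s1 <- matrix(0L, H, W); s2 <- matrix(0L, H, W)
  s1[region == 1L] <- as.integer(spec$signal_init)
  s2[region == 2L] <- as.integer(spec$signal_init)

  vidx <- which(valid)
  nS <- round(spec$dividing_fraction_S * length(vidx))
  nP <- round(spec$dividing_fraction_P * length(vidx))
  if (nS + nP > 0) {
    pos <- sample(vidx, nS + nP)
    if (nS > 0) {
      smap <- cached_map("stem")
      st <- sample_from_basin(nS, "S", map = smap)
      occ[pos[seq_len(nS)]] <- occ_codes[["S"]]
      x[pos[seq_len(nS)]] <- st$x
      y[pos[seq_len(nS)]] <- st$y
    }
    if (nP > 0) {
      pmap <- cached_map("progenitor")
      pr <- sample_from_basin(nP, "P", map = pmap)
      ppos <- pos[nS + seq_len(nP)]
      occ[ppos] <- occ_codes[["P"]]
      x[ppos] <- pr$x
      y[ppos] <- pr$y
    }
  }
  new_dish(valid, occ, x, y, div, s1, s2, region, spec, seed)
}

new_dish <- function(valid, occ, x, y, div, s1, s2, region, spec, seed) {
  structure(list(width = ncol(valid), height = nrow(valid), valid = valid,
                 occ = occ, x = x, y = y, div = div, s1 = s1, s2 = s2,
                 region = region, spec = spec, seed = seed),
            class = "dish")
}

#' @export
print.dish <- function(x, ...) {
  cat(sprintf("<dish %d x %d, %d valid meshes>\n", x$height, x$width,
              sum(x$valid)))
  print(dish_census(x))
  invisible(x)
}

#' Cell-type census of a dish
#'
#' @param dish A [build_dish()] object.
#' @return A one-row tibble with counts of empty meshes and each cell type,
#'   and the total signal loads.
#' @export
dish_census <- function(dish) {
  o <- dish$occ[dish$valid]
  tibble(empty = sum(o == 0L), n_S = sum(o == 1L), n_P = sum(o == 2L),
         n_A = sum(o == 3L), n_B = sum(o == 4L),
         s1_total = sum(dish$s1), s2_total = sum(dish$s2))
}

#' In-dish neighbours of a mesh
#'
#' @param dish A dish.
#' @param mesh Integer `c(row, col)`, 1-based.
#' @param kind `"orthogonal4"` (diffusion adjacency) or `"full8"`
#'   (daughter-placement adjacency).
#' @return An integer matrix with columns `row`, `col`, one neighbour per
#'   row; only valid in-dish meshes are returned.
#' @export
neighbors <- function(dish, mesh, kind = c("orthogonal4", "full8")) {
  kind <- match.arg(kind)
  r <- mesh[1]; c <- mesh[2]
  if (r < 1 || r > dish$height || c < 1 || c > dish$width ||
      !dish$valid[r, c]) {
    abort("`mesh` is not a valid dish mesh")
  }
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  if (kind == "orthogonal4") d <- d[d$dr == 0 | d$dc == 0, ]
  rr <- r + d$dr; cc <- c + d$dc
  ok <- rr >= 1 & rr <= dish$height & cc >= 1 & cc <= dish$width
  rr <- rr[ok]; cc <- cc[ok]
  ok2 <- dish$valid[cbind(rr, cc)]
  cbind(row = rr[ok2], col = cc[ok2])
}

#' Uniformly random empty mesh
#'
#' @param dish A dish.
#' @return Integer `c(row, col)` of an empty valid mesh drawn uniformly, or
#'   `NULL` when the dish is full (movement events then become no-ops).
#' @export
random_empty_mesh <- function(dish) {
  idx <- which(dish$valid & dish$occ == 0L)
  if (length(idx) == 0) return(NULL)
  m <- idx[sample.int(length(idx), 1)]
  c(row = (m - 1) %% dish$height + 1, col = (m - 1) %/% dish$height + 1)
}

#' Specify an injury
#'
#' An injury removes every cell in a region of the dish at the moment the
#' living progenitor cells' mean division count reaches `trigger`.  Signal
#' molecules are left in place (decay and diffusion erase them).
#'
#' @param shape `"circle"`, `"rect"` or `"mask"`.
#' @param center `c(row, col)` centre of the region.
#' @param size Radius (circle) or `c(height, width)` (rect), meshes.
#' @param trigger Mean progenitor division count at which the injury fires.
#' @param mask Logical matrix (dish-shaped) for `shape = "mask"`.
#' @return An object of class `injury_spec`.
#' @export
injury_spec <- function(shape = c("circle", "rect", "mask"), center = NULL,
                        size = NULL, trigger = 50, mask = NULL) {
  shape <- match.arg(shape)
  if (shape != "mask" && (is.null(center) || is.null(size))) {
    abort("`center` and `size` are required for circle/rect injuries")
  }
  if (shape == "mask" && is.null(mask)) abort("`mask` is required")
  if (trigger < 0) abort("`trigger` must be >= 0")
  structure(list(shape = shape, center = center, size = size,
                 trigger = trigger, mask = mask),
            class = "injury_spec")
}

injury_region <- function(dish, spec) {
  H <- dish$height; W <- dish$width
  if (spec$shape == "mask") {
    if (!all(dim(spec$mask) == c(H, W))) abort("injury mask shape mismatch")
    reg <- spec$mask
  } else if (spec$shape == "circle") {
    d <- sqrt(outer((seq_len(H) - spec$center[1])^2,
                    (seq_len(W) - spec$center[2])^2, `+`))
    reg <- d <= spec$size
  } else {
    reg <- matrix(FALSE, H, W)
    hh <- spec$size[1]; ww <- if (length(spec$size) > 1) spec$size[2] else hh
    rows <- pmax(1, spec$center[1] - floor(hh / 2)):pmin(H, spec$center[1] + ceiling(hh / 2) - 1)
    cols <- pmax(1, spec$center[2] - floor(ww / 2)):pmin(W, spec$center[2] + ceiling(ww / 2) - 1)
    reg[rows, cols] <- TRUE
  }
  reg & dish$valid
}

#' Apply an injury to a dish
#'
#' Removes every occupant inside the injury region; signal counts are left
#' untouched.  (Inside a running simulation, injuries fire automatically at
#' their trigger; this function is the standalone equivalent.)
#'
#' @param dish A dish.
#' @param spec An [injury_spec()].
#' @return The injured dish.
#' @export
apply_injury <- function(dish, spec) {
  reg <- injury_region(dish, spec)
  dish$occ[reg] <- 0L
  dish$x[reg] <- 0L
  dish$y[reg] <- 0L
  dish$div[reg] <- 0L
  dish
}
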