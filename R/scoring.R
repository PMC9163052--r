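# Template/penalty pattern-similarity score: filters derived from the
# initial pattern, zero padding, a sliding inner product sweep, the max of
# (template - penalty) responses, and normalisation by the initial
# configuration's own score.

#' Build template and penalty filters from a dish
#'
#' The template is +1 on the meshes whose target fate is A (the inner
#' region), -1 on the B-region meshes and 0 elsewhere; the penalty is 1
#' outside the dish (within the square frame) and 0 otherwise.  Their
#' supports are disjoint by construction.  Non-square dishes are embedded
#' centred in a `d x d` frame, `d = max(height, width)`.
#'
#' @param dish A dish (its `region` labels define the partition).
#' @return An object of class `filter_pair`: list with `template`,
#'   `penalty` (d x d integer matrices) and `d`.
#' @export
build_filters <- function(dish) {
  if (!any(dish$region == 1L) || !any(dish$region == 2L)) {
    abort("dish has no A/B region partition to build filters from")
  }
  reg <- embed_square(dish$region, dish)
  val <- embed_square(dish$valid + 0L, dish)
  template <- matrix(0L, nrow(reg), ncol(reg))
  template[reg == 1L] <- 1L
  template[reg == 2L] <- -1L
  penalty <- matrix(0L, nrow(reg), ncol(reg))
  penalty[val == 0L] <- 1L
  structure(list(template = template, penalty = penalty, d = nrow(reg)),
            class = "filter_pair")
}

embed_square <- function(m, dish) {
  d <- max(dish$height, dish$width)
  out <- matrix(0L, d, d)
  r0 <- floor((d - dish$height) / 2)
  c0 <- floor((d - dish$width) / 2)
  out[r0 + seq_len(dish$height), c0 + seq_len(dish$width)] <- m
  out
}

#' Encode a snapshot as a signed matrix
#'
#' A cells map to +1, B cells to -1, everything else (empty meshes,
#' dividing cells, out-of-dish frame) to 0.
#'
#' @param shot A dish, or an occupancy matrix (codes 0..4).
#' @param dish The dish supplying the frame geometry when `shot` is a bare
#'   matrix.
#' @return A `d x d` integer matrix with entries in -1/0/+1.
#' @export
encode_shot <- function(shot, dish = NULL) {
  if (inherits(shot, "dish")) {
    dish <- shot
    shot <- shot$occ
  }
  if (is.null(dish)) abort("`dish` is needed to frame a bare matrix")
  occ <- embed_square(shot, dish)
  enc <- matrix(0L, nrow(occ), ncol(occ))
  enc[occ == 3L] <- 1L
  enc[occ == 4L] <- -1L
  enc
}

#' Zero-pad an encoded shot
#'
#' Adds `floor(d/2)` zeros on the left/top and `ceiling(d/2)` on the
#' right/bottom, giving a `2d x 2d` matrix with the encoding in the centre
#' block.
#'
#' @param enc A `d x d` encoded shot.
#' @return A `2d x 2d` integer matrix.
#' @export
pad_shot <- function(enc) {
  d <- nrow(enc)
  out <- matrix(0L, 2L * d, 2L * d)
  o <- floor(d / 2)
  out[o + seq_len(d), o + seq_len(d)] <- enc
  out
}

#' Raw similarity score of one padded shot
#'
#' Slides the `d x d` template and penalty filters over the `2d x 2d`
#' padded shot and returns `max_i (t_i - p_i)` over the `d + 1` offsets of
#' a one-axis horizontal sweep (the vertical offset held at the centred
#' position), where `t_i`/`p_i` are the elementwise inner products of each
#' filter with the window.  `sweep = "full"` takes the maximum over all
#' `(d + 1)^2` two-axis offsets instead.
#'
#' @param padded A `2d x 2d` padded encoded shot.
#' @param filters A [build_filters()] pair.
#' @param sweep `"horizontal"` (default) or `"full"`.
#' @return The raw integer score.
#' @export
score_shot <- function(padded, filters, sweep = c("horizontal", "full")) {
  sweep <- match.arg(sweep)
  d <- filters$d
  if (!all(dim(padded) == 2L * d)) {
    abort(sprintf("padded shot must be %d x %d for these filters",
                  2L * d, 2L * d))
  }
  roff <- if (sweep == "horizontal") floor(d / 2) else 0:d
  best <- -Inf
  for (ro in roff) {
    rows <- ro + seq_len(d)
    for (co in 0:d) {
      w <- padded[rows, co + seq_len(d)]
      v <- sum(filters$template * w) - sum(filters$penalty * w)
      if (v > best) best <- v
    }
  }
  best
}

#' Normalise a raw score series
#'
#' Divides by the reference (the raw score of the initial configuration,
#' i.e. the perfect pattern) and clamps to `[0, 1]`, so the series reads
#' as "similarity to the initial pattern".
#'
#' @param raw Numeric vector of raw scores.
#' @param reference Raw score of the initial configuration (> 0).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(raw, reference) {
  if (!is.finite(reference) || reference <= 0) {
    abort("`reference` must be a positive raw score")
  }
  pmin(pmax(raw / reference, 0), 1)
}

#' Score the snapshot series of a simulation
#'
#' Builds the filters from the run's initial dish, scores every stored
#' snapshot and normalises by the initial configuration's raw score.
#'
#' @param sim A `dish_sim`.
#' @param filters Optional precomputed [build_filters()] pair (e.g. when
#'   scoring against a different target pattern).
#' @param sweep Passed to [score_shot()].
#' @return An object of class `score_series`: a tibble with `shot`,
#'   `time`, `raw`, `normalized`, carrying the filters and reference as
#'   attributes.
#' @export
score_trajectory <- function(sim, filters = NULL, sweep = "horizontal") {
  if (is.null(filters)) filters <- build_filters(sim$initial)
  ref <- score_shot(pad_shot(encode_shot(sim$initial)), filters, sweep)
  raw <- vapply(sim$snapshots, function(occ) {
    score_shot(pad_shot(encode_shot(occ, sim$initial)), filters, sweep)
  }, double(1))
  out <- tibble(shot = sim$trajectory$shot, time = sim$trajectory$time,
                raw = raw, normalized = normalize_scores(raw, ref))
  attr(out, "reference") <- ref
  attr(out, "filters") <- filters
  class(out) <- c("score_series", class(out))
  out
}

#' Export a score series
#'
#' @param scores A [score_trajectory()] result.
#' @param path Output file (tab-separated: shot, time, raw, normalized).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
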