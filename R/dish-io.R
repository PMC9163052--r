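# Delimited-text serialisation: label matrices (pattern input) and full
# dish snapshots.  All files are whitespace-delimited integers with '#'
# header lines, so they stay inspectable and diff-able.

#' Read / write pattern label matrices
#'
#' A label matrix codes the target pattern: 0 outside the dish, 1 A region,
#' 2 B region.  Dividing cells are always scattered programmatically, so
#' the file only carries the geometry.
#'
#' @param path File path.
#' @param mat Integer matrix with codes 0/1/2.
#' @return `read_label_matrix()` returns an integer matrix.
#' @export
read_label_matrix <- function(path) {
  m <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (!all(m %in% 0:2)) abort("label matrix codes must be 0/1/2")
  m
}

#' @rdname read_label_matrix
#' @export
write_label_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stemdish label matrix %d %d", nrow(mat), ncol(mat)),
             con)
  write.table(mat, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write full dish snapshots
#'
#' Serialises every lattice field of a dish (occupancy, determinants,
#' division counters, both signal species, region labels, validity mask) as
#' stacked integer matrices under a header carrying the shape and build
#' seed.  `read_dish_snapshot()` reconstructs an identical dish (its
#' pattern spec becomes a `labelfile` spec over the stored region labels).
#'
#' @param dish A dish.
#' @param path File path.
#' @return `read_dish_snapshot()` returns a `dish`.
#' @export
write_dish_snapshot <- function(dish, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- if (is.null(dish$seed)) NA_integer_ else dish$seed
  writeLines(sprintf("# stemdish snapshot %d %d seed=%s", dish$height,
                     dish$width, seed), con)
  for (field in c("occ", "x", "y", "div", "s1", "s2", "region")) {
    writeLines(paste0("# ", field), con)
    write.table(dish[[field]], con, row.names = FALSE, col.names = FALSE)
  }
  writeLines("# valid", con)
  write.table(dish$valid + 0L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dish_snapshot
#' @export
read_dish_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  H <- as.integer(hdr[4]); W <- as.integer(hdr[5])
  seed <- sub("seed=", "", hdr[6])
  seed <- if (seed == "NA") NULL else as.integer(seed)
  body <- lines[-1]
  starts <- grep("^# ", body)
  fields <- sub("^# ", "", body[starts])
  out <- list()
  for (k in seq_along(starts)) {
    rows <- body[(starts[k] + 1):(starts[k] + H)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.integer))
    out[[fields[k]]] <- m
  }
  valid <- out$valid == 1L
  spec <- pattern_spec(geometry = "labelfile", label_matrix = out$region)
  new_dish(valid, out$occ, out$x, out$y, out$div, out$s1, out$s2,
           out$region, spec, seed)
}
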