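#' Partition a slide into square tiles by cell centroid
#'
#' Lays a regular grid of `tile_size` x `tile_size` squares over the slide,
#' anchored at the minimum cell centroid, and assigns every cell to exactly
#' one tile by its centroid using half-open intervals `[x0, x1)`. Tiles with
#' fewer than `min_cells` cells are kept in the output but flagged
#' `retained = FALSE`; all downstream feature computation uses retained
#' tiles only.
#'
#' @param table A [cell_table()].
#' @param tile_size Tile edge length in microns (default 1000, i.e. 1 mm).
#' @param min_cells Minimum cells for a tile to be retained (default 100).
#' @return List with:
#'   \item{tiles}{data.frame: `tile_id`, `slide_id`, `ix`, `iy`,
#'     `x0`, `x1`, `y0`, `y1`, `n_cells`, `retained`.}
#'   \item{assignment}{character vector, one `tile_id` per cell (in the
#'     order of `table$cells`).}
#' @export
build_tiles <- function(table, tile_size = 1000, min_cells = 100) {
  stopifnot(inherits(table, "cell_table"))
  if (!is.numeric(tile_size) || tile_size <= 0) stop("tile_size must be > 0")
  if (!is.numeric(min_cells) || min_cells < 1) stop("min_cells must be >= 1")
  d <- table$cells
  if (nrow(d) == 0L) stop("cannot tile an empty cell table")

  x0 <- min(d$x_c); y0 <- min(d$y_c)
  ix <- floor((d$x_c - x0) / tile_size)
  iy <- floor((d$y_c - y0) / tile_size)
  tile_id <- paste(table$slide_id, ix, iy, sep = ":")

  key <- paste(ix, iy, sep = ":")
  tab <- table(key)
  uk <- names(tab)
  parts <- do.call(rbind, strsplit(uk, ":", fixed = TRUE))
  uix <- as.integer(parts[, 1]); uiy <- as.integer(parts[, 2])
  tiles <- data.frame(
    tile_id = paste(table$slide_id, uix, uiy, sep = ":"),
    slide_id = table$slide_id,
    ix = uix, iy = uiy,
    x0 = x0 + uix * tile_size, x1 = x0 + (uix + 1) * tile_size,
    y0 = y0 + uiy * tile_size, y1 = y0 + (uiy + 1) * tile_size,
    n_cells = as.integer(tab),
    stringsAsFactors = FALSE
  )
  tiles$retained <- tiles$n_cells >= min_cells
  tiles <- tiles[order(tiles$ix, tiles$iy), , drop = FALSE]
  rownames(tiles) <- NULL
  list(tiles = tiles, assignment = tile_id)
}

#' Split a cell table into per-tile cell data.frames
#'
#' Convenience used by the feature modules: returns, for each retained tile,
#' the cells assigned to it together with the tile's rectangle (the window
#' used for Ripley edge correction).
#'
#' @param table A [cell_table()].
#' @param tiling Result of [build_tiles()] on the same table.
#' @return Named list (by `tile_id`) of lists with `cells` (data.frame) and
#'   `window` (`c(x0, x1, y0, y1)` in microns).
#' @export
tile_cells <- function(table, tiling) {
  keep <- tiling$tiles[tiling$tiles$retained, , drop = FALSE]
  out <- lapply(seq_len(nrow(keep)), function(i) {
    tid <- keep$tile_id[i]
    list(cells = table$cells[tiling$assignment == tid, , drop = FALSE],
         window = c(x0 = keep$x0[i], x1 = keep$x1[i],
                    y0 = keep$y0[i], y1 = keep$y1[i]))
  })
  names(out) <- keep$tile_id
  out
}
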