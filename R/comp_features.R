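#' Per-tile cell-state proportions
#'
#' For each catalog state S, the fraction of tile cells belonging to S under
#' superset membership. Because a cell can belong to several states, the
#' proportions of non-stromal states need not sum to 1; the stromal
#' proportion plus the fraction of cells in at least one non-stromal state
#' always equals 1.
#'
#' @param cells Per-tile cell data.frame (as produced by [tile_cells()]).
#' @param catalog A [enumerate_states()] catalog.
#' @return Named numeric vector, names `comp/<state label>`.
#' @export
state_proportions <- function(cells, catalog) {
  n <- nrow(cells)
  if (n == 0L) stop("cannot compute state proportions of an empty tile")
  memb <- state_membership(as.matrix(cells[, catalog$panel$markers,
                                           drop = FALSE]), catalog)
  p <- colSums(memb) / n
  names(p) <- paste0("comp/", colnames(memb))
  p
}

#' Per-tile subpopulation marker proportions
#'
#' For every ordered marker pair (X, Y), X != Y: the fraction of X-positive
#' tile cells that are also Y-positive, `P(Y+ | X+)`. When the tile has no
#' X-positive cell the proportion is missing (`NA`), never 0 — absence of
#' evidence is kept distinct from evidence of absence.
#'
#' @param cells Per-tile cell data.frame.
#' @param markers Character vector of panel markers.
#' @return Named numeric vector, names `subpop/<Y>_in_<X>`.
#' @export
subpop_proportions <- function(cells, markers) {
  pos <- as.matrix(cells[, markers, drop = FALSE]) * 1L
  nx <- colSums(pos)
  co <- crossprod(pos)  # co[X, Y] = |X+ & Y+|
  out <- numeric(0)
  for (x in markers) {
    for (y in setdiff(markers, x)) {
      v <- if (nx[[x]] == 0L) NA_real_ else co[x, y] / nx[[x]]
      out[paste0("subpop/", y, "_in_", x)] <- v
    }
  }
  out
}
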