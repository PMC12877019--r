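# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except temporary files the tests themselves write.

fx_panel <- function() lymphoid_panel()

# build a cell_table from centroids + a list of positive-marker sets
fx_cells <- function(xy, marker_sets, slide_id = "T1",
                     response = "unknown", panel = fx_panel()) {
  n <- nrow(xy)
  df <- data.frame(
    cell_id = sprintf("%s_%03d", slide_id, seq_len(n)),
    x_min = xy[, 1], x_max = xy[, 1], y_min = xy[, 2], y_max = xy[, 2],
    x_c = xy[, 1], y_c = xy[, 2], stringsAsFactors = FALSE)
  for (m in panel$markers) {
    df[[m]] <- vapply(marker_sets, function(s) m %in% s, logical(1))
  }
  cell_table(df, panel, slide_id, response)
}

# random tile: n cells uniform in a square window with random marker calls
fx_random_tile <- function(n, extent = 1000, p_pos = 0.2, panel = fx_panel()) {
  xy <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  sets <- lapply(seq_len(n), function(i) {
    panel$markers[runif(8) < p_pos]
  })
  fx_cells(xy, sets)
}

# small labelled feature table for classifier tests: 6 slides x 12 tiles,
# signal planted in the first compositional feature
fx_feature_table <- function(seed = 1, signal = 1.5) {
  set.seed(seed)
  slides <- c("R1", "R2", "R3", "N1", "N2", "N3")
  resp <- rep(c("responder", "non-responder"), each = 3)
  rows <- list()
  for (s in seq_along(slides)) {
    for (t in 1:12) {
      shift <- if (resp[s] == "responder") signal else 0
      rows[[length(rows) + 1L]] <- data.frame(
        tile_id = paste0(slides[s], ":", t), slide_id = slides[s],
        response = resp[s], n_cells = 200L,
        `comp/A` = rnorm(1, shift), `comp/B` = rnorm(1),
        `subpop/Y_in_X` = runif(1), `rcn/RCN1` = runif(1),
        `rcn/RCN2` = runif(1), `ripley/dL20/A|A` = rnorm(1),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
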