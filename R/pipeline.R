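#' Compute the full per-tile feature table for a cohort
#'
#' Orchestrates the pipeline stages over a list of slides: 1 mm tiling,
#' cell-state catalog (unless supplied), compositional features (cell-state
#' and subpopulation proportions), RCN features (60 um neighborhood
#' profiles, elbow-selected or fixed-k k-means, per-tile proportions), and
#' Ripley's L features. Returns one row per retained tile with namespaced
#' feature columns (`comp/`, `subpop/`, `rcn/`, `ripley/`) plus metadata.
#'
#' @param tables List of [cell_table()]s (one per slide, shared panel).
#' @param catalog Optional [enumerate_states()] catalog; built from the
#'   cohort (with `top_n`) when `NULL`.
#' @param top_n Catalog size parameter when building the catalog.
#' @param tile_size,min_cells Tiling parameters (microns / cells), see
#'   [build_tiles()].
#' @param rcn_k `"auto"` for elbow selection, an integer for fixed k, or
#'   `NULL` to skip RCN features.
#' @param rcn_radius Neighborhood radius in microns (default 60).
#' @param k_range Candidate k values for the elbow scan.
#' @param ripley Compute Ripley features (default TRUE; the slowest stage).
#' @param ripley_radii Report radii for Ripley features.
#' @param seed Seed for the RCN clustering stages.
#' @return List with `features` (TileFeatureTable data.frame), `catalog`,
#'   `rcn_model` (or NULL), `tilings`.
#' @export
compute_tile_features <- function(tables, catalog = NULL, top_n = 20,
                                  tile_size = 1000, min_cells = 100,
                                  rcn_k = "auto", rcn_radius = 60,
                                  k_range = 2:12,
                                  ripley = TRUE,
                                  ripley_radii = c(20, 30, 60, 90),
                                  seed = 1) {
  stopifnot(length(tables) >= 1)
  if (is.null(catalog)) catalog <- enumerate_states(tables, top_n = top_n)
  tilings <- lapply(tables, build_tiles, tile_size = tile_size,
                    min_cells = min_cells)

  rows <- list()
  for (s in seq_along(tables)) {
    tc <- tile_cells(tables[[s]], tilings[[s]])
    for (tid in names(tc)) {
      cells <- tc[[tid]]$cells
      feats <- c(state_proportions(cells, catalog),
                 subpop_proportions(cells, catalog$panel$markers))
      if (ripley) {
        feats <- c(feats, ripley_tile_features(cells, catalog,
                                               tc[[tid]]$window,
                                               radii = ripley_radii))
      }
      rows[[tid]] <- c(list(tile_id = tid,
                            slide_id = tables[[s]]$slide_id,
                            response = tables[[s]]$response,
                            n_cells = nrow(cells)),
                       as.list(feats))
    }
  }
  features <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(features) <- NULL

  rcn_model <- NULL
  if (!is.null(rcn_k)) {
    prof <- cohort_profiles(tables, tilings, catalog, radius = rcn_radius)
    k <- if (identical(rcn_k, "auto")) {
      select_k_elbow(prof$profiles, k_range = k_range, seed = seed)
    } else {
      as.integer(rcn_k)
    }
    rcn_model <- fit_rcn(prof$profiles, k, seed = seed)
    rcn_model$cell_id <- prof$cell_id
    rcn_model$tile_id <- prof$tile_id
    rcn <- rcn_tile_proportions(rcn_model, prof$tile_id)
    features <- merge(features, rcn, by = "tile_id", sort = FALSE)
  }
  features <- features[order(features$tile_id), , drop = FALSE]
  rownames(features) <- NULL
  list(features = features, catalog = catalog, rcn_model = rcn_model,
       tilings = tilings)
}
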