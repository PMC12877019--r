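#' Cellular-neighborhood composition profiles
#'
#' Every cell in a retained tile acts as a seed; its neighborhood is the set
#' of tile cells (seed included) whose centroid lies within `radius` of the
#' seed centroid (<= convention at the boundary). The profile is the
#' cell-state proportion vector of the neighborhood. Neighborhoods are
#' tile-bounded: they never reach across tile borders.
#'
#' @param cells Per-tile cell data.frame.
#' @param catalog A [enumerate_states()] catalog.
#' @param radius Neighborhood radius in microns (default 60).
#' @param tile_id Tile identifier carried into the output.
#' @return List with `profiles` (cells x states numeric matrix of
#'   proportions), `cell_id`, `tile_id`, `n_neighbors` (integer vector,
#'   seed included).
#' @export
neighborhood_profiles <- function(cells, catalog, radius = 60, tile_id = NA) {
  n <- nrow(cells)
  if (n == 0L) stop("empty tile")
  memb <- state_membership(as.matrix(cells[, catalog$panel$markers,
                                           drop = FALSE]), catalog) * 1
  dx <- outer(cells$x_c, cells$x_c, "-")
  dy <- outer(cells$y_c, cells$y_c, "-")
  adj <- (dx * dx + dy * dy) <= radius * radius   # includes the diagonal
  counts <- adj %*% memb
  nn <- rowSums(adj)
  list(profiles = counts / nn,
       cell_id = cells$cell_id,
       tile_id = rep(tile_id, n),
       n_neighbors = as.integer(nn))
}

#' Neighborhood profiles for a whole cohort
#'
#' Runs [neighborhood_profiles()] over every retained tile of every slide.
#'
#' @param tables List of [cell_table()]s.
#' @param tilings List of [build_tiles()] results aligned with `tables`.
#' @param catalog A [enumerate_states()] catalog.
#' @param radius Neighborhood radius in microns.
#' @return List with `profiles` matrix, `cell_id`, `slide_id`, `tile_id`.
#' @export
cohort_profiles <- function(tables, tilings, catalog, radius = 60) {
  acc <- list()
  for (s in seq_along(tables)) {
    tc <- tile_cells(tables[[s]], tilings[[s]])
    for (tid in names(tc)) {
      np <- neighborhood_profiles(tc[[tid]]$cells, catalog, radius, tid)
      acc[[length(acc) + 1L]] <- list(
        profiles = np$profiles, cell_id = np$cell_id,
        slide_id = rep(tables[[s]]$slide_id, length(np$cell_id)),
        tile_id = np$tile_id)
    }
  }
  list(profiles = do.call(rbind, lapply(acc, `[[`, "profiles")),
       cell_id = unlist(lapply(acc, `[[`, "cell_id")),
       slide_id = unlist(lapply(acc, `[[`, "slide_id")),
       tile_id = unlist(lapply(acc, `[[`, "tile_id")))
}

# canonical row order: lexicographic over profile columns. Fitting on
# canonically ordered rows makes k-means results invariant to input row order.
canonical_order <- function(m) do.call(order, as.data.frame(m))

#' Elbow selection of the k-means cluster count
#'
#' Fits k-means for each k in `k_range` (fixed seed, canonical row order)
#' and returns the smallest k whose relative WCSS decrease to k + 1 falls
#' below `tau`: `(WCSS(k) - WCSS(k+1)) / WCSS(k) < tau`. The elbow rule
#' operationalises "increase k until the within-cluster sum of squares stops
#' decreasing" for a quantity that strictly decreases.
#'
#' @param profiles Numeric matrix of neighborhood profiles (rows = cells).
#' @param k_range Candidate k values, a contiguous range within 2..20
#'   (default `2:12`).
#' @param tau Relative-decrease threshold (default 0.10).
#' @param seed Integer RNG seed.
#' @param max_points Profiles are subsampled (seeded, canonical order) to at
#'   most this many rows for the WCSS scan (default 20000).
#' @param nstart,iter.max Passed to [stats::kmeans()].
#' @return Selected k (integer), with attribute `wcss` (named vector).
#' @export
select_k_elbow <- function(profiles, k_range = 2:12, tau = 0.10, seed = 1,
                           max_points = 20000, nstart = 5, iter.max = 50) {
  stopifnot(min(k_range) >= 2, max(k_range) <= 20)
  k_range <- sort(k_range)
  m <- as.matrix(profiles)
  m <- m[canonical_order(m), , drop = FALSE]
  set.seed(seed)
  if (nrow(m) > max_points) m <- m[sample.int(nrow(m), max_points), , drop = FALSE]
  if (nrow(m) < max(k_range)) stop("need at least max(k_range) profiles")
  ks <- c(k_range, max(k_range) + 1L)
  wcss <- vapply(ks, function(k) {
    set.seed(seed + k)
    stats::kmeans(m, centers = k, nstart = nstart, iter.max = iter.max)$tot.withinss
  }, numeric(1))
  names(wcss) <- ks
  k <- elbow_pick(wcss, ks, tau)
  structure(as.integer(k), wcss = wcss[as.character(k_range)])
}

# smallest k whose relative WCSS decrease to k+1 falls below tau;
# wcss is ordered by increasing k (the last k serves only as lookahead)
elbow_pick <- function(wcss, k_values, tau = 0.10) {
  rel <- (utils::head(wcss, -1) - utils::tail(wcss, -1)) / utils::head(wcss, -1)
  hit <- which(rel < tau)
  if (length(hit) == 0L) {
    warning("no elbow found in k_range; returning the largest candidate")
    return(k_values[length(k_values) - 1L])
  }
  k_values[hit[1L]]
}

#' Fit recurrent cellular neighborhoods by k-means
#'
#' Clusters neighborhood profiles with k-means (Euclidean, canonical row
#' order for row-order invariance) and relabels clusters by descending size:
#' RCN1 is the largest. When more than `max_fit_points` profiles are given,
#' centers are fitted on a seeded uniform subsample and all profiles are
#' then assigned to the nearest center.
#'
#' @param profiles Numeric matrix of neighborhood profiles.
#' @param k Number of clusters (>= 2).
#' @param seed Integer RNG seed.
#' @param max_fit_points Subsample ceiling for fitting (default 500000).
#' @param nstart,iter.max Passed to [stats::kmeans()].
#' @return Object of class `rcn_model`: list with `k`, `centers`
#'   (k x states, rows named RCN1..RCNk), `sizes`, `labels` (integer RCN id
#'   per profile row), `seed`.
#' @export
fit_rcn <- function(profiles, k, seed = 1, max_fit_points = 500000,
                    nstart = 5, iter.max = 50) {
  m <- as.matrix(profiles)
  if (k < 2) stop("k must be >= 2")
  if (nrow(unique(m)) < k) stop("k exceeds the number of distinct profiles")
  ord <- canonical_order(m)
  mfit <- m[ord, , drop = FALSE]
  set.seed(seed)
  if (nrow(mfit) > max_fit_points) {
    mfit <- mfit[sample.int(nrow(mfit), max_fit_points), , drop = FALSE]
  }
  set.seed(seed)
  km <- stats::kmeans(mfit, centers = k, nstart = nstart, iter.max = iter.max)
  centers <- km$centers
  # assign every profile to its nearest center
  d2 <- outer(rowSums(m * m), rep(1, k)) - 2 * m %*% t(centers) +
    outer(rep(1, nrow(m)), rowSums(centers * centers))
  lab <- max.col(-d2, ties.method = "first")
  sizes <- tabulate(lab, nbins = k)
  if (any(sizes == 0L)) stop("empty RCN cluster after assignment; reduce k")
  o <- order(-sizes)
  relabel <- integer(k); relabel[o] <- seq_len(k)
  lab <- relabel[lab]
  centers <- centers[o, , drop = FALSE]
  rownames(centers) <- paste0("RCN", seq_len(k))
  structure(list(k = as.integer(k), centers = centers,
                 sizes = sizes[o], labels = lab, seed = seed),
            class = "rcn_model")
}

#' @export
print.rcn_model <- function(x, ...) {
  cat("<rcn_model> k =", x$k, "| sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-tile RCN proportions
#'
#' @param model A [fit_rcn()] model.
#' @param tile_id Tile id per profiled cell (aligned with `model$labels`).
#' @return data.frame keyed by `tile_id` with columns `rcn/RCN1` ..
#'   `rcn/RCNk`; rows sum to 1.
#' @export
rcn_tile_proportions <- function(model, tile_id) {
  stopifnot(inherits(model, "rcn_model"),
            length(tile_id) == length(model$labels))
  tab <- table(tile_id, factor(model$labels, levels = seq_len(model$k)))
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  out <- data.frame(tile_id = rownames(prop), stringsAsFactors = FALSE)
  for (j in seq_len(model$k)) out[[paste0("rcn/RCN", j)]] <- prop[, j]
  rownames(out) <- NULL
  out
}
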