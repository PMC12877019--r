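#' Isotropic edge-correction weight in a rectangular window
#'
#' Ripley's isotropic correction: the weight of a point pair is the
#' reciprocal of the fraction of the circle centred at one point, with
#' radius equal to the pair distance, that lies inside the observation
#' window. For a rectangle the outside arc is computed analytically: each
#' edge closer than `d` removes an arc of angle `2*acos(a/d)` (a = distance
#' to the edge), and arcs overlapping at a corner (when `a_i^2 + a_j^2 <
#' d^2` for adjacent edges) are added back with angle
#' `acos(a_i/d) + acos(a_j/d) - pi/2`.
#'
#' @param x,y Coordinates of the circle centre(s), inside the window.
#' @param d Radius (pair distance), same length as `x`/`y` or scalar.
#' @param window Numeric vector `c(x0, x1, y0, y1)`.
#' @param floor Minimum inside fraction; smaller fractions (possible only for
#'   radii comparable to the window size at a corner) are capped to avoid
#'   weight blow-up, and a warning is issued.
#' @return Numeric vector of weights, each `>= 1`.
#' @export
isotropic_weight <- function(x, y, d, window, floor = 1e-3) {
  x0 <- window[[1]]; x1 <- window[[2]]; y0 <- window[[3]]; y1 <- window[[4]]
  if (any(x < x0 | x > x1 | y < y0 | y > y1)) {
    stop("circle centre outside the window")
  }
  if (any(d <= 0)) stop("radius must be positive")
  n <- max(length(x), length(d))
  x <- rep_len(x, n); y <- rep_len(y, n); d <- rep_len(d, n)

  a_l <- x - x0; a_r <- x1 - x; a_b <- y - y0; a_t <- y1 - y
  edge_arc <- function(a) ifelse(a < d, 2 * acos(pmin(a / d, 1)), 0)
  corner_arc <- function(a1, a2) {
    hit <- (a1 * a1 + a2 * a2) < d * d
    ifelse(hit,
           acos(pmin(a1 / d, 1)) + acos(pmin(a2 / d, 1)) - pi / 2,
           0)
  }
  outside <- edge_arc(a_l) + edge_arc(a_r) + edge_arc(a_b) + edge_arc(a_t) -
    corner_arc(a_l, a_b) - corner_arc(a_l, a_t) -
    corner_arc(a_r, a_b) - corner_arc(a_r, a_t)
  frac <- 1 - outside / (2 * pi)
  capped <- frac < floor
  if (any(capped)) {
    warning(sum(capped), " pair(s) capped at inside-fraction floor ", floor)
    frac[capped] <- floor
  }
  1 / frac
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Cross-type Ripley's K and L for two point sets in a tile
#'
#' Estimates
#' \deqn{\hat K_{AB}(r) = \frac{|W|}{n_A n_B} \sum_{i \in A}\sum_{j \in B, j \ne i}
#'   w_{ij}\, 1(d_{ij} \le r)}
#' with the symmetrised isotropic edge weight
#' `w_ij = (1/f_i + 1/f_j) / 2` (f = inside fraction at each endpoint), so
#' that `K(A, B) = K(B, A)` exactly. `L = sqrt(K/pi)` variance-stabilises K;
#' under complete spatial randomness `L(r) = r`, so `delta_L = L - r` is
#' positive for clustering and negative for repulsion. The cluster score is
#' the trapezoidal integral of `delta_L` over `r` in `[0, 100]` microns.
#'
#' @param xyA,xyB Two-column matrices (x, y) of cell centroids in microns.
#'   For a univariate (A = B) curve pass the same matrix twice with matching
#'   `idA`/`idB` (or leave ids `NULL` and identical row order).
#' @param window Tile rectangle `c(x0, x1, y0, y1)` in microns.
#' @param r_grid Increasing radii in microns (default 0:100, 1 um steps).
#' @param idA,idB Optional cell-id vectors used to exclude self pairs when a
#'   cell appears in both sets; identical matrices with `NULL` ids are
#'   treated as the same point set.
#' @param correction `"isotropic"` (default) or `"none"` (all weights 1;
#'   uncorrected estimator, mainly for cross-checks).
#' @return Object of class `ripley_curve`: list with `r`, `K`, `L`,
#'   `L_theo`, `delta_L`, `cluster_score`, `n_A`, `n_B`.
#' @export
ripley_cross_K <- function(xyA, xyB, window, r_grid = 0:100,
                           idA = NULL, idB = NULL,
                           correction = c("isotropic", "none")) {
  correction <- match.arg(correction)
  xyA <- as.matrix(xyA); xyB <- as.matrix(xyB)
  nA <- nrow(xyA); nB <- nrow(xyB)
  if (nA < 1L || nB < 1L) stop("both point sets must be non-empty")
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be increasing")
  same <- is.null(idA) && is.null(idB) && nA == nB && isTRUE(all.equal(xyA, xyB))
  if (same && nA < 2L) stop("univariate K needs at least 2 points")

  dx <- outer(xyA[, 1], xyB[, 1], "-")
  dy <- outer(xyA[, 2], xyB[, 2], "-")
  dmat <- sqrt(dx * dx + dy * dy)
  self <- if (same) {
    diag(nA) == 1
  } else if (!is.null(idA) && !is.null(idB)) {
    outer(idA, idB, "==")
  } else {
    matrix(FALSE, nA, nB)
  }
  keep <- !self & dmat <= max(r_grid) & dmat > 0
  ii <- row(dmat)[keep]; jj <- col(dmat)[keep]; dd <- dmat[keep]

  area <- (window[[2]] - window[[1]]) * (window[[4]] - window[[3]])
  if (length(dd)) {
    if (correction == "isotropic") {
      wA <- isotropic_weight(xyA[ii, 1], xyA[ii, 2], dd, window)
      wB <- isotropic_weight(xyB[jj, 1], xyB[jj, 2], dd, window)
      w <- (wA + wB) / 2
    } else {
      w <- rep(1, length(dd))
    }
    Ksum <- vapply(r_grid, function(r) sum(w[dd <= r]), numeric(1))
  } else {
    Ksum <- numeric(length(r_grid))
  }
  K <- area / (nA * nB) * Ksum
  L <- sqrt(K / pi)
  delta_L <- L - r_grid
  in100 <- r_grid <= 100
  score <- if (sum(in100) >= 2) trapz(r_grid[in100], delta_L[in100]) else NA_real_
  structure(list(r = r_grid, K = K, L = L, L_theo = r_grid,
                 delta_L = delta_L, cluster_score = score,
                 n_A = nA, n_B = nB),
            class = "ripley_curve")
}

#' Proximity score between two cell states in a tile
#'
#' Counts cell pairs of states A and B strictly closer than `radius`
#' (bipartite count for A != B with self distances excluded; unordered
#' distinct pairs for A = B) and normalises by the sum of the two states'
#' tile proportions. Missing when either state is absent from the tile.
#'
#' @param cells Per-tile cell data.frame.
#' @param catalog A [enumerate_states()] catalog.
#' @param state_a,state_b State labels from the catalog.
#' @param radius Distance threshold in microns (paper uses 20/30/60/90).
#' @return List with `count`, `prop_a`, `prop_b`, `score` (`NA` when either
#'   state is absent).
#' @export
proximity_score <- function(cells, catalog, state_a, state_b, radius) {
  memb <- state_membership(as.matrix(cells[, catalog$panel$markers,
                                           drop = FALSE]), catalog)
  if (!state_a %in% colnames(memb) || !state_b %in% colnames(memb)) {
    stop("state not in catalog: ", state_a, " / ", state_b)
  }
  n <- nrow(cells)
  ia <- which(memb[, state_a]); ib <- which(memb[, state_b])
  prop_a <- length(ia) / n; prop_b <- length(ib) / n
  if (length(ia) == 0L || length(ib) == 0L) {
    return(list(count = NA_integer_, prop_a = prop_a, prop_b = prop_b,
                score = NA_real_))
  }
  dx <- outer(cells$x_c[ia], cells$x_c[ib], "-")
  dy <- outer(cells$y_c[ia], cells$y_c[ib], "-")
  d <- sqrt(dx * dx + dy * dy)
  hit <- d < radius & !outer(ia, ib, "==")
  count <- if (state_a == state_b) sum(hit) / 2L else sum(hit)
  list(count = as.integer(count), prop_a = prop_a, prop_b = prop_b,
       score = count / (prop_a + prop_b))
}

#' Per-tile proximity-score features for all state pairs
#'
#' @param cells Per-tile cell data.frame.
#' @param catalog A [enumerate_states()] catalog.
#' @param radii Distance thresholds in microns (default `c(20, 30, 60, 90)`).
#' @return Named numeric vector `prox/r<radius>/<A>|<B>` over unordered state
#'   pairs (catalog order), `NA` where a state is absent.
#' @export
proximity_tile_features <- function(cells, catalog, radii = c(20, 30, 60, 90)) {
  labs <- catalog$states$label
  out <- numeric(0)
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      for (r in radii) {
        ps <- proximity_score(cells, catalog, labs[i], labs[j], r)
        out[paste0("prox/r", r, "/", labs[i], "|", labs[j])] <- ps$score
      }
    }
  }
  out
}

# Shared per-tile machinery: pair triplets (i, j, distance <= r_max, symmetric
# isotropic weight) computed once and reused across all state pairs.
tile_pair_triplets <- function(cells, window, r_max = 100) {
  n <- nrow(cells)
  x <- cells$x_c; y <- cells$y_c
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dmat <- sqrt(dx * dx + dy * dy)
  keep <- dmat <= r_max & row(dmat) != col(dmat)
  ii <- row(dmat)[keep]; jj <- col(dmat)[keep]; dd <- dmat[keep]
  if (length(dd)) {
    pos <- dd > 0
    w <- numeric(length(dd))
    if (any(pos)) {
      wi <- isotropic_weight(x[ii[pos]], y[ii[pos]], dd[pos], window)
      wj <- isotropic_weight(x[jj[pos]], y[jj[pos]], dd[pos], window)
      w[pos] <- (wi + wj) / 2
    }
  } else {
    w <- numeric(0)
  }
  area <- (window[[2]] - window[[1]]) * (window[[4]] - window[[3]])
  list(ii = ii, jj = jj, d = dd, w = w, n = n, area = area)
}

#' Per-tile Ripley's L features for all state pairs
#'
#' For every unordered pair of catalog states (including self pairs and the
#' stromal state): `L_iso` and `delta_L` at each radius, plus the cluster
#' score (integral of `delta_L` over 0-100 um). Pairs with an absent state
#' (or a self pair with fewer than 2 cells) are missing.
#'
#' @param cells Per-tile cell data.frame.
#' @param catalog A [enumerate_states()] catalog.
#' @param window Tile rectangle `c(x0, x1, y0, y1)` in microns.
#' @param radii Report radii in microns (default `c(20, 30, 60, 90)`).
#' @param r_max Upper integration limit in microns (default 100); the
#'   internal grid is 1 um steps from 0 to `r_max`.
#' @return Named numeric vector with entries
#'   `ripley/L<r>/<A>|<B>`, `ripley/dL<r>/<A>|<B>`, `ripley/score/<A>|<B>`.
#' @export
ripley_tile_features <- function(cells, catalog, window,
                                 radii = c(20, 30, 60, 90), r_max = 100) {
  trip <- tile_pair_triplets(cells, window, r_max)
  memb <- state_membership(as.matrix(cells[, catalog$panel$markers,
                                           drop = FALSE]), catalog)
  labs <- catalog$states$label
  r_grid <- 0:r_max
  # bin index of each triplet distance: d in (b-1, b] -> bin b (d = 0 never
  # occurs here; coincident centroids are excluded from the weighted sum)
  bin <- pmin(ceiling(trip$d), r_max)
  bin[trip$d == 0] <- 1L

  out <- numeric(0)
  for (a in seq_along(labs)) {
    mA <- memb[, a]
    iA <- mA[trip$ii]
    nA <- sum(mA)
    for (b in a:length(labs)) {
      mB <- memb[, b]
      nB <- sum(mB)
      pair <- paste0(labs[a], "|", labs[b])
      ok <- nA >= 1 && nB >= 1 && !(a == b && nA < 2)
      if (!ok) {
        for (r in radii) {
          out[paste0("ripley/L", r, "/", pair)] <- NA_real_
          out[paste0("ripley/dL", r, "/", pair)] <- NA_real_
        }
        out[paste0("ripley/score/", pair)] <- NA_real_
        next
      }
      sel <- iA & mB[trip$jj] & trip$d > 0
      if (any(sel)) {
        sums <- rowsum(trip$w[sel], bin[sel])
        Kbin <- numeric(r_max)
        Kbin[as.integer(rownames(sums))] <- sums
        Ksum <- c(0, cumsum(Kbin))
      } else {
        Ksum <- numeric(r_max + 1)
      }
      K <- trip$area / (nA * nB) * Ksum
      L <- sqrt(K / pi)
      dL <- L - r_grid
      for (r in radii) {
        out[paste0("ripley/L", r, "/", pair)] <- L[r + 1L]
        out[paste0("ripley/dL", r, "/", pair)] <- dL[r + 1L]
      }
      out[paste0("ripley/score/", pair)] <- trapz(r_grid, dL)
    }
  }
  out
}
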