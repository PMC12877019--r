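#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used to score
#' planted-structure recovery (e.g. RCN membership against ground-truth
#' niche cells).
#'
#' @param a,b Vectors of cluster labels (any type), same length.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Score RCN recovery of planted niches
#'
#' For every RCN of a fitted model, computes the adjusted Rand index between
#' the binary partition "cell in this RCN" and the ground-truth "cell in a
#' planted niche" partition, and returns the best match.
#'
#' @param model A [fit_rcn()] model fitted through [compute_tile_features()]
#'   (so it carries `cell_id`).
#' @param ground_truth Ground-truth data.frame from [generate_cohort()].
#' @return List: `ari` (best ARI), `rcn` (best-matching RCN id).
#' @export
niche_recovery_ari <- function(model, ground_truth) {
  stopifnot(inherits(model, "rcn_model"), !is.null(model$cell_id))
  truth <- ground_truth$in_niche[match(model$cell_id, ground_truth$cell_id)]
  stopifnot(!anyNA(truth))
  aris <- vapply(seq_len(model$k), function(j) {
    adjusted_rand_index(model$labels == j, truth)
  }, numeric(1))
  list(ari = max(aris), rcn = which.max(aris))
}
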