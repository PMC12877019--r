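#' Default marker co-expression probabilities for synthetic cells
#'
#' Bernoulli positivity probabilities per latent cell type over the eight
#' lymphoid-panel markers. Co-expression is induced only through latent
#' types (draws are independent given the type), keeping ground truth
#' interpretable. The stromal row is all zero, so stromal cells match the
#' marker-negative definition of the stromal population. The `niche` type
#' emulates a tumor-infiltrating-lymphocyte niche: co-positivity for CD8,
#' the checkpoint markers PD-L1 and LAG-3, the melanoma marker SOX10 and
#' iNOS.
#'
#' @return Numeric matrix, latent types x markers.
#' @export
default_marker_probs <- function() {
  mk <- lymphoid_panel()$markers
  m <- rbind(
    stromal     = c(0,    0,    0,    0,    0,    0,    0,    0),
    tumor       = c(0.15, 0.005, 0.05, 0.005, 0.01, 0.02, 0.90, 0.01),
    t_cell      = c(0.02, 0.01, 0.02, 0.05, 0.05, 0.01, 0.01, 0.95),
    cytotoxic_t = c(0.05, 0.01, 0.05, 0.10, 0.90, 0.01, 0.01, 0.90),
    b_cell      = c(0.01, 0.90, 0.02, 0.01, 0.01, 0.01, 0.01, 0.10),
    niche       = c(0.60, 0.02, 0.70, 0.60, 0.80, 0.02, 0.50, 0.50)
  )
  colnames(m) <- mk
  m
}

#' Synthetic-cohort configuration
#'
#' Defines the generative model for a synthetic mIF cohort: homogeneous
#' Poisson stroma, Thomas-process tumor nests (Poisson parents with
#' Gaussian-dispersed offspring), Poisson immune infiltrates, and — on
#' responder slides — planted TIL-like niches (disks whose cells draw from
#' the `niche` latent type) plus an elevated iNOS positivity among CD8+
#' cytotoxic T cells. The `effect` preset scales the responder signal:
#' `"null"` plants nothing (no group difference), `"weak"` 2 niches per
#' responder slide and +0.15 iNOS shift, `"strong"` 4 niches and +0.30.
#'
#' Intensities are in cells per mm^2; lengths in microns.
#'
#' @param effect Effect preset, one of `"null"`, `"weak"`, `"strong"`.
#' @param n_responders,n_nonresponders Cohort shape (default 4 and 8).
#' @param extent Slide extent `c(width, height)` in microns
#'   (default 3000 x 3000, i.e. 9 tiles).
#' @param stromal_intensity Background stroma, cells/mm^2.
#' @param tumor_parent_intensity,tumor_offspring_mean,tumor_sigma Thomas
#'   process: parent intensity (parents/mm^2), mean offspring per parent,
#'   Gaussian dispersion sigma (um).
#' @param immune_intensity Named vector of Poisson intensities for
#'   `t_cell`, `cytotoxic_t`, `b_cell` (cells/mm^2).
#' @param niche_count Niches per responder slide; `NULL` takes the preset
#'   value.
#' @param niche_radius Niche disk radius (um).
#' @param niche_intensity Cell intensity inside a niche disk (cells/mm^2).
#' @param inos_cd8_shift Additive shift of P(iNOS+ | cytotoxic_t) on
#'   responder slides; `NULL` takes the preset value.
#' @param marker_probs Latent-type x marker probability matrix
#'   (default [default_marker_probs()]).
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(effect = c("strong", "weak", "null"),
                             n_responders = 4, n_nonresponders = 8,
                             extent = c(3000, 3000),
                             stromal_intensity = 250,
                             tumor_parent_intensity = 3,
                             tumor_offspring_mean = 40,
                             tumor_sigma = 50,
                             immune_intensity = c(t_cell = 60,
                                                  cytotoxic_t = 30,
                                                  b_cell = 20),
                             niche_count = NULL,
                             niche_radius = 100,
                             niche_intensity = 3000,
                             inos_cd8_shift = NULL,
                             marker_probs = default_marker_probs(),
                             seed = 1) {
  effect <- match.arg(effect)
  preset <- switch(effect,
                   null = list(niches = 0L, shift = 0),
                   weak = list(niches = 2L, shift = 0.15),
                   strong = list(niches = 4L, shift = 0.30))
  if (is.null(niche_count)) niche_count <- preset$niches
  if (is.null(inos_cd8_shift)) inos_cd8_shift <- preset$shift
  stopifnot(all(extent > 1000), stromal_intensity >= 0,
            all(marker_probs >= 0 & marker_probs <= 1))
  structure(list(
    effect = effect, n_responders = n_responders,
    n_nonresponders = n_nonresponders, extent = extent,
    stromal_intensity = stromal_intensity,
    tumor_parent_intensity = tumor_parent_intensity,
    tumor_offspring_mean = tumor_offspring_mean, tumor_sigma = tumor_sigma,
    immune_intensity = immune_intensity,
    niche_count = as.integer(niche_count), niche_radius = niche_radius,
    niche_intensity = niche_intensity, inos_cd8_shift = inos_cd8_shift,
    marker_probs = marker_probs, seed = seed), class = "synthetic_config")
}

#' Designed scenario: responder signal confined to CD8-rich tiles
#'
#' A configuration in which the only responder effect is the planted
#' TIL-like niches (no cohort-wide marker shift) and the background CD8+
#' proportion sits well below 2%, so only niche-bearing tiles are CD8-rich.
#' Used to demonstrate the benefit of immune-high tile filtering on a
#' signal that is, by construction, confined to CD8-rich tiles.
#'
#' @param seed Integer RNG seed.
#' @return A [synthetic_config()].
#' @export
preset_cd8_confined <- function(seed = 1) {
  probs <- default_marker_probs()
  probs["t_cell", "CD8"] <- 0.02
  synthetic_config(
    effect = "strong", inos_cd8_shift = 0,
    immune_intensity = c(t_cell = 60, cytotoxic_t = 4, b_cell = 20),
    marker_probs = probs, seed = seed)
}

#' Sample one slide's spatial point pattern with latent types
#'
#' @param config A [synthetic_config()].
#' @param role `"responder"` or `"non-responder"`; responder slides receive
#'   the planted niches.
#' @param seed Integer RNG seed for this slide.
#' @return data.frame: `x`, `y` (um), `latent` (type), `in_niche` (logical).
#' @export
sample_point_pattern <- function(config, role = c("non-responder", "responder"),
                                 seed = 1) {
  role <- match.arg(role)
  set.seed(seed)
  W <- config$extent
  area_mm2 <- prod(W) / 1e6
  total_intensity <- config$stromal_intensity +
    config$tumor_parent_intensity * config$tumor_offspring_mean +
    sum(config$immune_intensity)
  if (total_intensity * area_mm2 > 1e7) {
    stop("configured intensities imply more than 1e7 cells per slide")
  }
  pois_uniform <- function(lambda, latent) {
    n <- stats::rpois(1, lambda * area_mm2)
    data.frame(x = stats::runif(n, 0, W[1]), y = stats::runif(n, 0, W[2]),
               latent = rep(latent, n), in_niche = rep(FALSE, n))
  }
  parts <- list(pois_uniform(config$stromal_intensity, "stromal"))
  # tumor nests: Thomas process, offspring outside the window discarded
  n_par <- stats::rpois(1, config$tumor_parent_intensity * area_mm2)
  if (n_par > 0) {
    px <- stats::runif(n_par, 0, W[1]); py <- stats::runif(n_par, 0, W[2])
    noff <- stats::rpois(n_par, config$tumor_offspring_mean)
    ox <- rep(px, noff) + stats::rnorm(sum(noff), 0, config$tumor_sigma)
    oy <- rep(py, noff) + stats::rnorm(sum(noff), 0, config$tumor_sigma)
    keep <- ox >= 0 & ox <= W[1] & oy >= 0 & oy <= W[2]
    parts[[length(parts) + 1L]] <- data.frame(
      x = ox[keep], y = oy[keep],
      latent = rep("tumor", sum(keep)), in_niche = rep(FALSE, sum(keep)))
  }
  for (ty in names(config$immune_intensity)) {
    parts[[length(parts) + 1L]] <- pois_uniform(config$immune_intensity[[ty]], ty)
  }
  if (role == "responder" && config$niche_count > 0) {
    r <- config$niche_radius
    disk_mm2 <- pi * r * r / 1e6
    for (k in seq_len(config$niche_count)) {
      cx <- stats::runif(1, r, W[1] - r); cy <- stats::runif(1, r, W[2] - r)
      n <- stats::rpois(1, config$niche_intensity * disk_mm2)
      rr <- r * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
      parts[[length(parts) + 1L]] <- data.frame(
        x = cx + rr * cos(th), y = cy + rr * sin(th),
        latent = rep("niche", n), in_niche = rep(TRUE, n))
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Draw marker positivity from latent types
#'
#' Each marker is an independent Bernoulli draw with the probability of the
#' cell's latent type.
#'
#' @param latent Character vector of latent types.
#' @param probs Latent-type x marker probability matrix; every latent type
#'   present must have a row.
#' @param seed Integer RNG seed.
#' @return Logical matrix (cells x markers).
#' @export
assign_markers <- function(latent, probs, seed = 1) {
  missing_rows <- setdiff(unique(latent), rownames(probs))
  if (length(missing_rows)) {
    stop("no probability row for latent type(s): ",
         paste(missing_rows, collapse = ", "))
  }
  set.seed(seed)
  p <- probs[latent, , drop = FALSE]
  pos <- matrix(stats::runif(length(p)) < p, nrow = nrow(p),
                dimnames = list(NULL, colnames(probs)))
  pos
}

#' Generate a synthetic mIF cohort with ground truth
#'
#' Responder slides are named L1..Ln, non-responder slides S1..Sm (cohort
#' default: 4 responders, 8 non-responders). All randomness derives from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with:
#'   \item{tables}{list of [cell_table()]s (lymphoid panel, degenerate
#'     bounding boxes at the centroid).}
#'   \item{metadata}{data.frame: slide_id, response, sample_type.}
#'   \item{ground_truth}{data.frame: slide_id, cell_id, latent, in_niche.}
#'   \item{config}{the configuration used.}
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  panel <- lymphoid_panel()
  set.seed(config$seed)
  n_slides <- config$n_responders + config$n_nonresponders
  slide_seeds <- sample.int(.Machine$integer.max - 1L, n_slides)
  slide_ids <- c(paste0("L", seq_len(config$n_responders)),
                 paste0("S", seq_len(config$n_nonresponders)))
  roles <- rep(c("responder", "non-responder"),
               c(config$n_responders, config$n_nonresponders))

  tables <- vector("list", n_slides); gt <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    pts <- sample_point_pattern(config, roles[i], slide_seeds[i])
    probs <- config$marker_probs
    if (roles[i] == "responder" && config$inos_cd8_shift != 0) {
      probs["cytotoxic_t", "iNOS"] <-
        min(1, probs["cytotoxic_t", "iNOS"] + config$inos_cd8_shift)
    }
    pos <- assign_markers(pts$latent, probs, seed = slide_seeds[i] + 1L)
    cell_id <- sprintf("%s_%06d", slide_ids[i], seq_len(nrow(pts)))
    df <- data.frame(cell_id = cell_id,
                     x_min = pts$x, x_max = pts$x,
                     y_min = pts$y, y_max = pts$y,
                     x_c = pts$x, y_c = pts$y,
                     stringsAsFactors = FALSE)
    for (m in panel$markers) df[[m]] <- pos[, m]
    tables[[i]] <- cell_table(df, panel, slide_ids[i], roles[i], "resection")
    gt[[i]] <- data.frame(slide_id = slide_ids[i], cell_id = cell_id,
                          latent = pts$latent, in_niche = pts$in_niche,
                          stringsAsFactors = FALSE)
  }
  names(tables) <- slide_ids
  list(tables = tables,
       metadata = data.frame(slide_id = slide_ids, response = roles,
                             sample_type = "resection",
                             stringsAsFactors = FALSE),
       ground_truth = do.call(rbind, gt),
       config = config)
}
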