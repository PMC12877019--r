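#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotone enforcement, returned in the input
#' order (thin wrapper over [stats::p.adjust()], kept as a named surface so
#' the adjustment used across the package is one auditable choice).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s allowed and
#'   preserved).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum screen of tile features
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test per feature, responder
#' tiles versus non-responder tiles, on non-missing values; BH adjustment
#' across the tested feature family; fold change of group means. Tiles are
#' treated as independent observations — a deliberate, descriptive choice;
#' see [mixed_effects_screen()] for the slide-aware complement.
#'
#' @param features TileFeatureTable data.frame (feature columns + metadata).
#' @param labels Response label per row (`"responder"` / `"non-responder"`).
#' @param feature_cols Character vector of feature columns to test; default
#'   all columns whose name contains a namespace `/`.
#' @return data.frame: `feature`, `n_R`, `n_NR`, `mean_R`, `mean_NR`,
#'   `fold_change` (mean_R / mean_NR), `p_raw`, `p_adj`, `test`,
#'   `untestable`.
#' @export
wilcoxon_screen <- function(features, labels, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- grep("/", names(features), value = TRUE, fixed = TRUE)
  }
  is_r <- labels == "responder"
  if (!any(is_r) || !any(!is_r)) stop("both response groups must be non-empty")
  rows <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    vr <- v[is_r & !is.na(v)]; vn <- v[!is_r & !is.na(v)]
    untestable <- length(vr) == 0L || length(vn) == 0L
    p <- if (untestable) NA_real_ else {
      suppressWarnings(stats::wilcox.test(vr, vn, exact = NULL)$p.value)
    }
    if (!untestable && is.nan(p)) p <- 1   # all-tied (constant) feature
    mr <- if (length(vr)) mean(vr) else NA_real_
    mn <- if (length(vn)) mean(vn) else NA_real_
    fc <- if (!is.na(mr) && !is.na(mn) && mn > 0) mr / mn else NA_real_
    data.frame(feature = f, n_R = length(vr), n_NR = length(vn),
               mean_R = mr, mean_NR = mn, fold_change = fc,
               p_raw = p, untestable = untestable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res$test <- "wilcoxon"
  res
}

#' Within-group Pearson correlation of tile features
#'
#' Pairwise Pearson correlations across tiles, computed separately within
#' each response group, pairwise-complete on missing values.
#'
#' @param features TileFeatureTable data.frame.
#' @param labels Response label per row.
#' @param feature_cols Columns to correlate (default: all namespaced).
#' @return Named list of correlation matrices, one per group.
#' @export
group_correlations <- function(features, labels, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- grep("/", names(features), value = TRUE, fixed = TRUE)
  }
  out <- list()
  for (g in unique(labels)) {
    m <- as.matrix(features[labels == g, feature_cols, drop = FALSE])
    if (nrow(m) < 3L) stop("need at least 3 tiles per group, got ", nrow(m))
    out[[g]] <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  }
  out
}

#' Mixed-effects screen with slide as random effect
#'
#' Per feature: values are log10-transformed after adding a pseudo-count of
#' half the smallest non-zero value of that feature (proportions of zero are
#' common), then a linear mixed model `value ~ response + (1 | slide)` is
#' fitted by maximum likelihood and compared against the intercept-only
#' mixed model with a likelihood-ratio test. Features observed (non-missing)
#' in fewer than `min_slides_present` slides are skipped; BH adjustment runs
#' across the tested features. Singular fits are flagged and their p set to
#' missing.
#'
#' @param features TileFeatureTable data.frame.
#' @param labels Response label per row.
#' @param slide_ids Slide id per row.
#' @param min_slides_present Minimum number of slides with non-missing
#'   values (default 10).
#' @param log_transform Apply the log10 + pseudo-count transform
#'   (default TRUE; sensible for proportion-valued features).
#' @param feature_cols Columns to test (default: all namespaced).
#' @return data.frame: `feature`, `n_slides`, `mean_R`, `mean_NR`,
#'   `fold_change`, `p_raw`, `p_adj`, `singular`, `skipped`, `test`.
#' @export
mixed_effects_screen <- function(features, labels, slide_ids,
                                 min_slides_present = 10,
                                 log_transform = TRUE, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- grep("/", names(features), value = TRUE, fixed = TRUE)
  }
  grp <- factor(ifelse(labels == "responder", "responder", "non-responder"),
                levels = c("non-responder", "responder"))
  if (length(unique(slide_ids[grp == "responder"])) < 2L ||
      length(unique(slide_ids[grp == "non-responder"])) < 2L) {
    stop("need at least 2 slides per response group")
  }
  rows <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    ok <- !is.na(v)
    n_slides <- length(unique(slide_ids[ok]))
    base <- data.frame(feature = f, n_slides = n_slides,
                       mean_R = mean(v[ok & grp == "responder"]),
                       mean_NR = mean(v[ok & grp == "non-responder"]),
                       stringsAsFactors = FALSE)
    base$fold_change <- ifelse(base$mean_NR > 0, base$mean_R / base$mean_NR,
                               NA_real_)
    if (n_slides < min_slides_present) {
      return(cbind(base, p_raw = NA_real_, singular = FALSE, skipped = TRUE))
    }
    val <- v[ok]
    if (log_transform) {
      nz <- val[val > 0]
      pc <- if (length(nz)) min(nz) / 2 else 1e-6
      val <- log10(val + pc)
    }
    d <- data.frame(value = val, response = grp[ok],
                    slide = factor(slide_ids[ok]))
    fit <- tryCatch({
      m1 <- lme4::lmer(value ~ response + (1 | slide), data = d, REML = FALSE)
      m0 <- lme4::lmer(value ~ 1 + (1 | slide), data = d, REML = FALSE)
      sing <- lme4::isSingular(m1)
      p <- if (sing) NA_real_ else stats::anova(m0, m1)[2, "Pr(>Chisq)"]
      list(p = p, singular = sing)
    }, error = function(e) list(p = NA_real_, singular = TRUE))
    cbind(base, p_raw = fit$p, singular = fit$singular, skipped = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  tested <- !res$skipped
  res$p_adj[tested] <- bh_adjust(res$p_raw[tested])
  res$test <- "mixed_effects"
  res
}
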