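#' Gradient-boosted tree classifier backend
#'
#' Default classifier for [logo_cv()]: an xgboost binary classifier with
#' native missing-value handling and TreeSHAP attributions. The interface is
#' pluggable: any list with the same `fit` / `predict_prob` / `contrib`
#' functions can be passed as `classifier` in [model_config()] (set
#' `contrib = NULL` for backends without additive attributions; importance
#' then falls back to permutation importance).
#'
#' @param nrounds,max_depth,eta,min_child_weight,subsample,colsample_bytree
#'   Standard boosted tree hyperparameters. The default is an additive
#'   (depth-1 stump) ensemble: with a dozen patients, trees deep enough to
#'   form feature conjunctions memorise slide-specific feature fingerprints,
#'   and under leave-one-patient-out evaluation that pushes held-out slides
#'   of the minority class toward the majority region, depressing pooled AUC
#'   below chance even on unstructured data. Stumps keep the model to
#'   marginal feature effects, which both classifies planted signal well and
#'   stays near chance on no-signal cohorts. Deeper trees can be requested
#'   for larger cohorts.
#' @param ... Additional xgboost params.
#' @return List with `name`, `fit(X, y01, seed)`, `predict_prob(model, X)`,
#'   `contrib(model, X)`.
#' @export
classifier_xgboost <- function(nrounds = 100, max_depth = 1, eta = 0.1,
                               min_child_weight = 2,
                               subsample = 0.9, colsample_bytree = 0.9, ...) {
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, min_child_weight = min_child_weight,
                 subsample = subsample,
                 colsample_bytree = colsample_bytree, nthread = 1, ...)
  list(
    name = "xgboost",
    fit = function(X, y01, seed) {
      set.seed(seed)
      p <- params; p$seed <- seed
      # balance classes within every training fold: with leave-one-patient-out
      # CV the training class prior shifts with the held-out slide's class,
      # which otherwise biases pooled cross-fold probabilities
      if (sum(y01 == 1) > 0) {
        p$scale_pos_weight <- sum(y01 == 0) / sum(y01 == 1)
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = y01)
      xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                         verbose = 0)
    },
    predict_prob = function(model, X) {
      stats::predict(model, xgboost::xgb.DMatrix(X))
    },
    contrib = function(model, X) {
      stats::predict(model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
    }
  )
}

#' Model configuration for response classification
#'
#' @param mode Feature set: `"compositional"` (cell-state + subpopulation
#'   proportions), `"combined"` (+ RCN proportions + Ripley delta-L at
#'   20 um), or `"immune_high"` (combined, restricted to tiles with a CD8+
#'   cell proportion >= `cd8_threshold`).
#' @param cd8_threshold CD8+ tile-proportion cutoff for immune-high
#'   filtering, in `[0, 0.05]` (default 0.02, i.e. 2%).
#' @param n_iterations Number of repeated CV iterations (default 100).
#' @param seed Base RNG seed; iteration i uses `seed + i`.
#' @param classifier Classifier backend (default [classifier_xgboost()]).
#' @param feature_include Optional character vector restricting the feature
#'   columns (applied after mode selection).
#' @param cd8_feature Name of the CD8+ proportion column
#'   (default `"comp/CD8"`).
#' @return List of class `model_config`.
#' @export
model_config <- function(mode = c("compositional", "combined", "immune_high"),
                         cd8_threshold = 0.02, n_iterations = 100, seed = 1,
                         classifier = classifier_xgboost(),
                         feature_include = NULL, cd8_feature = "comp/CD8") {
  mode <- match.arg(mode)
  if (cd8_threshold < 0 || cd8_threshold > 0.05) {
    stop("cd8_threshold must lie in [0, 0.05]")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(mode = mode, cd8_threshold = cd8_threshold,
                 n_iterations = as.integer(n_iterations), seed = seed,
                 classifier = classifier, feature_include = feature_include,
                 cd8_feature = cd8_feature),
            class = "model_config")
}

#' Assemble the design matrix for a model mode
#'
#' Selects feature columns by namespace — compositional: `comp/` + `subpop/`;
#' combined: compositional plus `rcn/` and `ripley/dL20/`; immune-high:
#' combined restricted to tiles whose CD8+ proportion is at least the
#' threshold. Missing values are preserved as `NA`.
#'
#' @param features TileFeatureTable data.frame with metadata columns
#'   `tile_id`, `slide_id`, `response`.
#' @param config A [model_config()].
#' @return List: `X` (numeric matrix), `y` (character labels), `groups`
#'   (slide ids), `tile_id`, `dropped_slides` (slides with zero qualifying
#'   tiles under immune-high filtering).
#' @export
assemble_features <- function(features, config) {
  comp_cols <- grep("^(comp|subpop)/", names(features), value = TRUE)
  if (config$mode == "compositional") {
    cols <- comp_cols
  } else {
    cols <- c(comp_cols,
              grep("^rcn/", names(features), value = TRUE),
              grep("^ripley/dL20/", names(features), value = TRUE))
  }
  if (!is.null(config$feature_include)) {
    cols <- intersect(cols, config$feature_include)
  }
  if (!length(cols)) stop("no feature columns selected")
  keep <- rep(TRUE, nrow(features))
  dropped <- character(0)
  if (config$mode == "immune_high") {
    cd8 <- features[[config$cd8_feature]]
    if (is.null(cd8)) stop("missing CD8 feature column: ", config$cd8_feature)
    keep <- !is.na(cd8) & cd8 >= config$cd8_threshold
    dropped <- setdiff(unique(features$slide_id),
                       unique(features$slide_id[keep]))
  }
  X <- as.matrix(features[keep, cols, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = features$response[keep],
       groups = features$slide_id[keep],
       tile_id = features$tile_id[keep],
       dropped_slides = dropped)
}

#' Pooled classification metrics
#'
#' The eight reported metrics, computed from pooled tile predictions with
#' responder as the positive class: accuracy, ROC AUC (rank-based
#' Mann-Whitney form, ties averaged), AUPRC (average precision: step
#' integral of precision over recall), precision, recall, specificity,
#' balanced accuracy, F1. AUCs are missing when only one truth class is
#' present.
#'
#' @param truth Character vector of true labels.
#' @param prob Predicted responder probability.
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector of the 8 metrics.
#' @export
pool_metrics <- function(truth, prob, threshold = 0.5) {
  stopifnot(length(truth) == length(prob), length(truth) >= 1)
  pos <- truth == "responder"
  pred <- prob >= threshold
  tp <- sum(pos & pred); fp <- sum(!pos & pred)
  tn <- sum(!pos & !pred); fn <- sum(pos & !pred)
  acc <- (tp + tn) / length(truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- mean(c(rec, spec))
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  if (any(pos) && any(!pos)) {
    r <- rank(prob)
    auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
    auprc <- average_precision(pos, prob)
  } else {
    auc <- NA_real_; auprc <- NA_real_
  }
  c(accuracy = acc, roc_auc = auc, auprc = auprc, precision = prec,
    recall = rec, specificity = spec, balanced_accuracy = bal, f1 = f1)
}

# average precision with tied scores handled by threshold groups
average_precision <- function(pos, score) {
  o <- order(score, decreasing = TRUE)
  pos <- pos[o]; score <- score[o]
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(pos); n <- seq_along(pos)
  last <- !duplicated(grp, fromLast = TRUE)   # last index of each tie group
  tp_k <- tp[last]; n_k <- n[last]
  P <- tp_k / n_k
  R <- tp_k / sum(pos)
  sum(diff(c(0, R)) * P)
}

#' Patient-level call from tile predictions
#'
#' Majority class over a slide's predicted tiles; an exact tie is called
#' non-responder (the cohort majority class and the conservative clinical
#' call); zero tiles yields `"no-call"`.
#'
#' @param pred_class Character vector of per-tile predicted classes for one
#'   slide (`"responder"` / `"non-responder"`).
#' @return `"responder"`, `"non-responder"`, or `"no-call"`.
#' @export
patient_vote <- function(pred_class) {
  if (length(pred_class) == 0L) return("no-call")
  n_r <- sum(pred_class == "responder")
  if (n_r > length(pred_class) / 2) "responder" else "non-responder"
}

#' Leave-one-patient-out cross-validation
#'
#' For each iteration (seed = base seed + iteration) and each slide g, a
#' classifier is trained on all tiles not from g and predicts g's tiles, so
#' no slide contributes to both training and test of a fold. Each
#' iteration's predictions are pooled across the folds before computing
#' metrics; mean and sd across iterations are reported.
#'
#' @param X Numeric feature matrix (tiles x features, `NA` allowed).
#' @param y Character labels per tile (`"responder"` / `"non-responder"`).
#' @param groups Slide id per tile.
#' @param config A [model_config()] (classifier, n_iterations, seed).
#' @param tile_id Optional tile ids carried into the predictions.
#' @param importance Collect per-prediction additive attributions
#'   (default FALSE).
#' @return Object of class `cv_result`: list with
#'   \item{predictions}{data.frame: iteration, tile_id, slide_id, truth,
#'     prob, pred_class.}
#'   \item{metrics}{data.frame of pooled metrics per iteration.}
#'   \item{summary}{data.frame: metric, mean, sd.}
#'   \item{slide_accuracy}{data.frame: slide, mean tile accuracy across
#'     iterations.}
#'   \item{patient_calls}{data.frame: slide, truth, call (majority over
#'     tiles, modal across iterations), agreement fraction.}
#'   \item{contrib}{attribution matrix (predictions x features + BIAS), or
#'     NULL.}
#' @export
logo_cv <- function(X, y, groups, config, tile_id = NULL, importance = FALSE) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(tile_id)) tile_id <- as.character(seq_len(nrow(X)))
  slides <- unique(groups)
  if (length(unique(y)) < 2L) stop("need both classes in the data")
  clf <- config$classifier
  y01 <- as.integer(y == "responder")

  preds <- list(); contribs <- list()
  for (it in seq_len(config$n_iterations)) {
    it_seed <- config$seed + it
    for (g in slides) {
      tr <- groups != g
      if (length(unique(y01[tr])) < 2L) {
        warning("fold ", g, " skipped: training data single-class")
        next
      }
      model <- clf$fit(X[tr, , drop = FALSE], y01[tr], it_seed)
      te <- which(!tr)
      prob <- clf$predict_prob(model, X[te, , drop = FALSE])
      preds[[length(preds) + 1L]] <- data.frame(
        iteration = it, tile_id = tile_id[te], slide_id = g,
        truth = y[te], prob = prob,
        pred_class = ifelse(prob >= 0.5, "responder", "non-responder"),
        stringsAsFactors = FALSE)
      if (importance && !is.null(clf$contrib)) {
        contribs[[length(contribs) + 1L]] <-
          clf$contrib(model, X[te, , drop = FALSE])
      }
    }
  }
  predictions <- do.call(rbind, preds)

  metrics <- do.call(rbind, lapply(split(predictions, predictions$iteration),
    function(d) {
      as.data.frame(t(pool_metrics(d$truth, d$prob)))
    }))
  metrics <- cbind(iteration = as.integer(rownames(metrics)), metrics)
  metrics <- metrics[order(metrics$iteration), , drop = FALSE]
  rownames(metrics) <- NULL

  mcols <- setdiff(names(metrics), "iteration")
  summary <- data.frame(
    metric = mcols,
    mean = vapply(mcols, function(m) mean(metrics[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(mcols, function(m) stats::sd(metrics[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  slide_accuracy <- do.call(rbind, lapply(split(predictions, predictions$slide_id),
    function(d) data.frame(slide = d$slide_id[1L],
                           accuracy = mean(d$pred_class == d$truth),
                           n_tiles = length(unique(d$tile_id)),
                           stringsAsFactors = FALSE)))
  rownames(slide_accuracy) <- NULL

  patient_calls <- do.call(rbind, lapply(split(predictions, predictions$slide_id),
    function(d) {
      calls <- vapply(split(d, d$iteration),
                      function(di) patient_vote(di$pred_class), character(1))
      tab <- sort(table(calls), decreasing = TRUE)
      data.frame(slide = d$slide_id[1L], truth = d$truth[1L],
                 call = names(tab)[1L],
                 agreement = as.numeric(tab[1L]) / length(calls),
                 stringsAsFactors = FALSE)
    }))
  rownames(patient_calls) <- NULL

  structure(list(predictions = predictions, metrics = metrics,
                 summary = summary, slide_accuracy = slide_accuracy,
                 patient_calls = patient_calls,
                 contrib = if (length(contribs)) do.call(rbind, contribs) else NULL,
                 feature_names = colnames(X), config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", max(x$metrics$iteration), " iteration(s), ",
      length(unique(x$predictions$slide_id)), " folds\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Feature importance from additive attributions
#'
#' Ranks features by the mean absolute per-prediction attribution (TreeSHAP
#' contributions for the xgboost backend) over all test-tile predictions
#' across folds and iterations. For classifier backends without additive
#' attributions, permutation importance would be the fallback; the shipped
#' backend always provides attributions.
#'
#' @param cv A [logo_cv()] result run with `importance = TRUE`.
#' @param top_n Return the top-n features (default all).
#' @return data.frame: `feature`, `mean_abs_attribution`, `rank`, ordered by
#'   rank. Attribute `"signed"` holds the full signed attribution matrix for
#'   beeswarm-style exports.
#' @export
importance_summary <- function(cv, top_n = Inf) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$contrib)) stop("run logo_cv with importance = TRUE")
  m <- cv$contrib
  feat <- setdiff(colnames(m), c("BIAS", "(Intercept)"))
  imp <- colMeans(abs(m[, feat, drop = FALSE]))
  o <- order(-imp)
  out <- data.frame(feature = feat[o], mean_abs_attribution = imp[o],
                    rank = seq_along(feat), row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- utils::head(out, top_n)
  attr(out, "signed") <- m
  out
}

#' CD8 threshold sweep for the immune-high model
#'
#' Re-runs [logo_cv()] at each CD8+ proportion cutoff on the
#' correspondingly filtered tile set (cutoff 0 equals the combined model on
#' all tiles) and tabulates pooled metrics plus per-slide qualifying-tile
#' counts.
#'
#' @param features TileFeatureTable data.frame.
#' @param cutoffs Sorted CD8 proportion cutoffs in `[0, 0.05]`.
#' @param config A [model_config()]; its mode/threshold are overridden per
#'   cutoff.
#' @return List with `metrics` (data.frame: cutoff x metric means),
#'   `qualifying` (data.frame: cutoff, slide, n_tiles), `results`
#'   (list of `cv_result`).
#' @export
threshold_sweep <- function(features, cutoffs, config) {
  stopifnot(!is.unsorted(cutoffs))
  res <- list(); mrows <- list(); qrows <- list()
  for (ct in cutoffs) {
    cfg <- config
    cfg$mode <- if (ct == 0) "combined" else "immune_high"
    cfg$cd8_threshold <- ct
    a <- assemble_features(features, cfg)
    cv <- logo_cv(a$X, a$y, a$groups, cfg, tile_id = a$tile_id)
    res[[as.character(ct)]] <- cv
    mm <- cv$summary$mean; names(mm) <- cv$summary$metric
    mrows[[length(mrows) + 1L]] <- cbind(data.frame(cutoff = ct), t(mm))
    counts <- table(a$groups)
    qrows[[length(qrows) + 1L]] <- data.frame(
      cutoff = ct, slide = names(counts), n_tiles = as.integer(counts),
      stringsAsFactors = FALSE)
    for (s in a$dropped_slides) {
      qrows[[length(qrows) + 1L]] <- data.frame(cutoff = ct, slide = s,
                                                n_tiles = 0L)
    }
  }
  list(metrics = do.call(rbind, mrows),
       qualifying = do.call(rbind, qrows),
       results = res)
}
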