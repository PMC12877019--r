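test_that("feature assembly selects columns by mode and filters immune-high", {
  feats <- fx_feature_table()
  cfg_c <- model_config("compositional", n_iterations = 1)
  a <- assemble_features(feats, cfg_c)
  expect_equal(ncol(a$X), 3)   # 2 comp + 1 subpop
  cfg_k <- model_config("combined", n_iterations = 1)
  b <- assemble_features(feats, cfg_k)
  expect_equal(ncol(b$X), 6)   # + 2 rcn + 1 ripley dL20

  # immune-high boundary semantics: >= threshold
  feats$`comp/CD8` <- rep(c(0.01, 0.02, 0.05), length.out = nrow(feats))
  cfg_i <- model_config("immune_high", cd8_threshold = 0.02, n_iterations = 1)
  d <- assemble_features(feats, cfg_i)
  expect_equal(nrow(d$X), sum(feats$`comp/CD8` >= 0.02))
})

test_that("pooled metrics match confusion-matrix arithmetic", {
  truth <- c(rep("responder", 4), rep("non-responder", 6))
  prob <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  m <- pool_metrics(truth, prob)   # TP=3 FP=1 TN=5 FN=1
  expect_equal(m[["accuracy"]], 0.8)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["specificity"]], 5 / 6)
  expect_equal(m[["f1"]], 0.75)
  expect_equal(m[["balanced_accuracy"]], (0.75 + 5 / 6) / 2, tolerance = 1e-4)

  # perfectly separated scores
  m2 <- pool_metrics(c("responder", "non-responder"), c(0.9, 0.1))
  expect_equal(m2[["roc_auc"]], 1)
  expect_equal(m2[["auprc"]], 1)
  # constant score
  m3 <- pool_metrics(rep(c("responder", "non-responder"), 5), rep(0.5, 10))
  expect_equal(m3[["roc_auc"]], 0.5)
  # single-class truth: AUCs undefined
  m4 <- pool_metrics(rep("responder", 3), c(0.2, 0.5, 0.9))
  expect_true(is.na(m4[["roc_auc"]]))
})

test_that("average precision matches a hand-computed step integral", {
  # scores .9 .8 .7 .6, positives at ranks 1 and 3:
  # AP = 0.5 * 1 + 0.5 * (2/3)
  ap <- miftiles:::average_precision(c(TRUE, FALSE, TRUE, FALSE),
                                     c(0.9, 0.8, 0.7, 0.6))
  expect_equal(ap, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
})

test_that("rank-based ROC AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(61)
  truth <- sample(c("responder", "non-responder"), 60, replace = TRUE)
  prob <- runif(60)
  m <- pool_metrics(truth, prob)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob, levels = c("non-responder", "responder"),
    direction = "<", quiet = TRUE)))
  expect_equal(m[["roc_auc"]], ref, tolerance = 1e-12)
})

test_that("patient vote is a majority with a conservative tie-break", {
  expect_equal(patient_vote(rep(c("responder", "non-responder"), c(7, 3))),
               "responder")
  expect_equal(patient_vote(rep(c("responder", "non-responder"), c(5, 5))),
               "non-responder")
  expect_equal(patient_vote(character(0)), "no-call")
})

test_that("LOGO-CV is leak-free, complete and reproducible", {
  feats <- fx_feature_table(seed = 62)
  cfg <- model_config("combined", n_iterations = 3, seed = 7)
  a <- assemble_features(feats, cfg)

  # record the training groups seen by the classifier
  seen <- new.env(); seen$train <- list()
  base <- classifier_xgboost(nrounds = 20)
  spy <- base
  spy$fit <- function(X, y01, seed) {
    seen$train[[length(seen$train) + 1L]] <- rownames(X)
    base$fit(X, y01, seed)
  }
  rownames(a$X) <- a$groups
  cfg$classifier <- spy
  cv <- logo_cv(a$X, a$y, a$groups, cfg, tile_id = a$tile_id)

  # leakage: no training fold contains the predicted slide
  folds_per_iter <- length(unique(a$groups))
  for (i in seq_along(seen$train)) {
    test_slide <- unique(a$groups)[((i - 1) %% folds_per_iter) + 1]
    expect_false(test_slide %in% seen$train[[i]])
  }
  # completeness: every tile predicted exactly once per iteration
  counts <- table(cv$predictions$iteration, cv$predictions$tile_id)
  expect_true(all(counts == 1))

  # reproducibility: identical config and seed give identical results
  cfg2 <- model_config("combined", n_iterations = 3, seed = 7,
                       classifier = classifier_xgboost(nrounds = 20))
  cv2 <- logo_cv(a$X, a$y, a$groups, cfg2, tile_id = a$tile_id)
  cfg3 <- model_config("combined", n_iterations = 3, seed = 7,
                       classifier = classifier_xgboost(nrounds = 20))
  cv3 <- logo_cv(a$X, a$y, a$groups, cfg3, tile_id = a$tile_id)
  expect_identical(cv2$metrics, cv3$metrics)
  expect_identical(cv2$predictions, cv3$predictions)

  # balanced accuracy identity on every iteration
  for (i in unique(cv2$metrics$iteration)) {
    row <- cv2$metrics[cv2$metrics$iteration == i, ]
    expect_equal(row$balanced_accuracy, (row$recall + row$specificity) / 2)
  }
})

test_that("planted signal is recovered and dominates feature importance", {
  feats <- fx_feature_table(seed = 63, signal = 2)
  cfg <- model_config("combined", n_iterations = 2, seed = 11)
  a <- assemble_features(feats, cfg)
  cv <- logo_cv(a$X, a$y, a$groups, cfg, tile_id = a$tile_id,
                importance = TRUE)
  expect_gt(mean(cv$metrics$roc_auc), 0.8)

  imp <- importance_summary(cv)
  expect_equal(imp$feature[1], "comp/A")

  # Shapley additivity: contributions (incl. bias) sum to the logit output
  contrib <- cv$contrib
  probs <- cv$predictions$prob
  expect_equal(rowSums(contrib), stats::qlogis(probs), tolerance = 1e-4)
})

test_that("threshold sweep: cutoff 0 equals combined; counts are monotone", {
  feats <- fx_feature_table(seed = 64, signal = 2)
  feats$`comp/CD8` <- runif(nrow(feats), 0, 0.04)
  cfg <- model_config("combined", n_iterations = 2, seed = 3)
  sw <- threshold_sweep(feats, c(0, 0.01, 0.03), cfg)

  a <- assemble_features(feats, cfg)
  cv_comb <- logo_cv(a$X, a$y, a$groups, cfg, tile_id = a$tile_id)
  expect_equal(sw$metrics$roc_auc[sw$metrics$cutoff == 0],
               mean(cv_comb$metrics$roc_auc))
  # qualifying-tile counts never increase with the cutoff
  for (s in unique(sw$qualifying$slide)) {
    q <- sw$qualifying[sw$qualifying$slide == s, ]
    q <- q[order(q$cutoff), ]
    expect_true(all(diff(q$n_tiles) <= 0))
  }
})
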