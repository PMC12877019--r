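test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone dominance: adjusted values never fall below the raw ones and
  # preserve the sorted order
  set.seed(51)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(!is.unsorted(q[order(p)]))
})

test_that("Wilcoxon screen reproduces exact rank-sum p-values", {
  feats <- data.frame(`comp/A` = c(1, 2, 3, 4, 5, 6),
                      `comp/B` = c(5, 5, 5, 5, 5, 5),
                      check.names = FALSE)
  labels <- rep(c("responder", "non-responder"), each = 3)
  res <- wilcoxon_screen(feats, labels)
  a <- res[res$feature == "comp/A", ]
  expect_equal(a$p_raw, 0.1)   # 2 / choose(6, 3)
  expect_equal(a$fold_change, mean(1:3) / mean(4:6))
  b <- res[res$feature == "comp/B", ]
  expect_equal(b$p_raw, 1)
  expect_equal(b$fold_change, 1)
})

test_that("Wilcoxon p is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rnorm(30)
  labels <- rep(c("responder", "non-responder"), 15)
  f1 <- data.frame(`comp/A` = x, check.names = FALSE)
  f2 <- data.frame(`comp/A` = exp(x), check.names = FALSE)
  expect_equal(wilcoxon_screen(f1, labels)$p_raw,
               wilcoxon_screen(f2, labels)$p_raw)
})

test_that("features entirely missing in one group are untestable", {
  feats <- data.frame(`comp/A` = c(NA, NA, NA, 1, 2, 3), check.names = FALSE)
  labels <- rep(c("responder", "non-responder"), each = 3)
  res <- wilcoxon_screen(feats, labels)
  expect_true(res$untestable)
  expect_true(is.na(res$p_raw))
})

test_that("group correlations match hand-computed Pearson R", {
  x <- c(1, 2, 3, 4)
  feats <- data.frame(`comp/X` = c(x, x), `comp/Y` = c(x, -x),
                      `comp/Z` = c(1, 3, 2, 4, 1, 3, 2, 4),
                      check.names = FALSE)
  labels <- rep(c("responder", "non-responder"), each = 4)
  cors <- group_correlations(feats, labels)
  expect_equal(cors$responder["comp/X", "comp/Y"], 1)
  expect_equal(cors$`non-responder`["comp/X", "comp/Y"], -1)
  expect_equal(cors$responder["comp/X", "comp/Z"], 0.8)
})

fx_slide_data <- function(effect = 0, n_slides = 12, tiles_per = 20,
                          slide_sd = 0.3, seed = 1) {
  set.seed(seed)
  slides <- sprintf("s%02d", seq_len(n_slides))
  resp <- rep(c("responder", "non-responder"), c(4, n_slides - 4))
  rows <- do.call(rbind, lapply(seq_len(n_slides), function(i) {
    mu <- stats::rnorm(1, 0, slide_sd) +
      if (resp[i] == "responder") effect else 0
    data.frame(slide = slides[i], response = resp[i],
               value = 0.1 * exp(stats::rnorm(tiles_per, mu, 0.5)))
  }))
  rows
}

test_that("mixed-effects screen detects a strong planted slide-level effect", {
  d <- fx_slide_data(effect = 2, seed = 53)
  feats <- data.frame(`comp/A` = d$value, check.names = FALSE)
  res <- mixed_effects_screen(feats, d$response, d$slide,
                              min_slides_present = 10)
  expect_lt(res$p_raw, 0.01)
  expect_false(res$skipped)
})

test_that("mixed-effects type-I error is near nominal under the null", {
  ps <- vapply(1:100, function(i) {
    d <- fx_slide_data(effect = 0, seed = 100 + i)
    feats <- data.frame(`comp/A` = d$value, check.names = FALSE)
    res <- mixed_effects_screen(feats, d$response, d$slide,
                                min_slides_present = 10)
    res$p_raw
  }, numeric(1))
  frac <- mean(ps < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("features observed in too few slides are skipped", {
  d <- fx_slide_data(effect = 0, seed = 54)
  v <- d$value
  v[d$slide %in% sprintf("s%02d", 10:12)] <- NA   # present in 9 of 12 slides
  feats <- data.frame(`comp/A` = v, check.names = FALSE)
  res <- mixed_effects_screen(feats, d$response, d$slide,
                              min_slides_present = 10)
  expect_true(res$skipped)
  expect_true(is.na(res$p_raw))
})
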