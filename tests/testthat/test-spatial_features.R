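test_that("isotropic weight matches the analytic half-plane and corner cases", {
  W <- c(0, 10, 0, 10)
  expect_equal(isotropic_weight(5, 5, 2, W), 1)          # fully interior
  expect_equal(isotropic_weight(0, 5, 1, W), 2)          # on an edge: half in
  expect_equal(isotropic_weight(1, 5, 2, W), 1.5)        # 1/3 of arc outside
  expect_equal(isotropic_weight(0, 0, 1, W), 4)          # corner: quarter in
  expect_error(isotropic_weight(-1, 5, 1, W), "outside")
  expect_error(isotropic_weight(5, 5, 0, W), "positive")
})

test_that("isotropic weight agrees with numeric arc integration", {
  set.seed(31)
  W <- c(0, 100, 0, 80)
  theta <- seq(0, 2 * pi, length.out = 40001)[-1]
  for (rep in 1:50) {
    x <- runif(1, 0, 100); y <- runif(1, 0, 80); d <- runif(1, 1, 60)
    inside <- mean(x + d * cos(theta) >= W[1] & x + d * cos(theta) <= W[2] &
                     y + d * sin(theta) >= W[3] & y + d * sin(theta) <= W[4])
    w_num <- 1 / inside
    expect_equal(isotropic_weight(x, y, d, W), w_num, tolerance = 1e-3)
  }
})

test_that("single-pair cross-K matches the closed form", {
  W <- c(0, 100, 0, 100)
  cur <- ripley_cross_K(cbind(50, 50), cbind(50, 55), W, r_grid = 0:10,
                        idA = "a", idB = "b")
  expect_equal(cur$K[cur$r == 5], 10000, tolerance = 1e-9)
  expect_equal(cur$L[cur$r == 5], sqrt(10000 / pi), tolerance = 1e-9)
  expect_equal(cur$delta_L[cur$r == 5], sqrt(10000 / pi) - 5, tolerance = 1e-9)
  # below the pair distance the estimate is empty
  cur2 <- ripley_cross_K(cbind(50, 50), cbind(50, 55), W, r_grid = c(0, 4.9),
                         idA = "a", idB = "b")
  expect_equal(cur2$K[2], 0)
  expect_equal(cur2$delta_L[2], -4.9)
  expect_equal(cur$K[cur$r == 0], 0)
})

test_that("uncorrected K equals brute-force pair counting on random tiles", {
  set.seed(32)
  W <- c(0, 500, 0, 500)
  for (rep in 1:25) {
    nA <- sample(2:60, 1); nB <- sample(2:60, 1)
    A <- cbind(runif(nA, 0, 500), runif(nA, 0, 500))
    B <- cbind(runif(nB, 0, 500), runif(nB, 0, 500))
    r_grid <- c(0, 25, 60, 120)
    cur <- ripley_cross_K(A, B, W, r_grid, idA = paste0("a", 1:nA),
                          idB = paste0("b", 1:nB), correction = "none")
    # oracle: exhaustive double loop
    for (k in seq_along(r_grid)) {
      cnt <- 0
      for (i in seq_len(nA)) {
        for (j in seq_len(nB)) {
          dij <- sqrt(sum((A[i, ] - B[j, ])^2))
          if (dij <= r_grid[k] && dij > 0) cnt <- cnt + 1
        }
      }
      expect_equal(cur$K[k], 250000 / (nA * nB) * cnt, tolerance = 1e-12)
    }
  }
})

test_that("cross-K is symmetric in its arguments and monotone in r", {
  set.seed(33)
  W <- c(0, 300, 0, 300)
  for (rep in 1:10) {
    A <- cbind(runif(30, 0, 300), runif(30, 0, 300))
    B <- cbind(runif(20, 0, 300), runif(20, 0, 300))
    kab <- ripley_cross_K(A, B, W, 0:100, idA = paste0("a", 1:30),
                          idB = paste0("b", 1:20))
    kba <- ripley_cross_K(B, A, W, 0:100, idA = paste0("b", 1:20),
                          idB = paste0("a", 1:30))
    expect_equal(kab$K, kba$K, tolerance = 1e-12)
    expect_true(all(diff(kab$K) >= 0))
  }
  # univariate K is invariant to point relabeling
  A <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  k1 <- ripley_cross_K(A, A, W, 0:50)
  perm <- sample(40)
  k2 <- ripley_cross_K(A[perm, ], A[perm, ], W, 0:50)
  expect_equal(k1$K, k2$K, tolerance = 1e-12)
})

test_that("proximity score matches hand enumeration and its normalization", {
  xy <- rbind(c(0, 0), c(10, 0), c(0, 5), c(500, 500))
  tab <- fx_cells(xy, list("CD3", "CD3", "CD8", character(0)))
  cat <- enumerate_states(tab, top_n = 4)
  ps <- proximity_score(tab$cells, cat, "CD3", "CD8", 20)
  expect_equal(ps$count, 2L)        # distances 5 and sqrt(125), both < 20
  expect_equal(ps$prop_a, 0.5)
  expect_equal(ps$prop_b, 0.25)
  expect_equal(ps$score, 2 / 0.75, tolerance = 1e-12)
  # absent partner state -> missing
  expect_true(is.na(proximity_score(tab$cells, cat, "CD3", "SOX10", 20)$score))
})

test_that("self-pair proximity counts unordered pairs with strict <", {
  xy <- rbind(c(0, 0), c(100, 0))
  tab <- fx_cells(xy, list("CD3", "CD3"))
  cat <- enumerate_states(tab, top_n = 2)
  ps <- proximity_score(tab$cells, cat, "CD3", "CD3", 20)
  expect_equal(ps$count, 0L)
  expect_equal(ps$score, 0)
  # exactly at the radius is NOT counted (strict inequality)
  ps2 <- proximity_score(tab$cells, cat, "CD3", "CD3", 100)
  expect_equal(ps2$count, 0L)
  ps3 <- proximity_score(tab$cells, cat, "CD3", "CD3", 100.001)
  expect_equal(ps3$count, 1L)
})

test_that("proximity scores equal an exhaustive pair-enumeration oracle", {
  set.seed(34)
  for (rep in 1:20) {
    tab <- fx_random_tile(80)
    cat <- enumerate_states(tab, top_n = 6)
    labs <- sample(cat$states$label, 2)
    r <- sample(c(20, 30, 60, 90), 1)
    ps <- proximity_score(tab$cells, cat, labs[1], labs[2], r)
    m <- state_membership(as.matrix(tab$cells[, fx_panel()$markers]), cat)
    ia <- which(m[, labs[1]]); ib <- which(m[, labs[2]])
    if (length(ia) == 0 || length(ib) == 0) {
      expect_true(is.na(ps$score))
      next
    }
    cnt <- 0
    for (i in ia) {
      for (j in ib) {
        if (i == j) next
        dij <- sqrt((tab$cells$x_c[i] - tab$cells$x_c[j])^2 +
                      (tab$cells$y_c[i] - tab$cells$y_c[j])^2)
        if (dij < r) cnt <- cnt + 1
      }
    }
    if (labs[1] == labs[2]) cnt <- cnt / 2
    expect_identical(ps$count, as.integer(cnt))
    expect_equal(ps$score,
                 cnt / (length(ia) / 80 + length(ib) / 80),
                 tolerance = 1e-12)
  }
})

test_that("tile features: co-located clusters attract, separated ones repel", {
  set.seed(35)
  # co-located: A and B intermixed in one blob
  blob <- cbind(rnorm(60, 500, 15), rnorm(60, 500, 15))
  blob <- blob[blob[, 1] > 0 & blob[, 1] < 1000 & blob[, 2] > 0 &
                 blob[, 2] < 1000, ]
  sets <- rep(list("CD3", "CD8"), length.out = nrow(blob))
  tab <- fx_cells(blob, sets)
  cat <- enumerate_states(tab, top_n = 2)
  f <- ripley_tile_features(tab$cells, cat, c(0, 1000, 0, 1000))
  expect_gt(f[["ripley/dL20/CD3|CD8"]], 0)

  # far-separated halves: zero cross pairs within 100 um
  A <- cbind(runif(30, 0, 300), runif(30, 0, 1000))
  B <- cbind(runif(30, 700, 1000), runif(30, 0, 1000))
  tab2 <- fx_cells(rbind(A, B), c(rep(list("CD3"), 30), rep(list("CD8"), 30)))
  cat2 <- enumerate_states(tab2, top_n = 2)
  f2 <- ripley_tile_features(tab2$cells, cat2, c(0, 1000, 0, 1000))
  expect_equal(f2[["ripley/dL20/CD3|CD8"]], -20)
  expect_equal(f2[["ripley/L20/CD3|CD8"]], 0)
  # absent pair -> missing columns
  expect_true(is.na(f2[["ripley/dL20/SOX10|SOX10"]]))
})

test_that("tile-feature curves agree with the reference estimator at 20 um", {
  set.seed(36)
  tab <- fx_random_tile(120)
  cat <- enumerate_states(tab, top_n = 4)
  W <- c(0, 1000, 0, 1000)
  f <- ripley_tile_features(tab$cells, cat, W)
  m <- state_membership(as.matrix(tab$cells[, fx_panel()$markers]), cat)
  labs <- cat$states$label
  for (a in 1:2) {
    for (b in a:3) {
      iA <- which(m[, a]); iB <- which(m[, b])
      if (length(iA) < 2 || length(iB) < 2) next
      xy <- as.matrix(tab$cells[, c("x_c", "y_c")])
      cur <- ripley_cross_K(xy[iA, , drop = FALSE], xy[iB, , drop = FALSE], W,
                            r_grid = c(0, 20),
                            idA = tab$cells$cell_id[iA],
                            idB = tab$cells$cell_id[iB])
      expect_equal(f[[paste0("ripley/L20/", labs[a], "|", labs[b])]],
                   cur$L[2], tolerance = 1e-9)
    }
  }
})
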