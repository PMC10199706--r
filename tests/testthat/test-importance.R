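test_that("a single unshrunken tree's gain equals its SSE reduction", {
  design <- make_design()
  set.seed(17)
  y <- 2 * (design$soil == "soil_c") + rnorm(108, 0, 0.3)
  fit <- fit_gbm(y, design, n_trees = 1, learning_rate = 1, subsample = 1,
                 seed = 1)
  # recompute: SSE at root minus summed SSE over the leaves this tree built
  pred <- predict(fit)
  sse_root <- sum((y - mean(y))^2)
  sse_after <- sum((y - pred)^2)
  expect_equal(fit$total_gain, sse_root - sse_after, tolerance = 1e-8)
  expect_equal(sum(fit$vim), fit$total_gain, tolerance = 1e-10)
})

test_that("importances are conserved, deterministic and driver-dominated", {
  design <- make_design()
  set.seed(23)
  y <- 2 * (design$soil == "soil_c") + rnorm(108, 0, 0.2)
  fit <- fit_gbm(y, design, seed = 5)
  # conservation: per-variable gains sum to the ensemble total
  expect_equal(sum(fit$vim), fit$total_gain, tolerance = 1e-6 * fit$total_gain)
  # deterministic given the seed
  fit2 <- fit_gbm(y, design, seed = 5)
  expect_identical(fit$vim, fit2$vim)
  expect_false(identical(fit$vim, fit_gbm(y, design, seed = 6)$vim))
  # the planted driver dominates
  expect_gt(fit$vim[["soil"]] / sum(fit$vim), 0.8)

  # cultivar-driven gene: first rank for cultivar, low elsewhere
  yc <- 2 * (design$cultivar == "cv_b") + rnorm(108, 0, 0.2)
  fc <- fit_gbm(yc, design, seed = 5)
  expect_equal(names(which.max(fc$vim)), "cultivar")
  expect_gt(fc$vim[["cultivar"]] / sum(fc$vim), 0.8)

  # constant gene: all importances zero and flagged
  f0 <- fit_gbm(rep(3, 108), design, seed = 5)
  expect_true(f0$constant)
  expect_equal(unname(f0$vim), rep(0, 4))
})

test_that("permuting a non-driver factor barely moves its importance", {
  design <- make_design()
  set.seed(29)
  y <- 2 * (design$soil == "soil_c") + rnorm(108, 0, 0.2)
  fit <- fit_gbm(y, design, seed = 7)
  perm <- design
  set.seed(30)
  perm$tissue <- sample(perm$tissue)
  fit_p <- fit_gbm(y, perm, seed = 7)
  expect_lt(abs(fit_p$vim[["tissue"]] - fit$vim[["tissue"]]),
            0.2 * fit$vim[["soil"]])
})

test_that("per-gene importances aggregate to cluster medians and ranks", {
  gv <- tibble::tibble(
    gene = sprintf("g%02d", 1:9),
    vim_stage = c(1, 5, 100, rep(2, 6)),
    vim_cultivar = rep(1, 9),
    vim_tissue = rep(1, 9),
    vim_soil = c(rep(0, 3), 7, 7, 7, 50, 60, 70)
  )
  cl <- structure(list(
    k = 3,
    assignment = tibble::tibble(gene = gv$gene,
                                cluster = rep(1:3, each = 3)),
    centroids = matrix(0, 3, 4), rc = rep(1, 3), sizes = rep(3L, 3),
    variance_explained = 0.9, conditions = NULL, seed = 1
  ), class = "cluster_set")
  vt <- cluster_vims(gv, cl)
  expect_equal(vt$vim_stage[vt$cluster == 1], 5)       # median of 1,5,100
  expect_equal(vt$vim_soil[vt$cluster == 3], 60)
  # each rank column is a permutation of 1..k
  for (col in grep("^rnk_", names(vt), value = TRUE)) {
    expect_setequal(vt[[col]], 1:3)
  }
  # equal importances break ties toward the lower cluster id
  expect_equal(vt$rnk_vim_cultivar, 1:3)
  # a clustered gene without scores is an error
  expect_error(cluster_vims(gv[-1, ], cl), "importance")
})

test_that("top-k intersections partition exactly as the bitmask oracle", {
  # disjoint top sets: four specific categories of size k_top
  vt_disjoint <- tibble::tibble(
    cluster = 1:8,
    rnk_vim_stage = c(1, 2, 3, 4, 5, 6, 7, 8),
    rnk_vim_cultivar = c(3, 4, 1, 2, 7, 8, 5, 6),
    rnk_vim_tissue = c(5, 6, 7, 8, 1, 2, 3, 4),
    rnk_vim_soil = c(7, 8, 5, 6, 3, 4, 1, 2)
  )
  tk <- top_k_intersections(vt_disjoint, k_top = 2)
  expect_equal(nrow(tk$membership), 8)
  expect_true(all(tk$membership$specific))
  expect_equal(sort(tk$categories$n_clusters), rep(2L, 4))

  # identical top sets: one 4-way shared category
  vt_same <- vt_disjoint
  for (col in grep("^rnk_", names(vt_same))) vt_same[[col]] <- 1:8
  tk_same <- top_k_intersections(vt_same, k_top = 3)
  expect_equal(nrow(tk_same$categories), 1)
  expect_equal(tk_same$categories$n_clusters, 3L)
  expect_equal(tk_same$categories$category,
               "stage+cultivar+tissue+soil")

  # random permutations match the brute-force membership oracle
  set.seed(44)
  for (rep in 1:5) {
    vt <- tibble::tibble(
      cluster = 1:40,
      rnk_vim_stage = sample(40), rnk_vim_cultivar = sample(40),
      rnk_vim_tissue = sample(40), rnk_vim_soil = sample(40)
    )
    tk <- top_k_intersections(vt, k_top = 10)
    sets <- lapply(c("stage", "cultivar", "tissue", "soil"), function(v) {
      vt$cluster[vt[[paste0("rnk_vim_", v)]] <= 10]
    })
    names(sets) <- c("stage", "cultivar", "tissue", "soil")
    oracle <- oracle_partition(sets)
    got <- setNames(tk$membership$category,
                    as.character(tk$membership$cluster))
    expect_identical(got[names(oracle)], oracle)
    # category sizes cover the union exactly
    expect_equal(sum(tk$categories$n_clusters), length(oracle))
  }
  expect_error(top_k_intersections(vt_disjoint, k_top = 50), "exceeds")
})

test_that("interaction strength separates additive from interacting pairs", {
  design <- make_design()
  set.seed(61)
  # purely additive response: H(stage, soil) < 0.1
  ya <- (as.integer(design$stage) - 2) + (as.integer(design$soil) - 2) +
    rnorm(108, 0, 0.2)
  fa <- fit_gbm(ya, design, seed = 9)
  h_add <- interaction_strength(fa, design, c("stage", "soil"))$h_statistic
  expect_lt(h_add, 0.1)

  # planted pure stage x soil interaction dominates every other pair
  yi <- 2 * (as.integer(design$stage) == as.integer(design$soil)) +
    rnorm(108, 0, 0.2)
  fi <- fit_gbm(yi, design, seed = 9)
  hs <- interaction_strength(fi, design)
  top <- hs[which.max(hs$h_statistic), ]
  expect_setequal(c(top$var1, top$var2), c("stage", "soil"))
  expect_true(all(hs$h_statistic >= 0 & hs$h_statistic <= 1))

  # a single-level variable has zero interaction strength
  d1 <- make_design(list(cultivar = 1, tissue = 2, stage = 3, soil = 3))
  set.seed(62)
  y1 <- rnorm(nrow(d1))
  f1 <- suppressWarnings(fit_gbm(y1, d1, n_trees = 50, seed = 9))
  h1 <- interaction_strength(f1, d1, c("cultivar", "soil"))$h_statistic
  expect_equal(h1, 0)
})
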