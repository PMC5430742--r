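test_that("matrix-form objective equals the explicit blockwise residue", {
  set.seed(21)
  G <- random_expr(12, 8)
  rl <- sample(1:3, 12, replace = TRUE)
  cl <- sample(1:2, 8, replace = TRUE)
  w <- runif(12, 0.5, 2)
  obj <- netbc_objective(G, hard_indicator(rl, 3), hard_indicator(cl, 2), w)
  expect_equal(obj, blockwise_objective(G, rl, cl, w), tolerance = 1e-10)

  # unweighted form equals w = 1
  expect_equal(netbc_objective(G, hard_indicator(rl, 3), hard_indicator(cl, 2)),
               blockwise_objective(G, rl, cl, rep(1, 12)), tolerance = 1e-10)
})

test_that("doubling one gene's weight adds exactly its residue contribution", {
  set.seed(22)
  G <- random_expr(10, 6)
  rl <- sample(1:2, 10, replace = TRUE)
  cl <- sample(1:2, 6, replace = TRUE)
  R <- hard_indicator(rl, 2)
  C <- hard_indicator(cl, 2)
  w <- rep(1, 10)
  base <- netbc_objective(G, R, C, w)
  E <- netbc:::netbc_residual(G, R, C)
  w2 <- w
  w2[4] <- 2
  expect_equal(netbc_objective(G, R, C, w2), base + sum(E[4, ]^2),
               tolerance = 1e-10)
})

test_that("hard row projection reproduces group means", {
  set.seed(23)
  G <- random_expr(15, 7)
  rl <- sample(1:4, 15, replace = TRUE)
  R <- hard_indicator(rl, 4)
  proj <- R %*% solve(crossprod(R), t(R) %*% G)
  for (kk in 1:4) {
    members <- which(rl == kk)
    mean_profile <- colMeans(G[members, , drop = FALSE])
    for (i in members) {
      expect_equal(unname(proj[i, ]), unname(mean_profile), tolerance = 1e-12)
    }
  }
})

test_that("objective vanishes on additively structured blocks", {
  # per block: g_ij = u + alpha_i + beta_j has exactly zero residue
  set.seed(24)
  rl <- rep(1:3, times = c(4, 5, 3))
  cl <- rep(1:2, times = c(4, 2))
  G <- matrix(0, 12, 6)
  for (kk in 1:3) for (dd in 1:2) {
    ri <- which(rl == kk); ci <- which(cl == dd)
    G[ri, ci] <- rnorm(1) + outer(rnorm(length(ri)), rnorm(length(ci)), `+`)
  }
  dimnames(G) <- list(paste0("g", 1:12), paste0("s", 1:6))
  obj <- netbc_objective(G, hard_indicator(rl, 3), hard_indicator(cl, 2),
                         runif(12, 0.5, 2))
  expect_lt(obj, 1e-16)
})

test_that("k = d = 1 reduces to double centring of the whole matrix", {
  G <- random_expr(9, 7, seed = 31)
  w <- runif(9, 0.5, 2)
  res <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G)) + mean(G)
  expect_equal(netbc_objective(G, matrix(1, 9, 1), matrix(1, 7, 1), w),
               sum(w * rowSums(res^2)), tolerance = 1e-10)
})

test_that("one multiplicative update never increases the objective", {
  set.seed(25)
  for (rep in 1:50) {
    G <- matrix(rnorm(20 * 10), 20, 10)
    w <- runif(20, 0.5, 2)
    init <- netbc_init(G, 3, 2, method = "random", seed = rep)
    before <- netbc_objective(G, init$R, init$C, w)
    R2 <- netbc:::update_R(G, init$R, init$C, w)
    mid <- netbc_objective(G, R2, init$C, w)
    C2 <- netbc:::update_C(G, R2, init$C, w)
    after <- netbc_objective(G, R2, C2, w)
    expect_lte(mid, before * (1 + 1e-9))
    expect_lte(after, mid * (1 + 1e-9))
  }
})

test_that("the update is a fixed point on exactly fitted data", {
  sim <- sim_checkerboard(m = 12, n = 8, k = 2, d = 2, type = "additive",
                          sigma = 0, seed = 6)
  R <- netbc:::soft_onehot(as.integer(sim$row_labels), 2, 1e-9)
  C <- netbc:::soft_onehot(as.integer(sim$col_labels), 2, 1e-9)
  R2 <- netbc:::update_R(sim$expr, R, C, rep(1, 12))
  C2 <- netbc:::update_C(sim$expr, R, C, rep(1, 8))
  expect_equal(max.col(R2), max.col(R))
  expect_equal(max.col(C2), max.col(C))
})

test_that("identity weights and omitted weights give identical updates", {
  set.seed(26)
  G <- random_expr(10, 6)
  init <- netbc_init(G, 2, 2, method = "random", seed = 1)
  a <- netbc:::update_R(G, init$R, init$C, rep(1, 10))
  b <- netbc:::update_R(G, init$R, init$C, w = rep(1, nrow(G)))
  expect_identical(a, b)
})

test_that("initialization respects shape, determinism and constraints", {
  G <- random_expr(10, 6)
  init <- netbc_init(G, 3, 2, method = "random", seed = 4)
  expect_equal(dim(init$R), c(10, 3))
  expect_equal(dim(init$C), c(6, 2))
  expect_equal(rowSums(init$R), rep(1, 10))
  expect_equal(rowSums(init$C), rep(1, 6))
  again <- netbc_init(G, 3, 2, method = "random", seed = 4)
  expect_identical(init, again)

  expect_error(netbc_init(G, 11, 2), "k must be")
  expect_error(netbc_init(G, 3, 7), "d must be")
})

test_that("k-means initialization hardens onto duplicated row blocks", {
  block <- matrix(rnorm(4 * 6), 4, 6)
  G <- rbind(block, block + 10)  # two clearly separated duplicated blocks
  dimnames(G) <- list(paste0("g", 1:8), paste0("s", 1:6))
  init <- netbc_init(G, 2, 2, method = "kmeans", seed = 1)
  labels <- max.col(init$R)
  expect_equal(length(unique(labels[1:4])), 1L)
  expect_equal(length(unique(labels[5:8])), 1L)
  expect_false(labels[1] == labels[5])
})

test_that("fit recovers a clean checkerboard exactly", {
  sim <- sim_checkerboard(m = 30, n = 12, k = 3, d = 2, type = "constant",
                          sigma = 0, seed = 8)
  fit <- netbc(sim$expr, k = 3, d = 2, init = "kmeans", seed = 8)
  expect_ri_one(sim$row_labels, fit$row_labels)
  expect_ri_one(sim$col_labels, fit$col_labels)
  expect_lt(fit$objective, 1e-12)
  expect_equal(sort(unique(as.integer(fit$row_labels))), 1:3)
})

test_that("objective trace is non-increasing within tolerance", {
  for (s in 1:10) {
    sim <- sim_implanted(m = 40, n = 20, n_biclusters = 2,
                         bicluster_rows = 8, bicluster_cols = 5,
                         type = "additive", sigma = 0.1, seed = s)
    fit <- netbc(sim$expr, k = 3, d = 3, seed = s, iters = 80)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("permuting genes permutes the solution and preserves the objective", {
  G <- random_expr(14, 9, seed = 41)
  w <- runif(14, 0.5, 2)
  rl <- sample(1:3, 14, replace = TRUE)
  cl <- sample(1:2, 9, replace = TRUE)
  perm <- sample(14)
  obj1 <- netbc_objective(G, hard_indicator(rl, 3), hard_indicator(cl, 2), w)
  obj2 <- netbc_objective(G[perm, ], hard_indicator(rl[perm], 3),
                          hard_indicator(cl, 2), w[perm])
  expect_equal(obj1, obj2, tolerance = 1e-12)
})

test_that("extract_biclusters tiles the matrix exactly once", {
  sim <- sim_checkerboard(m = 20, n = 10, k = 2, d = 2, seed = 9)
  fit <- netbc(sim$expr, k = 2, d = 2, init = "kmeans", seed = 9, iters = 50)
  blocks <- extract_biclusters(fit)
  expect_equal(length(blocks), 4L)
  cover <- matrix(0L, 20, 10, dimnames = dimnames(sim$expr))
  for (b in blocks) cover[b$genes, b$samples] <- cover[b$genes, b$samples] + 1L
  expect_true(all(cover == 1L))
})

test_that("top_biclusters ranks blocks by coherence", {
  sim <- sim_checkerboard(m = 20, n = 10, k = 2, d = 2, type = "constant",
                          sigma = 0, seed = 10)
  # corrupt one block so it is strictly less coherent
  expr <- sim$expr
  noisy_rows <- names(sim$row_labels)[sim$row_labels == 2]
  noisy_cols <- names(sim$col_labels)[sim$col_labels == 2]
  set.seed(1)
  expr[noisy_rows, noisy_cols] <- rnorm(length(noisy_rows) * length(noisy_cols))
  fit <- netbc(expr, k = 2, d = 2, init = "kmeans", seed = 10, iters = 50)
  top <- top_biclusters(fit, expr, q = 3)
  expect_equal(length(top), 3L)
  worst <- extract_biclusters(fit)
  expect_equal(length(worst), 4L)
})

test_that("labels keep all requested clusters via empty-cluster repair", {
  # data with only 2 distinguishable row groups, but k = 3 requested
  sim <- sim_checkerboard(m = 12, n = 8, k = 2, d = 2, type = "constant",
                          sigma = 0.01, seed = 11)
  fit <- netbc(sim$expr, k = 3, d = 2, seed = 11, iters = 60)
  expect_equal(length(unique(as.integer(fit$row_labels))), 3L)
})

test_that("glance and tidy summarize fits", {
  sim <- sim_checkerboard(m = 12, n = 8, k = 2, d = 2, seed = 12)
  fit <- netbc(sim$expr, k = 2, d = 2, init = "kmeans", seed = 12, iters = 40)
  g <- glance(fit)
  expect_equal(g$k, 2)
  expect_equal(g$objective, fit$objective)
  td <- tidy(fit)
  expect_equal(nrow(td), 12 + 8)
  expect_setequal(unique(td$dimension), c("gene", "sample"))
  expect_true(all(td$membership >= 0 & td$membership <= 1))
})

test_that("autoplot returns ggplot objects", {
  sim <- sim_checkerboard(m = 12, n = 8, k = 2, d = 2, seed = 13)
  fit <- netbc(sim$expr, k = 2, d = 2, init = "kmeans", seed = 13, iters = 40)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, expr = sim$expr, type = "heatmap"), "ggplot")
})
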