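test_that("background generator is standard normal and reproducible", {
  G <- sim_background(100, 100, seed = 1)
  expect_equal(dim(G), c(100, 100))
  expect_lt(abs(mean(G)), 4 / sqrt(100 * 100))
  expect_lt(abs(stats::var(as.vector(G)) - 1), 4 * sqrt(2 / (100 * 100 - 1)))
  expect_identical(G, sim_background(100, 100, seed = 1))
  expect_false(identical(G, sim_background(100, 100, seed = 2)))
})

test_that("implants follow their archetype", {
  G <- sim_background(20, 12, seed = 3)
  rs <- list(1:5, 11:14)
  cs <- list(1:4, 7:10)

  con <- sim_implant(G, rs, cs, type = "constant", seed = 1)
  expect_equal(stats::var(as.vector(con$values[1:5, 1:4])), 0)
  expect_equal(length(con$truth), 2L)

  rowc <- sim_implant(G, rs, cs, type = "row_constant", seed = 1)
  sub <- rowc$values[1:5, 1:4]
  expect_true(all(sub == sub[, 1]))  # every column identical

  colc <- sim_implant(G, rs, cs, type = "column_constant", seed = 1)
  sub <- colc$values[1:5, 1:4]
  expect_true(all(t(sub) == sub[1, ]))  # every row identical

  add <- sim_implant(G, rs, cs, type = "additive", seed = 1)
  sub <- add$values[1:5, 1:4]
  res <- sub - rowMeans(sub) -
    matrix(colMeans(sub), 5, 4, byrow = TRUE) + mean(sub)
  expect_lt(sum(res^2), 1e-20)

  mul <- sim_implant(G, rs, cs, type = "multiplicative", seed = 1)
  sub <- mul$values[11:14, 7:10]
  ratios <- sub / matrix(sub[1, ], 4, 4, byrow = TRUE)
  expect_equal(unname(apply(ratios, 1, stats::var)), rep(0, 4),
               tolerance = 1e-12)
})

test_that("implant bookkeeping matches the modified cells", {
  G <- sim_background(15, 10, seed = 4)
  rs <- list(2:5, 8:10)
  cs <- list(1:3, 5:8)
  imp <- sim_implant(G, rs, cs, type = "constant", seed = 2)
  changed <- which(imp$values != G, arr.ind = TRUE)
  claimed <- matrix(FALSE, 15, 10)
  for (b in seq_along(rs)) claimed[rs[[b]], cs[[b]]] <- TRUE
  expect_true(all(claimed[changed]))
  for (b in seq_along(rs)) {
    expect_equal(imp$truth[[b]]$genes, rownames(G)[rs[[b]]])
    expect_equal(imp$truth[[b]]$samples, colnames(G)[cs[[b]]])
  }
})

test_that("overlapping implants are rejected", {
  G <- sim_background(10, 8)
  expect_error(sim_implant(G, list(1:4, 3:6), list(1:2, 4:6), type = "constant"),
               "overlap")
  expect_error(sim_implant(G, list(1:4, 5:8), list(1:3, 2:5), type = "constant"),
               "overlap")
})

test_that("noise addition behaves like N(0, sigma^2)", {
  G <- sim_background(60, 40, seed = 5)
  expect_identical(sim_add_noise(G, 0), G)
  noisy <- sim_add_noise(G, 0.2, seed = 6)
  delta <- noisy - G
  expect_lt(abs(stats::sd(delta) - 0.2), 0.01)
  expect_false(identical(sim_add_noise(G, 0.2, seed = 7), noisy))
})

test_that("noisy-gene injection replaces exactly the lowest-weight rows", {
  G <- sim_background(10, 8, seed = 8)
  w <- c(5, 4, 0.1, 3, 0.2, 6, 7, 8, 9, 10)
  out <- inject_noisy_genes(G, w, n_noisy = 2, seed = 9)
  expect_setequal(out$noisy_genes, c("g3", "g5"))
  untouched <- setdiff(rownames(G), out$noisy_genes)
  expect_identical(out$expr[untouched, ], G[untouched, ])
  expect_true(all(out$expr[out$noisy_genes, ] >= min(G) &
                    out$expr[out$noisy_genes, ] <= max(G)))

  none <- inject_noisy_genes(G, w, n_noisy = 0)
  expect_identical(none$expr, G)
  expect_length(none$noisy_genes, 0)
})

test_that("network perturbation conserves structure and counts", {
  net <- random_network(20, p = 0.2, seed = 10)
  n_edges <- sum(net$degrees) / 2

  same <- perturb_network(net, seed = 1)
  expect_equal(as.matrix(same$adjacency), as.matrix(net$adjacency))

  pert <- perturb_network(net, n_add = 5, n_delete = 3, n_rewire = 4, seed = 2)
  P <- as.matrix(pert$adjacency)
  expect_equal(sum(P) / 2, n_edges + 5 - 3)  # rewiring conserves the count
  expect_equal(P, t(P))
  expect_true(all(diag(P) == 0))
  expect_true(all(P %in% c(0, 1)))

  expect_error(perturb_network(net, n_delete = n_edges + 1), "not enough edges")
  dense <- random_network(5, p = 1, seed = 3)
  expect_error(perturb_network(dense, n_add = 1), "not enough non-edges")
})

test_that("structured network makes informative genes hubs", {
  star <- sim_structured_network(3, informative = 1, p_hub = 1,
                                 p_background = 0, seed = 1)
  P <- as.matrix(star$adjacency)
  expect_equal(unname(P), rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))

  set.seed(11)
  deg_inf <- deg_bg <- numeric(10)
  for (r in 1:10) {
    net <- sim_structured_network(60, informative = 1:20, p_hub = 0.3,
                                  p_background = 0.02, seed = r)
    deg_inf[r] <- mean(net$degrees[1:20])
    deg_bg[r] <- mean(net$degrees[21:60])
  }
  expect_gt(mean(deg_inf), mean(deg_bg))
})

test_that("checkerboard generator tiles the matrix with labelled blocks", {
  sim <- sim_checkerboard(m = 20, n = 12, k = 3, d = 2, type = "constant",
                          sigma = 0, seed = 12)
  expect_length(sim$truth, 6L)
  expect_equal(sort(unique(as.integer(sim$row_labels))), 1:3)
  expect_equal(sort(unique(as.integer(sim$col_labels))), 1:2)
  # each block constant
  for (b in sim$truth) {
    expect_equal(stats::var(as.vector(sim$expr[b$genes, b$samples])), 0)
  }
  expect_identical(sim$expr,
                   sim_checkerboard(m = 20, n = 12, k = 3, d = 2,
                                    type = "constant", sigma = 0, seed = 12)$expr)
})

test_that("zero-noise implanted data has zero residue at the truth partition", {
  for (type in c("constant", "row_constant", "column_constant", "additive")) {
    sim <- sim_checkerboard(m = 24, n = 12, k = 3, d = 2, type = type,
                            sigma = 0, seed = 13)
    obj <- netbc_objective(sim$expr,
                           hard_indicator(as.integer(sim$row_labels), 3),
                           hard_indicator(as.integer(sim$col_labels), 2))
    expect_lt(obj, 1e-16)
  }
})
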