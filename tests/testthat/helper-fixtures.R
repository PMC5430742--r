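# Shared fixtures and independent oracles, built in code at test time.

random_expr <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(paste0("g", seq_len(m)), paste0("s", seq_len(n))))
}

hard_indicator <- function(labels, k) diag(k)[labels, , drop = FALSE]

# Independent oracle for the weighted sum-squared residue: explicit loop
# over checkerboard blocks, comparing every entry with its row mean, column
# mean and block mean computed by plain arithmetic.
blockwise_objective <- function(G, row_labels, col_labels, w) {
  total <- 0
  for (kk in unique(row_labels)) {
    for (dd in unique(col_labels)) {
      ri <- which(row_labels == kk)
      ci <- which(col_labels == dd)
      sub <- G[ri, ci, drop = FALSE]
      res <- sub - rowMeans(sub) -
        matrix(colMeans(sub), nrow(sub), ncol(sub), byrow = TRUE) + mean(sub)
      total <- total + sum(w[ri] * rowSums(res * res))
    }
  }
  total
}

# Independent pair-counting oracle: loop over all unordered item pairs.
brute_pair_counts <- function(truth, pred) {
  n <- length(truth)
  counts <- c(np1 = 0, np2 = 0, np3 = 0, np4 = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- truth[i] == truth[j]
      same_p <- pred[i] == pred[j]
      idx <- if (same_t && same_p) 1 else if (same_t) 2 else if (same_p) 3 else 4
      counts[idx] <- counts[idx] + 1
    }
  }
  counts
}

# Random Erdos-Renyi gene network over m genes.
random_network <- function(m, p, seed = 1) {
  sim_structured_network(m, informative = seq_len(m), p_hub = p,
                         p_background = p, seed = seed)
}

expect_ri_one <- function(truth, pred) {
  expect_equal(rand_index(truth, pred), 1)
}
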