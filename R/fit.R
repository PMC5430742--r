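#' Weighted sum-squared residue of a checkerboard bi-clustering
#'
#' Evaluates
#' `Phi(R, C) = || (I - R(R'R)^-1 R') G (I - C(C'C)^-1 C') ||^2_W`,
#' the squared Frobenius norm of the double-centred residual with each gene
#' row i scaled by its weight `W_ii = w_i`. For hard (one-hot) indicator
#' matrices this equals the classical sum-squared residue summed over all
#' k x d blocks: within a block, each entry is compared against its row
#' mean, column mean and block mean, so any block whose entries follow a
#' constant, row-constant, column-constant or additive pattern contributes
#' exactly zero.
#'
#' @param G Numeric genes x samples matrix.
#' @param R Nonnegative m x k row-indicator matrix.
#' @param C Nonnegative n x d column-indicator matrix.
#' @param w Per-gene weight vector (default all 1).
#' @param ridge Relative ridge added to `R'R` and `C'C` before inversion;
#'   guards against near-empty soft clusters.
#' @return Nonnegative scalar.
#' @export
netbc_objective <- function(G, R, C, w = rep(1, nrow(G)),
                            ridge = 1e-10) {
  if (any(!is.finite(G))) stop("G contains non-finite values", call. = FALSE)
  E <- netbc_residual(G, R, C, ridge)
  sum(w * rowSums(E * E))
}

# (I - R(R'R)^-1 R') G (I - C(C'C)^-1 C'), via two centring passes.
netbc_residual <- function(G, R, C, ridge = 1e-10) {
  X3 <- G - R %*% ridged_solve(crossprod(R), t(R) %*% G, ridge)
  X3 - (X3 %*% C) %*% ridged_solve(crossprod(C), t(C), ridge)
}

# solve((M + lambda I), B) with lambda = ridge * trace(M)/ncol(M)
ridged_solve <- function(M, B, ridge) {
  lambda <- ridge * sum(diag(M)) / ncol(M)
  solve(M + diag(lambda, ncol(M)), B)
}

# Positive/negative part split M = M+ - M-, both elementwise nonnegative.
pos_part <- function(M) (abs(M) + M) / 2
neg_part <- function(M) (abs(M) - M) / 2

# One multiplicative update of the row indicators (C fixed).
# R <- R * sqrt((A+ + W R B-) / (A- + W R B+)), A = W X1 X2', B = X2 X2'.
# eps_guard is added to BOTH numerator and denominator so that a 0/0 entry
# (exactly fitted data) yields factor 1 and the entry stays put.
update_R <- function(G, R, C, w, eps_guard = 1e-12, ridge = 1e-10,
                     renormalize = TRUE) {
  X1 <- G - (G %*% C) %*% ridged_solve(crossprod(C), t(C), ridge)
  X2 <- ridged_solve(crossprod(R), t(R) %*% X1, ridge)   # k x n
  A <- w * (X1 %*% t(X2))                                # m x k
  B <- X2 %*% t(X2)                                      # k x k
  num <- pos_part(A) + w * (R %*% neg_part(B))
  den <- neg_part(A) + w * (R %*% pos_part(B))
  R_new <- R * sqrt((pmax(num, 0) + eps_guard) / (pmax(den, 0) + eps_guard))
  if (any(!is.finite(R_new))) {
    stop("non-finite entries in row-indicator update", call. = FALSE)
  }
  if (renormalize) {
    R_new <- R_new / rowSums(R_new)
  } else {
    R_new <- rescale_columns(R_new)
  }
  R_new
}

# Rescale indicator columns to unit maximum. The residue and the
# multiplicative update factor are both invariant to column rescaling, so
# this changes nothing but the floating-point range.
rescale_columns <- function(M) {
  cmax <- apply(M, 2L, max)
  cmax[cmax <= 0 | !is.finite(cmax)] <- 1
  sweep(M, 2L, cmax, "/")
}

# One multiplicative update of the column indicators (R fixed).
# C <- C * sqrt((Dm+ + C F-) / (Dm- + C F+)), Dm = X3' W X4, F = X4' W X4.
update_C <- function(G, R, C, w, eps_guard = 1e-12, ridge = 1e-10,
                     renormalize = TRUE) {
  X3 <- G - R %*% ridged_solve(crossprod(R), t(R) %*% G, ridge)
  X4 <- (X3 %*% C) %*% ridged_solve(crossprod(C), diag(ncol(C)), ridge)
  WX4 <- w * X4
  Dm <- t(X3) %*% WX4                                    # n x d
  Fm <- t(X4) %*% WX4                                    # d x d
  num <- pos_part(Dm) + C %*% neg_part(Fm)
  den <- neg_part(Dm) + C %*% pos_part(Fm)
  C_new <- C * sqrt((pmax(num, 0) + eps_guard) / (pmax(den, 0) + eps_guard))
  if (any(!is.finite(C_new))) {
    stop("non-finite entries in column-indicator update", call. = FALSE)
  }
  if (renormalize) {
    C_new <- C_new / rowSums(C_new)
  } else {
    C_new <- rescale_columns(C_new)
  }
  C_new
}

#' Initialize indicator matrices
#'
#' `random` draws entries uniform(0, 1) and normalizes each row to sum 1.
#' `kmeans` runs k-means on the rows of `G` (for `R`) and on the columns
#' (for `C`), one-hot encodes the labels, then replaces exact zeros by a
#' small jitter and renormalizes: multiplicative updates cannot move an
#' entry off an exact zero, so hard initial indicators must be softened.
#'
#' @param G Genes x samples matrix.
#' @param k,d Number of gene and sample clusters (`2 <= k <= m`,
#'   `2 <= d <= n`).
#' @param method `"random"` or `"kmeans"`.
#' @param seed Optional integer seed; the same seed yields the same pair.
#' @param init_jitter Replacement value for exact zeros in k-means one-hot
#'   indicators, before row renormalization.
#' @return List with elements `R` (m x k) and `C` (n x d).
#' @export
netbc_init <- function(G, k, d, method = c("random", "kmeans"), seed = NULL,
                       init_jitter = 0.01) {
  method <- match.arg(method)
  m <- nrow(G)
  n <- ncol(G)
  if (k < 2L || k > m) stop("k must be in [2, m]", call. = FALSE)
  if (d < 2L || d > n) stop("d must be in [2, n]", call. = FALSE)
  with_seed(seed, {
    if (method == "random") {
      R <- matrix(stats::runif(m * k), m, k)
      C <- matrix(stats::runif(n * d), n, d)
    } else {
      R <- soft_onehot(kmeans_labels(G, k), k, init_jitter)
      C <- soft_onehot(kmeans_labels(t(G), d), d, init_jitter)
    }
    list(R = R / rowSums(R), C = C / rowSums(C))
  })
}

# k-means labels with re-tries should a run come back with an empty cluster
# (stats::kmeans errors when more centres than distinct points are requested).
kmeans_labels <- function(X, k, attempts = 10L) {
  for (a in seq_len(attempts)) {
    fit <- tryCatch(
      stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L),
      error = function(e) NULL
    )
    if (!is.null(fit) && length(unique(fit$cluster)) == k) {
      return(fit$cluster)
    }
  }
  # fall back: contiguous slices along the ordering of the row means
  o <- order(rowMeans(X))
  labels <- integer(nrow(X))
  labels[o] <- sort(rep(seq_len(k), length.out = nrow(X)))
  labels
}

soft_onehot <- function(labels, k, jitter) {
  H <- matrix(jitter, length(labels), k)
  H[cbind(seq_along(labels), labels)] <- 1
  H / rowSums(H)
}

#' Fit a network-aided bi-clustering
#'
#' Alternates multiplicative updates of the nonnegative row and column
#' indicator matrices to minimize the gene-weighted sum-squared residue
#' [netbc_objective()], then hardens the soft indicators to cluster labels
#' by row-wise argmax (ties to the smallest index). The optimization runs
#' over the continuous relaxation of the one-hot constraint set. By
#' default the indicator rows are renormalized to sum 1 only on output:
#' the residue is invariant to column rescaling of the indicators and the
#' argmax labels are invariant to row rescaling, while renormalizing
#' inside the loop (available via `renormalize = TRUE`) breaks the
#' monotone descent of the multiplicative updates.
#'
#' @param expr Genes x samples matrix (from [read_expression()] or a
#'   generator).
#' @param k,d Number of gene and sample clusters.
#' @param weights A `gene_weights` object, a bare numeric weight vector, or
#'   `NULL` (default), which uses weights proportional to the per-gene
#'   expression variability (the no-network, `theta = 0` setting).
#' @param iters Maximum number of alternating iterations (default 300).
#' @param init Initialization method, `"random"` or `"kmeans"`.
#' @param seed Optional integer seed for the initialization.
#' @param rtol Early-stopping threshold: stop when the relative objective
#'   change stays below `rtol` for 5 consecutive iterations.
#' @param eps_guard Floor applied to update denominators.
#' @param ridge Relative ridge used in all `(X'X)^-1` solves.
#' @param renormalize Renormalize indicator rows to sum 1 after every
#'   update instead of only on output (default `FALSE`; see Details).
#' @param refine After argmax hardening, run the discrete alternating
#'   minimization of the same weighted residue (batch reassignment of each
#'   gene to the row cluster minimizing its weighted residual, then each
#'   sample likewise, to convergence). The soft optimum of the relaxation
#'   is generally interior, so bare argmax can land far from the best hard
#'   checkerboard; this step hardens onto a local optimum of the discrete
#'   problem. Default `TRUE`.
#' @return A `netbc` object: list with `row_labels`, `col_labels` (named
#'   integer vectors in `1..k` / `1..d`), soft `R` and `C`, the per-gene
#'   weight vector `w`, `theta`, `objective_trace`, `objective`, `k`, `d`,
#'   `iterations`, `converged`, and `seed`.
#' @export
#' @examples
#' sim <- sim_checkerboard(m = 30, n = 12, k = 3, d = 2, seed = 1)
#' fit <- netbc(sim$expr, k = 3, d = 2, init = "kmeans", seed = 1)
#' glance(fit)
netbc <- function(expr, k, d, weights = NULL, iters = 300L,
                  init = c("random", "kmeans"), seed = NULL, rtol = 1e-8,
                  eps_guard = 1e-12, ridge = 1e-10, renormalize = FALSE,
                  refine = TRUE) {
  init <- match.arg(init)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (any(!is.finite(expr))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  m <- nrow(expr)
  n <- ncol(expr)
  wobj <- as_weight_vector(weights, expr)
  w <- wobj$w
  theta <- wobj$theta

  start <- netbc_init(expr, k, d, method = init, seed = seed)
  R <- start$R
  C <- start$C

  trace <- numeric(0)
  obj_prev <- netbc_objective(expr, R, C, w, ridge)
  stable <- 0L
  iterations <- 0L
  for (it in seq_len(iters)) {
    R <- update_R(expr, R, C, w, eps_guard, ridge, renormalize)
    C <- update_C(expr, R, C, w, eps_guard, ridge, renormalize)
    obj <- netbc_objective(expr, R, C, w, ridge)
    trace <- c(trace, obj)
    iterations <- it
    rel <- abs(obj_prev - obj) / max(abs(obj_prev), .Machine$double.eps)
    stable <- if (rel < rtol) stable + 1L else 0L
    obj_prev <- obj
    if (stable >= 5L) break
  }

  R <- normalize_rows(R)  # report on the sum-to-one feasible set
  C <- normalize_rows(C)
  row_labels <- harden_labels(R, expr, C, w, margin = "row", ridge = ridge)
  col_labels <- harden_labels(C, expr, R, w, margin = "col", ridge = ridge)
  if (refine) {
    ref <- refine_labels(expr, row_labels, col_labels, w, k, d)
    row_labels <- ref$row_labels
    col_labels <- ref$col_labels
  }
  names(row_labels) <- rownames(expr) %||% paste0("g", seq_len(m))
  names(col_labels) <- colnames(expr) %||% paste0("s", seq_len(n))

  structure(
    list(row_labels = row_labels, col_labels = col_labels, R = R, C = C,
         w = w, theta = theta, objective_trace = trace,
         objective = trace[length(trace)], k = k, d = d,
         iterations = iterations, converged = stable >= 5L, seed = seed,
         gene_ids = names(row_labels), sample_ids = names(col_labels)),
    class = "netbc"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-stochastic normalization; rows that underflowed to zero become
# uniform (their assignment is decided by the empty-cluster repair).
normalize_rows <- function(M) {
  rs <- rowSums(M)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) M[bad, ] <- 1
  M / rowSums(M)
}

as_weight_vector <- function(weights, expr) {
  if (is.null(weights)) {
    gw <- gene_weights(expr, network = NULL, theta = 0)
    list(w = as.numeric(gw$w), theta = 0)
  } else if (inherits(weights, "gene_weights")) {
    if (length(weights$w) != nrow(expr)) {
      stop("weights length does not match the number of genes", call. = FALSE)
    }
    list(w = as.numeric(weights$w), theta = weights$theta)
  } else if (is.numeric(weights)) {
    if (length(weights) != nrow(expr)) {
      stop("weights length does not match the number of genes", call. = FALSE)
    }
    if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
    list(w = as.numeric(weights), theta = NA_real_)
  } else {
    stop("weights must be NULL, a gene_weights object or a numeric vector",
         call. = FALSE)
  }
}

# Argmax hardening (ties to smallest index) with empty-cluster repair: a
# cluster left without members receives the item with the largest weighted
# residual contribution, so the requested k (or d) is honoured.
harden_labels <- function(M, G, other, w, margin, ridge) {
  labels <- max.col(M, ties.method = "first")
  n_clusters <- ncol(M)
  missing <- setdiff(seq_len(n_clusters), unique(labels))
  if (length(missing) > 0L) {
    E <- if (margin == "row") {
      netbc_residual(G, M, other, ridge)
    } else {
      t(netbc_residual(G, other, M, ridge))
    }
    contrib <- if (margin == "row") w * rowSums(E * E) else rowSums(E * E)
    for (cl in missing) {
      movable <- which(tabulate(labels, n_clusters)[labels] > 1L)
      if (length(movable) == 0L) break
      worst <- movable[which.max(contrib[movable])]
      labels[worst] <- cl
      contrib[worst] <- -Inf
    }
  }
  labels
}

# Discrete alternating minimization of the weighted sum-squared residue in
# hard label space: batch-reassign every gene to the row cluster whose mean
# profile (with the sample partition fixed) minimizes the gene's weighted
# residual, then every sample symmetrically, until no label moves. A step
# that would empty a cluster is skipped, preserving the requested k and d.
refine_labels <- function(G, rl, cl, w, k, d, max_pass = 100L) {
  rl <- as.integer(rl)
  cl <- as.integer(cl)
  m <- nrow(G)
  n <- ncol(G)
  for (p in seq_len(max_pass)) {
    changed <- FALSE
    rcounts <- tabulate(rl, k)
    ccounts <- tabulate(cl, d)
    row_profiles <- rowsum(G, rl, reorder = TRUE) / pmax(rcounts, 1)  # k x n
    col_mean_i <- (t(rowsum(t(G), cl, reorder = TRUE)) /
                     rep(pmax(ccounts, 1), each = m))[, cl, drop = FALSE]
    block_means <- t(rowsum(t(rowsum(G, rl, reorder = TRUE)), cl,
                            reorder = TRUE)) /
      outer(pmax(rcounts, 1), pmax(ccounts, 1))                       # k x d
    cost <- matrix(0, m, k)
    for (kk in seq_len(k)) {
      resid <- G - row_profiles[rep(kk, m), , drop = FALSE] - col_mean_i +
        matrix(block_means[kk, cl], m, n, byrow = TRUE)
      cost[, kk] <- w * rowSums(resid * resid)
    }
    rl_new <- max.col(-cost, ties.method = "first")
    if (all(tabulate(rl_new, k) > 0L) && !identical(rl_new, rl)) {
      rl <- rl_new
      changed <- TRUE
    }
    rcounts <- tabulate(rl, k)
    col_profiles <- t(rowsum(t(G), cl, reorder = TRUE)) /
      rep(pmax(tabulate(cl, d), 1), each = m)                         # m x d
    row_mean_j <- (rowsum(G, rl, reorder = TRUE) /
                     pmax(rcounts, 1))[rl, , drop = FALSE]
    block_means <- rowsum(t(rowsum(G, rl, reorder = TRUE)), cl,
                          reorder = TRUE) /
      outer(pmax(tabulate(cl, d), 1), pmax(rcounts, 1))               # d x k
    cost <- matrix(0, n, d)
    for (dd in seq_len(d)) {
      resid <- G - col_profiles[, rep(dd, n), drop = FALSE] - row_mean_j +
        matrix(block_means[dd, rl], m, n)
      cost[, dd] <- colSums(w * resid * resid)
    }
    cl_new <- max.col(-cost, ties.method = "first")
    if (all(tabulate(cl_new, d) > 0L) && !identical(cl_new, cl)) {
      cl <- cl_new
      changed <- TRUE
    }
    if (!changed) break
  }
  list(row_labels = rl, col_labels = cl)
}

#' Enumerate checkerboard blocks as bi-clusters
#'
#' Returns every non-empty (gene cluster, sample cluster) block of a fitted
#' checkerboard as a bi-cluster `{genes, samples}`. The union of the blocks
#' covers every cell of the matrix exactly once.
#'
#' @param result A fitted `netbc` object.
#' @return A `bicluster_set`: list of lists with character elements `genes`
#'   and `samples`.
#' @export
extract_biclusters <- function(result) {
  stopifnot(inherits(result, "netbc"))
  blocks <- list()
  for (kk in sort(unique(result$row_labels))) {
    for (dd in sort(unique(result$col_labels))) {
      genes <- names(result$row_labels)[result$row_labels == kk]
      samples <- names(result$col_labels)[result$col_labels == dd]
      if (length(genes) > 0L && length(samples) > 0L) {
        blocks[[length(blocks) + 1L]] <-
          list(genes = genes, samples = samples,
               row_cluster = kk, col_cluster = dd)
      }
    }
  }
  structure(blocks, class = "bicluster_set")
}

#' Select the most coherent checkerboard blocks
#'
#' Ranks the k x d blocks of a fitted checkerboard by their per-cell
#' sum-squared residue (entry minus row mean, column mean, plus block mean,
#' squared, averaged over the block) and returns the `q` most coherent.
#' When a benchmark prescribes a number of bi-clusters (for example the
#' number implanted in a synthetic matrix), this is how a checkerboard fit
#' is reduced to exactly that many reported bi-clusters.
#'
#' @param result A fitted `netbc` object.
#' @param expr The expression matrix that was fitted.
#' @param q Number of blocks to return (capped at the number of non-empty
#'   blocks).
#' @return A `bicluster_set` of the `q` lowest-residue blocks.
#' @export
top_biclusters <- function(result, expr, q) {
  blocks <- extract_biclusters(result)
  score <- vapply(blocks, function(b) {
    sub <- expr[b$genes, b$samples, drop = FALSE]
    res <- sub - rowMeans(sub) -
      matrix(colMeans(sub), nrow(sub), ncol(sub), byrow = TRUE) + mean(sub)
    mean(res * res)
  }, numeric(1L))
  keep <- order(score)[seq_len(min(q, length(blocks)))]
  structure(blocks[keep], class = "bicluster_set")
}

#' @export
print.netbc <- function(x, ...) {
  cat("netbc fit: ", length(x$row_labels), " genes x ",
      length(x$col_labels), " samples into ", x$k, " x ", x$d,
      " checkerboard blocks\n", sep = "")
  cat("  objective ", formatC(x$objective, digits = 6), " after ",
      x$iterations, " iterations",
      if (isTRUE(x$converged)) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat("bicluster_set with", length(x), "bi-cluster(s)\n")
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] %d genes x %d samples\n", i,
                length(x[[i]]$genes), length(x[[i]]$samples)))
  }
  invisible(x)
}

#' Tidy cluster assignments of a fitted bi-clustering
#'
#' @param x A fitted `netbc` object.
#' @param ... Unused.
#' @return A tibble with columns `id`, `dimension` (`"gene"` or
#'   `"sample"`), `cluster`, and `membership` (the item's soft indicator
#'   weight for its assigned cluster).
#' @method tidy netbc
#' @export
tidy.netbc <- function(x, ...) {
  tibble::tibble(
    id = c(names(x$row_labels), names(x$col_labels)),
    dimension = rep(c("gene", "sample"),
                    c(length(x$row_labels), length(x$col_labels))),
    cluster = c(as.integer(x$row_labels), as.integer(x$col_labels)),
    membership = c(x$R[cbind(seq_along(x$row_labels), x$row_labels)],
                   x$C[cbind(seq_along(x$col_labels), x$col_labels)])
  )
}

#' One-row summary of a fitted bi-clustering
#'
#' @param x A fitted `netbc` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `d`, `theta`, `objective`, `iterations`,
#'   `converged`.
#' @method glance netbc
#' @export
glance.netbc <- function(x, ...) {
  tibble::tibble(k = x$k, d = x$d, theta = x$theta,
                 objective = x$objective, iterations = x$iterations,
                 converged = x$converged)
}

#' Plot a fitted bi-clustering
#'
#' `type = "trace"` plots the objective value per iteration;
#' `type = "heatmap"` shows the expression matrix with rows and columns
#' regrouped by their clusters, with cluster boundaries drawn.
#'
#' @param object A fitted `netbc` object.
#' @param expr Expression matrix (required for `type = "heatmap"`).
#' @param type `"trace"` or `"heatmap"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot netbc
#' @export
autoplot.netbc <- function(object, expr = NULL,
                           type = c("trace", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                         objective = object$objective_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "Iteration", y = "Weighted sum-squared residue") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(expr)) stop("heatmap plot needs the expression matrix",
                          call. = FALSE)
  ro <- order(object$row_labels)
  co <- order(object$col_labels)
  df <- tibble::tibble(
    gene = factor(rep(rownames(expr)[ro], times = ncol(expr)),
                  levels = rev(rownames(expr)[ro])),
    sample = factor(rep(colnames(expr)[co], each = nrow(expr)),
                    levels = colnames(expr)[co]),
    value = as.vector(expr[ro, co])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Samples (grouped by cluster)",
                  y = "Genes (grouped by cluster)", fill = "Expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
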