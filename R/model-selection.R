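#' Co-assignment matrix of a label vector
#'
#' `M[i, j] = 1` when items i and j carry the same cluster label, else 0;
#' the diagonal is 1.
#'
#' @param labels Integer (or factor) vector of length >= 2.
#' @return A symmetric 0/1 matrix.
#' @export
coassignment <- function(labels) {
  stopifnot(length(labels) >= 2L)
  labels <- as.integer(as.factor(labels))
  outer(labels, labels, `==`) * 1
}

#' Consensus matrices over repeated bi-clustering runs
#'
#' Runs [netbc()] `n_runs` times with random initialization under seeds
#' `seed, seed + 1, ...` and averages the gene and sample co-assignment
#' matrices. Entry (i, j) of a consensus matrix is the fraction of runs in
#' which the pair co-clustered; a stable (k, d) drives entries towards 0
#' or 1.
#'
#' @param expr Genes x samples matrix.
#' @param k,d Number of gene and sample clusters for each run.
#' @param weights Passed to [netbc()].
#' @param n_runs Number of runs to average (>= 2).
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param ... Further arguments passed to [netbc()] (e.g. `iters`).
#' @return List with `genes` and `samples`, each a `consensus_matrix`
#'   (symmetric, unit diagonal, entries in `[0, 1]`) with attribute
#'   `n_runs`.
#' @export
consensus_matrices <- function(expr, k, d, weights = NULL, n_runs = 20L,
                               seed = 1L, ...) {
  stopifnot(n_runs >= 2L)
  m <- nrow(expr)
  n <- ncol(expr)
  Mg <- matrix(0, m, m)
  Ms <- matrix(0, n, n)
  ok <- 0L
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      netbc(expr, k = k, d = d, weights = weights, init = "random",
            seed = seed + r - 1L, ...),
      error = function(e) {
        warning("consensus run ", r, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(fit)) next
    Mg <- Mg + coassignment(fit$row_labels)
    Ms <- Ms + coassignment(fit$col_labels)
    ok <- ok + 1L
  }
  if (ok < 2L) stop("fewer than 2 successful consensus runs", call. = FALSE)
  list(
    genes = structure(Mg / ok, n_runs = ok, class = "consensus_matrix"),
    samples = structure(Ms / ok, n_runs = ok, class = "consensus_matrix")
  )
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Treats `1 - M` as a distance matrix, clusters it with average-linkage
#' hierarchical clustering, and returns the Pearson correlation between the
#' original distances and the cophenetic distances implied by the tree.
#' Values near 1 indicate a stable, block-like consensus. When either
#' distance vector has zero variance (e.g. an all-ones consensus), the
#' coefficient is returned as 1 by convention, with a warning.
#'
#' @param consensus A square symmetric matrix with entries in `[0, 1]`
#'   (typically from [consensus_matrices()]), size >= 3.
#' @return A scalar in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  consensus <- unclass(consensus)
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus),
            nrow(consensus) >= 3L)
  d_obs <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d_obs, method = "average")
  d_coph <- stats::cophenetic(hc)
  if (stats::sd(d_obs) == 0 || stats::sd(d_coph) == 0) {
    warning("degenerate consensus (zero-variance distances); ",
            "cophenetic correlation set to 1", call. = FALSE)
    return(1)
  }
  stats::cor(as.numeric(d_obs), as.numeric(d_coph))
}

#' Select the number of gene and sample clusters by consensus stability
#'
#' Evaluates every (k, d) combination on a grid by the average of the gene
#' and sample cophenetic correlation coefficients of the consensus matrices
#' over `n_runs` randomly initialized fits, and returns the combination
#' with the largest combined score (ties broken towards the smallest k,
#' then the smallest d).
#'
#' @param expr Genes x samples matrix.
#' @param k_range,d_range Integer vectors of candidate cluster counts.
#' @param weights Passed to [netbc()].
#' @param n_runs Runs per grid cell.
#' @param seed Base seed (each cell reuses the same run seeds, so cells are
#'   comparable).
#' @param ... Further arguments passed to [netbc()].
#' @return A `netbc_selection` object: list with `k`, `d`, and `grid`, a
#'   tibble with columns `k`, `d`, `rho_genes`, `rho_samples`, `combined`.
#' @export
#' @examples
#' sim <- sim_checkerboard(m = 24, n = 12, k = 2, d = 2, seed = 1)
#' sel <- select_k_d(sim$expr, k_range = 2:3, d_range = 2, n_runs = 3,
#'                   seed = 1, iters = 60)
#' sel$grid
select_k_d <- function(expr, k_range, d_range, weights = NULL,
                       n_runs = 20L, seed = 1L, ...) {
  stopifnot(length(k_range) >= 1L, length(d_range) >= 1L)
  grid <- expand.grid(k = sort(unique(as.integer(k_range))),
                      d = sort(unique(as.integer(d_range))))
  rho_g <- rho_s <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cm <- consensus_matrices(expr, k = grid$k[i], d = grid$d[i],
                             weights = weights, n_runs = n_runs,
                             seed = seed, ...)
    rho_g[i] <- suppressWarnings(cophenetic_coefficient(cm$genes))
    rho_s[i] <- suppressWarnings(cophenetic_coefficient(cm$samples))
  }
  out <- tibble::tibble(k = grid$k, d = grid$d, rho_genes = rho_g,
                        rho_samples = rho_s,
                        combined = (rho_g + rho_s) / 2)
  ord <- order(-out$combined, out$k, out$d)
  best <- out[ord[1L], ]
  structure(list(k = best$k, d = best$d, grid = out),
            class = "netbc_selection")
}

#' @export
print.netbc_selection <- function(x, ...) {
  cat("netbc model selection: k =", x$k, ", d =", x$d, "\n")
  print(x$grid)
  invisible(x)
}

#' @rdname select_k_d
#' @param x A `netbc_selection` object.
#' @method tidy netbc_selection
#' @export
tidy.netbc_selection <- function(x, ...) x$grid

#' Plot a model-selection stability grid
#'
#' @param object A `netbc_selection` object from [select_k_d()].
#' @param ... Unused.
#' @return A ggplot tile plot of the combined stability score over the
#'   (k, d) grid, with the selected cell outlined.
#' @method autoplot netbc_selection
#' @export
autoplot.netbc_selection <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(factor(.data$k), factor(.data$d),
                               fill = .data$combined)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = object$grid[object$grid$k == object$k &
                           object$grid$d == object$d, ],
      fill = NA, colour = "black", linewidth = 1
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(NA, 1)) +
    ggplot2::labs(x = "Gene clusters (k)", y = "Sample clusters (d)",
                  fill = "Stability") +
    ggplot2::theme_minimal()
}
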