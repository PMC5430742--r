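#' Per-gene expression variability
#'
#' Scores each gene by the mean absolute deviation of its expression values
#' about the gene's own mean across samples: `e_i = mean_j |g_ij - mean(g_i.)|`.
#' A constant gene scores 0; scaling a gene's row by `c > 0` scales its score
#' by `c`. Standard deviation and range are available as alternatives.
#'
#' @param expr Numeric genes x samples matrix with at least 2 samples.
#' @param method One of `"mad"` (mean absolute deviation about the row mean,
#'   the default), `"sd"`, `"range"`.
#' @return Nonnegative numeric vector of length `nrow(expr)`, named by gene.
#' @export
expression_deviation <- function(expr, method = c("mad", "sd", "range")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2L) {
    stop("need at least 2 samples to measure expression variation",
         call. = FALSE)
  }
  e <- switch(method,
    mad = rowMeans(abs(expr - rowMeans(expr))),
    sd = apply(expr, 1L, stats::sd),
    range = apply(expr, 1L, function(x) diff(range(x)))
  )
  stats::setNames(as.numeric(e), rownames(expr))
}

#' Network-blended gene weights (GeneRank)
#'
#' Assigns each gene a nonnegative importance weight that blends its
#' expression variability `e` with importance received from its interaction
#' partners, via the damped recursion
#' `w_i = (1 - theta) e_i + theta * sum_j P_ij w_j / deg_j`.
#' The fixed point solves the linear system `(I - theta P D^-1) w =
#' (1 - theta) e`, where `D` is the diagonal degree matrix (zero-degree
#' columns of `P D^-1` are treated as all-zero, so isolated genes are still
#' reached through the `(1 - theta) e` term). `theta = 0` returns weights
#' proportional to `e` alone; `theta = 1` (iterative method only) uses the
#' network alone. Weights are rescaled to mean 1 so that objective values
#' are comparable across `theta`.
#'
#' @param expr Expression matrix (used to compute `e` unless `e` is given).
#' @param network A `gene_network` from [align_network()], or `NULL` for no
#'   network (all degrees zero; weights are then proportional to `e`).
#' @param theta Damping parameter in `[0, 1]`; `[0, 1)` for the direct
#'   solver. The conventional setting is 0.85.
#' @param e Optional precomputed variability vector (length = genes).
#' @param method `"direct"` (sparse linear solve, default for `theta < 1`)
#'   or `"iterative"` (fixed-point iteration from `w = e`, required at
#'   `theta = 1`).
#' @param deviation Variability measure passed to [expression_deviation()].
#' @param tol Max-norm convergence tolerance for the iterative method.
#' @param max_iter Iteration cap for the iterative method.
#' @return A `gene_weights` object: list with `w` (named, nonnegative,
#'   mean 1), `e`, `theta`, `method`, and for the iterative path
#'   `iterations` and `converged`.
#' @export
#' @examples
#' expr <- matrix(rnorm(20), 5, 4,
#'                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' gene_weights(expr, network = NULL, theta = 0)
gene_weights <- function(expr = NULL, network = NULL, theta = 0.85,
                         e = NULL, method = c("direct", "iterative"),
                         deviation = "mad", tol = 1e-10, max_iter = 1000L) {
  method <- match.arg(method)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]", call. = FALSE)
  }
  if (theta == 1 && method == "direct") {
    method <- "iterative"  # (I - P D^-1) is singular; only the recursion applies
  }
  if (is.null(e)) {
    if (is.null(expr)) stop("either expr or e must be supplied", call. = FALSE)
    e <- expression_deviation(expr, method = deviation)
  }
  if (any(e < 0) || any(!is.finite(e))) {
    stop("expression-variation scores must be finite and nonnegative",
         call. = FALSE)
  }
  m <- length(e)
  if (is.null(network)) {
    PD <- NULL
  } else {
    stopifnot(inherits(network, "gene_network"))
    if (nrow(network$adjacency) != m) {
      stop("network has ", nrow(network$adjacency), " genes but e has ", m,
           call. = FALSE)
    }
    PD <- column_normalize(network$adjacency, network$degrees)
  }

  if (method == "direct") {
    w <- generank_direct(PD, e, theta)
    iterations <- NA_integer_
    converged <- TRUE
  } else {
    it <- generank_iterative(PD, e, theta, tol = tol, max_iter = max_iter)
    w <- it$w
    iterations <- it$iterations
    converged <- it$converged
  }

  w <- pmax(w, 0)
  if (sum(w) > 0) {
    w <- w / mean(w)
  } else {
    warning("degenerate gene weights (all zero); falling back to uniform",
            call. = FALSE)
    w <- rep(1, m)
  }
  structure(
    list(w = stats::setNames(w, names(e)), e = e, theta = theta,
         method = method, iterations = iterations, converged = converged),
    class = "gene_weights"
  )
}

# P D^-1 with zero-degree columns left all-zero.
column_normalize <- function(P, degrees) {
  inv <- ifelse(degrees > 0, 1 / degrees, 0)
  P %*% Matrix::Diagonal(x = inv)
}

generank_direct <- function(PD, e, theta) {
  if (theta >= 1) stop("direct solve requires theta < 1", call. = FALSE)
  m <- length(e)
  if (is.null(PD) || theta == 0) {
    return((1 - theta) * e)
  }
  M <- Matrix::Diagonal(m) - theta * PD
  as.numeric(Matrix::solve(M, (1 - theta) * e))
}

generank_iterative <- function(PD, e, theta, tol, max_iter) {
  stopifnot(tol > 0)
  w <- e
  if (theta == 0 || is.null(PD)) {
    return(list(w = (1 - theta) * e + theta * 0 * e,
                iterations = 1L, converged = TRUE))
  }
  converged <- FALSE
  iterations <- max_iter
  for (t in seq_len(max_iter)) {
    w_new <- (1 - theta) * e + theta * as.numeric(PD %*% w)
    if (max(abs(w_new - w)) < tol) {
      converged <- TRUE
      iterations <- t
      w <- w_new
      break
    }
    w <- w_new
  }
  if (!converged) {
    warning("gene-weight recursion did not converge in ", max_iter,
            " iterations (theta = ", theta, "); returning last iterate",
            call. = FALSE)
  }
  list(w = w, iterations = iterations, converged = converged)
}

#' @export
print.gene_weights <- function(x, ...) {
  cat("gene_weights: ", length(x$w), " genes, theta = ", x$theta,
      ", method = ", x$method, "\n", sep = "")
  cat("  weight range: [", formatC(min(x$w), digits = 4), ", ",
      formatC(max(x$w), digits = 4), "], mean 1\n", sep = "")
  invisible(x)
}

#' @rdname gene_weights
#' @param x A `gene_weights` object.
#' @param ... Unused.
#' @method tidy gene_weights
#' @export
tidy.gene_weights <- function(x, ...) {
  tibble::tibble(gene = names(x$w), weight = as.numeric(x$w),
                 deviation = as.numeric(x$e))
}
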