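#' Standard-normal background expression matrix
#'
#' @param m,n Number of genes and samples.
#' @param seed Optional integer seed.
#' @return An m x n matrix of i.i.d. N(0, 1) entries with gene names
#'   `g1..gm` and sample names `s1..sn`.
#' @export
sim_background <- function(m, n, seed = NULL) {
  stopifnot(m >= 1L, n >= 1L)
  with_seed(seed, {
    matrix(stats::rnorm(m * n), m, n,
           dimnames = list(paste0("g", seq_len(m)), paste0("s", seq_len(n))))
  })
}

# Rewrite one submatrix in place according to one of the five bi-cluster
# archetypes. `sub` keeps its dimensions; the pattern is drawn from the
# submatrix's own entries so implants stay on the scale of the background.
implant_block <- function(sub, type, shift_sd = 2, scale_range = c(0.5, 2)) {
  nr <- nrow(sub)
  nc <- ncol(sub)
  switch(type,
    constant = {
      v <- sub[sample.int(nr, 1L), sample.int(nc, 1L)]
      matrix(v, nr, nc)
    },
    row_constant = {
      base <- sub[, sample.int(nc, 1L)]
      matrix(base, nr, nc)
    },
    column_constant = {
      base <- sub[sample.int(nr, 1L), ]
      matrix(base, nr, nc, byrow = TRUE)
    },
    additive = {
      base <- sub[sample.int(nr, 1L), ]
      shifts <- stats::rnorm(nr, sd = shift_sd)
      matrix(base, nr, nc, byrow = TRUE) + shifts
    },
    multiplicative = {
      base <- sub[sample.int(nr, 1L), ]
      scales <- stats::runif(nr, scale_range[1L], scale_range[2L]) *
        sample(c(-1, 1), nr, replace = TRUE)
      matrix(base, nr, nc, byrow = TRUE) * scales
    },
    stop("unknown bi-cluster type: ", type, call. = FALSE)
  )
}

#' Implant bi-clusters of one archetype into a matrix
#'
#' Each (row set, column set) pair is rewritten according to the chosen
#' pattern: `constant` copies one randomly chosen entry to every cell;
#' `row_constant` copies a random base column across the block (every row
#' constant); `column_constant` copies a random base row down the block;
#' `additive` shifts the base row by a per-row N(0, `shift_sd`^2) offset;
#' `multiplicative` scales the base row by a per-row factor drawn uniform
#' from `scale_range` with random sign. Row sets must be pairwise
#' disjoint, and likewise column sets (non-overlapping implants).
#'
#' @param values Background matrix (with dimnames).
#' @param row_sets,col_sets Lists of integer index vectors, one pair per
#'   bi-cluster.
#' @param type One of `"constant"`, `"row_constant"`, `"column_constant"`,
#'   `"additive"`, `"multiplicative"`.
#' @param seed Optional integer seed.
#' @param shift_sd Standard deviation of additive per-row shifts.
#' @param scale_range Magnitude range of multiplicative per-row scales.
#' @return List with `values` (modified matrix) and `truth`, a
#'   `bicluster_set` of the implanted blocks (identifier sets).
#' @export
sim_implant <- function(values, row_sets, col_sets,
                        type = c("constant", "row_constant",
                                 "column_constant", "additive",
                                 "multiplicative"),
                        seed = NULL, shift_sd = 2, scale_range = c(0.5, 2)) {
  type <- match.arg(type)
  stopifnot(length(row_sets) == length(col_sets), length(row_sets) >= 1L)
  if (anyDuplicated(unlist(row_sets)) || anyDuplicated(unlist(col_sets))) {
    stop("implanted bi-clusters must not overlap in rows or columns",
         call. = FALSE)
  }
  stopifnot(max(unlist(row_sets)) <= nrow(values),
            max(unlist(col_sets)) <= ncol(values))
  with_seed(seed, {
    truth <- vector("list", length(row_sets))
    for (b in seq_along(row_sets)) {
      ri <- row_sets[[b]]
      ci <- col_sets[[b]]
      values[ri, ci] <- implant_block(values[ri, ci, drop = FALSE], type,
                                      shift_sd, scale_range)
      truth[[b]] <- list(genes = rownames(values)[ri],
                         samples = colnames(values)[ci])
    }
    list(values = values, truth = structure(truth, class = "bicluster_set"))
  })
}

#' Add i.i.d. Gaussian noise
#'
#' @param values Numeric matrix.
#' @param sigma Noise standard deviation (>= 0; 0 returns the input).
#' @param seed Optional integer seed.
#' @return The matrix plus N(0, sigma^2) noise on every entry.
#' @export
sim_add_noise <- function(values, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(values)
  with_seed(seed, {
    values + matrix(stats::rnorm(length(values), sd = sigma),
                    nrow(values), ncol(values))
  })
}

#' Benchmark matrix with implanted bi-clusters in a random background
#'
#' Generates an N(0, 1) background, places `n_biclusters` non-overlapping
#' blocks of `bicluster_rows` x `bicluster_cols` on randomly chosen
#' disjoint row and column index sets, implants the chosen pattern, and
#' adds N(0, sigma^2) noise. The default geometry (100 x 50 with three
#' 15 x 8 implants) is the package's desk-scale benchmark condition.
#'
#' @param m,n Matrix dimensions.
#' @param n_biclusters Number of implanted blocks.
#' @param bicluster_rows,bicluster_cols Block dimensions.
#' @param type Bi-cluster archetype, see [sim_implant()].
#' @param sigma Noise standard deviation.
#' @param seed Optional integer seed.
#' @param ... Passed to [sim_implant()] (`shift_sd`, `scale_range`).
#' @return List with `expr` (matrix), `truth` (`bicluster_set`),
#'   `row_labels` and `col_labels` (named truth labels; implants are
#'   clusters `1..n_biclusters`, background rows/columns form cluster
#'   `n_biclusters + 1`).
#' @export
sim_implanted <- function(m = 100L, n = 50L, n_biclusters = 3L,
                          bicluster_rows = 15L, bicluster_cols = 8L,
                          type = "constant", sigma = 0, seed = NULL, ...) {
  stopifnot(n_biclusters * bicluster_rows <= m,
            n_biclusters * bicluster_cols <= n)
  with_seed(seed, {
    G <- matrix(stats::rnorm(m * n), m, n,
                dimnames = list(paste0("g", seq_len(m)),
                                paste0("s", seq_len(n))))
    rows <- sample.int(m, n_biclusters * bicluster_rows)
    cols <- sample.int(n, n_biclusters * bicluster_cols)
    row_sets <- split(rows, rep(seq_len(n_biclusters), each = bicluster_rows))
    col_sets <- split(cols, rep(seq_len(n_biclusters), each = bicluster_cols))
    imp <- sim_implant(G, row_sets, col_sets, type = type, ...)
    expr <- sim_add_noise(imp$values, sigma)
    row_labels <- rep.int(n_biclusters + 1L, m)
    col_labels <- rep.int(n_biclusters + 1L, n)
    for (b in seq_len(n_biclusters)) {
      row_labels[row_sets[[b]]] <- b
      col_labels[col_sets[[b]]] <- b
    }
    list(expr = expr, truth = imp$truth,
         row_labels = stats::setNames(row_labels, rownames(expr)),
         col_labels = stats::setNames(col_labels, colnames(expr)))
  })
}

#' Full checkerboard matrix of patterned blocks
#'
#' Partitions all m genes into k groups and all n samples into d groups
#' (balanced, contiguous) and implants every one of the k x d blocks with
#' the chosen archetype, then adds noise. With `sigma = 0` and types
#' `constant` through `additive`, the sum-squared residue at the truth
#' partition is exactly zero, which makes this the reference condition for
#' recovery and model-selection studies.
#'
#' @param m,n Matrix dimensions.
#' @param k,d Number of gene and sample clusters.
#' @param type Bi-cluster archetype, see [sim_implant()].
#' @param sigma Noise standard deviation.
#' @param seed Optional integer seed.
#' @param ... Passed to [sim_implant()].
#' @return List with `expr`, `truth` (all k x d blocks as a
#'   `bicluster_set`), `row_labels`, `col_labels` (named truth labels in
#'   `1..k` / `1..d`).
#' @export
sim_checkerboard <- function(m, n, k, d, type = "constant", sigma = 0,
                             seed = NULL, ...) {
  stopifnot(k >= 1L, d >= 1L, k <= m, d <= n)
  with_seed(seed, {
    G <- matrix(stats::rnorm(m * n), m, n,
                dimnames = list(paste0("g", seq_len(m)),
                                paste0("s", seq_len(n))))
    row_labels <- sort(rep(seq_len(k), length.out = m))
    col_labels <- sort(rep(seq_len(d), length.out = n))
    truth <- list()
    for (kk in seq_len(k)) {
      for (dd in seq_len(d)) {
        ri <- which(row_labels == kk)
        ci <- which(col_labels == dd)
        G[ri, ci] <- implant_block(G[ri, ci, drop = FALSE], type, ...)
        truth[[length(truth) + 1L]] <- list(genes = rownames(G)[ri],
                                            samples = colnames(G)[ci])
      }
    }
    expr <- sim_add_noise(G, sigma)
    list(expr = expr,
         truth = structure(truth, class = "bicluster_set"),
         row_labels = stats::setNames(row_labels, rownames(expr)),
         col_labels = stats::setNames(col_labels, colnames(expr)))
  })
}

#' Replace low-weight genes by uniform noise
#'
#' Emulates uninformative "noisy genes": the `n_noisy` genes with the
#' lowest weights have their expression rows replaced by i.i.d. uniform
#' draws spanning the observed range of the whole matrix.
#'
#' @param expr Genes x samples matrix.
#' @param weights A `gene_weights` object or numeric vector aligned to the
#'   genes.
#' @param n_noisy Number of genes to replace (`< nrow(expr)`).
#' @param seed Optional integer seed.
#' @return List with `expr` (modified matrix) and `noisy_genes` (character
#'   vector of replaced gene identifiers).
#' @export
inject_noisy_genes <- function(expr, weights, n_noisy, seed = NULL) {
  stopifnot(n_noisy >= 0L, n_noisy < nrow(expr))
  w <- if (inherits(weights, "gene_weights")) weights$w else weights
  stopifnot(length(w) == nrow(expr))
  if (n_noisy == 0L) {
    return(list(expr = expr, noisy_genes = character(0)))
  }
  idx <- order(w)[seq_len(n_noisy)]
  lo <- min(expr)
  hi <- max(expr)
  with_seed(seed, {
    expr[idx, ] <- matrix(stats::runif(n_noisy * ncol(expr), lo, hi),
                          n_noisy, ncol(expr))
    list(expr = expr, noisy_genes = rownames(expr)[idx])
  })
}

# -- network perturbation ----------------------------------------------------

# Pairs are encoded as (i - 1) * m + j. For undirected networks only i < j
# codes are used and edges are symmetrized on reconstruction.
edge_codes <- function(net) {
  m <- nrow(net$adjacency)
  idx <- Matrix::which(net$adjacency != 0, arr.ind = TRUE)
  if (!net$directed) idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  (idx[, 1L] - 1L) * m + idx[, 2L]
}

all_pair_codes <- function(m, directed) {
  i <- rep(seq_len(m), each = m)
  j <- rep(seq_len(m), times = m)
  keep <- if (directed) i != j else i < j
  (i[keep] - 1L) * m + j[keep]
}

codes_to_network <- function(codes, m, directed, genes) {
  i <- (codes - 1L) %/% m + 1L
  j <- (codes - 1L) %% m + 1L
  if (!directed) {
    ii <- c(i, j)
    j <- c(j, i)
    i <- ii
  }
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(m, m),
                              dimnames = list(genes, genes))
  if (length(adj@x)) adj@x[] <- 1
  new_gene_network(adj, directed)
}

#' Randomly add, delete and rewire network edges
#'
#' Deletes `n_delete` uniformly chosen existing edges, adds `n_add`
#' uniformly chosen non-edges, and performs `n_rewire` rewirings (each
#' deletes one random edge and adds one random non-edge, conserving the
#' edge count). Symmetry is preserved for undirected networks, and no
#' duplicate edges or self-loops are ever introduced.
#'
#' @param net A `gene_network`.
#' @param n_add,n_delete,n_rewire Operation counts (defaults 0).
#' @param seed Optional integer seed.
#' @return A perturbed `gene_network` over the same genes.
#' @export
perturb_network <- function(net, n_add = 0L, n_delete = 0L, n_rewire = 0L,
                            seed = NULL) {
  stopifnot(inherits(net, "gene_network"),
            n_add >= 0L, n_delete >= 0L, n_rewire >= 0L)
  m <- nrow(net$adjacency)
  genes <- rownames(net$adjacency)
  edges <- edge_codes(net)
  non_edges <- setdiff(all_pair_codes(m, net$directed), edges)
  if (n_delete + n_rewire > length(edges)) {
    stop("not enough edges: need ", n_delete + n_rewire, ", have ",
         length(edges), call. = FALSE)
  }
  if (n_add + n_rewire > length(non_edges)) {
    stop("not enough non-edges: need ", n_add + n_rewire, ", have ",
         length(non_edges), call. = FALSE)
  }
  with_seed(seed, {
    if (n_delete > 0L) {
      del <- sample(seq_along(edges), n_delete)
      non_edges <- c(non_edges, edges[del])
      edges <- edges[-del]
    }
    if (n_add > 0L) {
      add <- sample(seq_along(non_edges), n_add)
      edges <- c(edges, non_edges[add])
      non_edges <- non_edges[-add]
    }
    for (r in seq_len(n_rewire)) {
      del <- sample(seq_along(edges), 1L)
      removed <- edges[del]
      edges <- edges[-del]
      non_edges <- c(non_edges, removed)
      add <- sample(seq_along(non_edges), 1L)
      edges <- c(edges, non_edges[add])
      non_edges <- non_edges[-add]
    }
    codes_to_network(edges, m, net$directed, genes)
  })
}

#' Synthetic network with informative-gene hubs
#'
#' Undirected random network in which every pair touching an informative
#' gene is connected with probability `p_hub` and every other pair with
#' probability `p_background`. With `p_hub >> p_background` the
#' informative genes become hubs, emulating the situation where genes that
#' carry the clustering signal are also well connected in the interaction
#' network.
#'
#' @param m Number of genes (named `g1..gm` to match [sim_background()]).
#' @param informative Integer indices of the informative genes.
#' @param p_hub Edge probability for pairs touching an informative gene.
#' @param p_background Edge probability for all remaining pairs.
#' @param seed Optional integer seed.
#' @return An undirected `gene_network`.
#' @export
sim_structured_network <- function(m, informative, p_hub = 0.2,
                                   p_background = 0.01, seed = NULL) {
  stopifnot(m >= 2L, all(informative >= 1L), all(informative <= m))
  is_inf <- logical(m)
  is_inf[informative] <- TRUE
  i <- rep(seq_len(m), each = m)
  j <- rep(seq_len(m), times = m)
  keep <- i < j
  i <- i[keep]
  j <- j[keep]
  p <- ifelse(is_inf[i] | is_inf[j], p_hub, p_background)
  genes <- paste0("g", seq_len(m))
  with_seed(seed, {
    on <- stats::runif(length(p)) < p
    codes <- (i[on] - 1L) * m + j[on]
    codes_to_network(codes, m, directed = FALSE, genes = genes)
  })
}
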