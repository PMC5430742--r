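#' Read a gene expression matrix from tab-separated text
#'
#' The expected dialect is a TSV with a mandatory header row of sample
#' identifiers and gene identifiers in the first column; every body cell must
#' be numeric. Rows are genes, columns are samples, as is conventional for
#' expression matrices. No imputation is attempted: any missing or
#' non-numeric cell is an error naming the offending gene and sample.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (genes x samples) with unique rownames (gene
#'   identifiers) and colnames (sample identifiers).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_expression(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                    paste0("s", 1:2))), f)
#' read_expression(f)
read_expression <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L || nrow(df) < 2L) {
    stop("expression matrix must have at least 2 genes and 2 samples, got ",
         nrow(df), " x ", ncol(df) - 1L, call. = FALSE)
  }
  gene_ids <- trimws(df[[1L]])
  sample_ids <- trimws(colnames(df)[-1L])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or missing value at gene '", gene_ids[bad[1L, 1L]],
         "', sample '", sample_ids[bad[1L, 2L]], "'", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: gene identifiers in the first column
#' (header `gene_id`), sample identifiers as the remaining header fields.
#' Values are written with full double precision so a write/read round trip
#' is bit-identical.
#'
#' @param values Numeric matrix with rownames and colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  header <- paste(c("gene_id", colnames(values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i],
            formatC(values[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a gene interaction network edge list
#'
#' Two-column tab-separated text of gene identifiers, one edge per line;
#' lines beginning with `#` are comments. Duplicate edges and self-loops are
#' removed, with counts reported as messages.
#'
#' @param path Path to the edge-list file.
#' @return A two-column character matrix of edges (columns `from`, `to`).
#' @export
read_network <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 2L)) {
    bad <- which(n_fields < 2L)[1L]
    stop("malformed network line ", bad, ": '", lines[bad], "'",
         call. = FALSE)
  }
  from <- trimws(vapply(parts, `[[`, character(1L), 1L))
  to <- trimws(vapply(parts, `[[`, character(1L), 2L))
  self <- from == to
  if (any(self)) {
    message(sum(self), " self-loop(s) removed")
    from <- from[!self]
    to <- to[!self]
  }
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) removed")
    from <- from[!dup]
    to <- to[!dup]
  }
  cbind(from = from, to = to)
}

#' Align a network edge list to the gene order of an expression matrix
#'
#' Builds the m x m sparse 0/1 adjacency matrix `P` over the expression
#' matrix's genes. Edges with an endpoint absent from the expression matrix
#' are dropped (count reported); genes absent from the network keep all-zero
#' rows and columns (degree 0). For undirected networks both `P[i, j]` and
#' `P[j, i]` are set. The degree of gene j is the column sum of `P`, i.e. the
#' number of genes interacting with (pointing at) gene j.
#'
#' @param edges Two-column character matrix of gene-identifier pairs, as
#'   returned by [read_network()].
#' @param expr Expression matrix whose rownames define the gene order.
#' @param directed Logical; if `FALSE` (default) each edge is symmetrized.
#' @return A `gene_network` object: list with `adjacency` (sparse m x m
#'   0/1 Matrix), `directed`, and `degrees` (named integer column sums).
#' @export
align_network <- function(edges, expr, directed = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  genes <- rownames(expr)
  m <- length(genes)
  if (is.null(edges) || nrow(edges) == 0L) {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(m, m),
                                dimnames = list(genes, genes))
    return(new_gene_network(adj, directed))
  }
  i <- match(edges[, 1L], genes)
  j <- match(edges[, 2L], genes)
  keep <- !is.na(i) & !is.na(j)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " edge(s) dropped (endpoint not in expression matrix)")
  }
  i <- i[keep]
  j <- j[keep]
  if (length(i) == 0L) {
    warning("no network edge matches the expression genes; ",
            "network is all-zero", call. = FALSE)
  }
  if (!directed) {
    ii <- c(i, j)
    j <- c(j, i)
    i <- ii
  }
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(m, m),
                              dimnames = list(genes, genes))
  adj@x[] <- 1  # duplicated (i,j) pairs collapse to 1, keeping P binary
  new_gene_network(adj, directed)
}

new_gene_network <- function(adjacency, directed) {
  degrees <- Matrix::colSums(adjacency)
  structure(
    list(adjacency = adjacency, directed = directed,
         degrees = stats::setNames(as.integer(degrees),
                                   colnames(adjacency))),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  m <- nrow(x$adjacency)
  n_edges <- Matrix::nnzero(x$adjacency)
  if (!x$directed) n_edges <- n_edges / 2
  cat("gene_network: ", m, " genes, ", n_edges,
      if (x$directed) " directed" else " undirected", " edges\n", sep = "")
  invisible(x)
}

#' Write bi-clustering results to a directory
#'
#' Writes `row_labels.tsv` (gene_id, cluster), `col_labels.tsv` (sample_id,
#' cluster), `biclusters.json` (list of `{genes: [...], samples: [...]}`)
#' and `objective_trace.tsv`. Identifiers, never indices, appear in the
#' files.
#'
#' @param result A fitted `netbc` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_netbc <- function(result, dir) {
  stopifnot(inherits(result, "netbc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_labels(result$row_labels, file.path(dir, "row_labels.tsv"), "gene_id")
  write_labels(result$col_labels, file.path(dir, "col_labels.tsv"), "sample_id")
  blocks <- extract_biclusters(result)
  jsonlite::write_json(
    lapply(blocks, function(b) list(genes = b$genes, samples = b$samples)),
    file.path(dir, "biclusters.json")
  )
  writeLines(
    c("iteration\tobjective",
      paste(seq_along(result$objective_trace),
            formatC(result$objective_trace, format = "g", digits = 17),
            sep = "\t")),
    file.path(dir, "objective_trace.tsv")
  )
  invisible(dir)
}

write_labels <- function(labels, path, id_name) {
  writeLines(
    c(paste(id_name, "cluster", sep = "\t"),
      paste(names(labels), labels, sep = "\t")),
    path
  )
  invisible(path)
}

#' Read a label assignment written by [write_netbc()]
#'
#' @param path Path to a two-column TSV (identifier, cluster).
#' @return Named integer vector of cluster labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}
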