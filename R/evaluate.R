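#' Pair-agreement counts between two partitions
#'
#' Counts the unordered item pairs that are (np1) together in both the
#' reference partition and the predicted partition, (np2) together in the
#' reference but split in the prediction, (np3) split in the reference but
#' together in the prediction, and (np4) split in both. The four counts
#' always sum to `choose(n, 2)`.
#'
#' @param truth,pred Equal-length label vectors (n >= 2); labels are
#'   compared only for equality, so their values are arbitrary.
#' @return Named integer vector `c(np1, np2, np3, np4)`.
#' @export
pair_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2L)
  tab <- table(truth, pred)
  n <- length(truth)
  total <- choose(n, 2)
  np1 <- sum(choose(tab, 2))
  same_truth <- sum(choose(rowSums(tab), 2))
  same_pred <- sum(choose(colSums(tab), 2))
  np2 <- same_truth - np1
  np3 <- same_pred - np1
  np4 <- total - np1 - np2 - np3
  c(np1 = np1, np2 = np2, np3 = np3, np4 = np4)
}

#' Rand index
#'
#' Fraction of item pairs on which two partitions agree:
#' `(np1 + np4) / (np1 + np2 + np3 + np4)`.
#'
#' @param truth,pred Label vectors, or `truth` may be a precomputed result
#'   of [pair_counts()] (then `pred` is omitted).
#' @return A scalar in `[0, 1]`; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
rand_index <- function(truth, pred = NULL) {
  counts <- if (is.null(pred)) truth else pair_counts(truth, pred)
  unname((counts["np1"] + counts["np4"]) / sum(counts))
}

#' Pairwise precision, recall and F1
#'
#' Precision `np1 / (np1 + np3)` and recall `np1 / (np1 + np2)` over item
#' pairs, with F1 their harmonic mean. Any ratio with a zero denominator
#' (including F1 when both precision and recall are zero) is defined as 0.
#'
#' @inheritParams rand_index
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
f1_measure <- function(truth, pred = NULL) {
  counts <- if (is.null(pred)) truth else pair_counts(truth, pred)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  pr <- safe_div(counts[["np1"]], counts[["np1"]] + counts[["np3"]])
  re <- safe_div(counts[["np1"]], counts[["np1"]] + counts[["np2"]])
  f1 <- safe_div(2 * pr * re, pr + re)
  c(precision = pr, recall = re, f1 = f1)
}

# Best-match mean Jaccard of gene sets of `from` against `against`.
gene_set_match <- function(from, against) {
  scores <- vapply(from, function(b) {
    g <- b$genes
    max(vapply(against, function(t) {
      length(intersect(g, t$genes)) / length(union(g, t$genes))
    }, numeric(1L)))
  }, numeric(1L))
  mean(scores)
}

#' Bi-cluster relevance
#'
#' Average, over the discovered bi-clusters, of the best Jaccard overlap
#' of each discovered gene set with any implanted gene set. Measures to
#' what extent the discovered bi-clusters represent the implanted ones in
#' the gene dimension; sample sets are carried in the objects but do not
#' enter the score.
#'
#' @param discovered,truth `bicluster_set` objects (or plain lists of
#'   `list(genes=, samples=)`), both non-empty.
#' @return A scalar in `[0, 1]`.
#' @export
bicluster_relevance <- function(discovered, truth) {
  stopifnot(length(discovered) >= 1L, length(truth) >= 1L)
  gene_set_match(discovered, truth)
}

#' Bi-cluster recovery
#'
#' [bicluster_relevance()] with the arguments swapped: average best
#' Jaccard of each implanted gene set against the discovered ones, i.e.
#' how well the implanted bi-clusters are covered.
#'
#' @inheritParams bicluster_relevance
#' @return A scalar in `[0, 1]`.
#' @export
bicluster_recovery <- function(discovered, truth) {
  bicluster_relevance(truth, discovered)
}

#' Score a predicted partition against a reference
#'
#' Convenience wrapper returning all pair-counting scores as one tidy row.
#'
#' @param truth,pred Equal-length label vectors.
#' @return A one-row tibble: `ri`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' evaluate_partition(c(1, 1, 2, 2), c(1, 1, 1, 2))
evaluate_partition <- function(truth, pred) {
  counts <- pair_counts(truth, pred)
  f <- f1_measure(counts)
  tibble::tibble(ri = rand_index(counts),
                 precision = f[["precision"]],
                 recall = f[["recall"]],
                 f1 = f[["f1"]])
}

#' Read a bi-cluster set from JSON
#'
#' Reads the `biclusters.json` format written by [write_netbc()]: a list
#' of objects with `genes` and `samples` arrays of identifier strings.
#'
#' @param path Path to the JSON file.
#' @return A `bicluster_set`.
#' @export
read_biclusters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  structure(
    lapply(raw, function(b) list(genes = as.character(b$genes),
                                 samples = as.character(b$samples))),
    class = "bicluster_set"
  )
}
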