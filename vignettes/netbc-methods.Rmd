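---
title: "Network-aided bi-clustering: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-aided bi-clustering: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbc)
```

## The problem

Expression studies of tumour cohorts ask a two-sided question: which
samples form subtypes, and which genes define each subtype? A bi-cluster —
a gene subset crossed with a sample subset whose entries share a pattern —
answers both at once. `netbc` searches for a *checkerboard*: a simultaneous
partition of all m genes into k clusters and all n samples into d clusters,
whose k x d blocks are the bi-clusters. Checkerboards cannot express
overlapping or free-floating bi-clusters, but they cover the dominant use
case for subtype discovery, where every sample must receive a subtype and
every gene a module.

A second, independent idea enters through a gene interaction network. Genes
that interact with many partners and vary strongly across samples are more
informative about subtype structure than genes that merely fluctuate. The
package therefore weights each gene's contribution to the fit by a
PageRank-style score that blends expression variability with importance
received from network neighbours.

## Model and objective

Let `G` be the m x n expression matrix, `R` (m x k) and `C` (n x d)
nonnegative indicator matrices whose rows encode cluster membership, and
`W = diag(w)` the per-gene weights. Writing `P_R = R (R'R)^{-1} R'` and
`P_C = C (C'C)^{-1} C'`, the fitted objective is the weighted squared
Frobenius norm of the doubly centred residual

    Phi(R, C) = || (I - P_R) G (I - P_C) ||^2_W
              = sum_i w_i * sum_j residual_ij^2 .

For hard (one-hot) `R` and `C` this is exactly the classical sum-squared
residue: within each block, every entry is compared against its row mean,
column mean and block mean. The residue vanishes identically on blocks that
are constant, constant by row, constant by column, or additively coherent
(`g_ij = u + alpha_i + beta_j`), so the objective rewards "coherent trends",
not only flat blocks. Multiplicatively coherent blocks
(`g_ij = u * alpha_i * beta_j`) are *not* in the nullspace; they are
recovered only approximately.

## Gene weights

Per-gene variability is scored as the mean absolute deviation about the
row mean, `e_i = mean_j |g_ij - mean(g_i.)|` (standard deviation and range
are available alternatives; MAD is the default because it is the most
literal "average absolute change across samples" and is robust to single
outlying samples). Given the binary adjacency `P` (column degree `deg_j`)
and a damping parameter `theta` in [0, 1], the weights solve

    (I - theta * P D^{-1}) w = (1 - theta) * e ,

equivalently the fixed point of
`w_i <- (1-theta) e_i + theta * sum_j P_ij w_j / deg_j`. `theta = 0` uses
expression variability alone; `theta = 1` (iterative path only — the system
matrix is singular there) uses the network alone; 0.85 is the conventional
blend. Columns of `P D^{-1}` with zero degree are left all-zero, so
isolated genes are reached only through the `(1-theta) e` term and never
lose their expression-based weight. Weights are rescaled to mean 1: the
objective is homogeneous in `W`, and a fixed scale makes objective values
comparable across `theta`.

The weight matrix `W` is m x m over genes: the weighted sum in the
objective runs over genes, so the gene-sided convention is the only
consistent one.

## Optimization

`netbc()` alternates multiplicative updates derived from the KKT conditions
of each subproblem. With `X1 = G (I - P_C)`, `X2 = (R'R)^{-1} R' X1`,
`A = W X1 X2'`, `B = X2 X2'` and the split `M = M+ - M-` into positive and
negative parts,

    R <- R * sqrt( (A+ + W R B-) / (A- + W R B+) ) ,

and symmetrically for `C` with `X3 = (I - P_R) G`, `X4 = X3 C (C'C)^{-1}`,
`Dm = X3' W X4`, `F = X4' W X4`. Numerical choices that matter:

* **0/0 guard.** A small epsilon (1e-12) is added to *both* numerator and
  denominator. On exactly fitted data both sides of an update entry are
  zero; the stabilized ratio is then 1 and the entry stays put. (Flooring
  only the denominator sends such entries to zero and lets a perfect
  solution drift away.)
* **Ridge.** `(R'R)^{-1}` and `(C'C)^{-1}` are computed with a relative
  ridge `1e-10 * trace/k`, which keeps near-empty soft clusters from
  making the solve ill-conditioned.
* **Scaling.** The residue is invariant to rescaling indicator *columns*,
  and the update factor is equivariant under it, so after every update each
  column is rescaled to unit maximum purely for floating-point hygiene.
  Row sums are normalized to 1 only on output: renormalizing rows inside
  the loop changes the objective (the projector is not row-scale
  invariant) and measurably breaks the monotone descent of the updates,
  so it is off by default (`renormalize` switches it back on).
* **Stopping.** A fixed cap of 300 alternations (the method's conventional
  setting), with early exit once the relative objective change stays below
  `rtol = 1e-8` for 5 consecutive iterations.

### Hardening

The relaxation optimized above is continuous; cluster labels require a hard
partition. The optimum of the relaxation is generally *interior*: soft
indicator subspaces absorb noise that no hard partition can, so the naive
row-wise argmax of `R` can sit far from any good hard checkerboard.
`netbc()` therefore hardens in two steps: argmax (ties to the smallest
index), then a discrete alternating minimization of the same weighted
residue — every gene is batch-reassigned to the row cluster minimizing its
weighted residual given the sample partition, then every sample
symmetrically, until no label moves. Each pass cannot increase the hard
objective; a pass that would empty a cluster is skipped, so the requested
k and d are kept (as is any cluster revived by the empty-cluster repair in
the argmax step). On additive 3 x 2 checkerboards at noise 0.05 this
refinement takes randomly initialized fits from Rand indices of roughly
0.5-0.8 to exact recovery; it can be disabled with `refine = FALSE`.

Initialization is uniform random (rows normalized to sum 1) or k-means on
rows and columns with the one-hot labels softened by a 0.01 jitter —
multiplicative updates cannot move entries off exact zeros.

## Model selection

`select_k_d()` scores every (k, d) on a grid by consensus stability:
`n_runs` randomly initialized fits, gene and sample co-assignment matrices
averaged into consensus matrices, and each consensus summarized by the
cophenetic correlation coefficient of average-linkage clustering on
`1 - M` (average linkage is the convention of the NMF consensus
methodology this follows). The combination with the largest mean of the
gene and sample coefficients wins; ties go to the smaller k, then d.

Two caveats are documented deliberately. First, k = 1 makes the gene
consensus all-ones and the coefficient degenerate (returned as 1 with a
warning), so grids should start at 2. Second, on cleanly separable data
*under*-clustering is itself highly stable — every run merges the same two
closest clusters — so the maximum-coefficient rule can prefer a smaller k
than the generating one. This is a known behaviour of consensus stability
selection, and the reason practitioners often look for the largest k
before the coefficient drops rather than the global maximum. The test
suite records this limitation honestly: on 3 x 2 additive checkerboards
the generating pair is selected in a minority of repetitions, with the
(2, 2) cell scoring a deterministic 1.0.

## Synthetic benchmarks

`sim_implanted()` reproduces the classical implanted-bi-cluster protocol:
an N(0, 1) background, three non-overlapping 15 x 8 blocks (defaults;
placements are random disjoint index sets) rewritten by one of five
archetypes — constant (one entry copied across the block), row-constant
(a base column copied), column-constant (a base row copied), additive
(base row plus per-row N(0, 2^2) shifts) and multiplicative (base row
times per-row uniform [0.5, 2] factors with random sign) — plus N(0,
sigma^2) noise, sigma conventionally 0.05 to 0.25. The shift and scale
distributions are package choices (the protocol leaves them open), sized
to keep implants on the background's scale while distinguishable.

`sim_checkerboard()` tiles the whole matrix with patterned blocks instead
of leaving a majority background; this is the reference condition under
which the truth partition is provably the objective's nullspace (types
i-iv, sigma = 0). The distinction matters: with a large unstructured
background, re-fitting noise buys the objective more than respecting
small implants costs it, so *no* optimizer of this objective will score
well against sparse implants — the package's tests measure both regimes
and the implant-benchmark scores are reported as-is. Two observed
identifiability limits of the archetypes themselves: in a row-constant
checkerboard any row partition has zero residue (the row labels are
unidentifiable in principle), and symmetrically for column-constant.

`inject_noisy_genes()` and `perturb_network()` implement the stress
protocols: replacing the lowest-weight genes by uniform draws spanning the
matrix range, and adding/deleting/rewiring network edges while preserving
simplicity and symmetry. `sim_structured_network()` builds the matched
condition in which informative genes are hubs, so that network-blended
weights (theta = 0.85) can down-weight noise genes that expression
variability alone would up-weight — uniform noise over the matrix range
has a *larger* mean absolute deviation than real signal, which is exactly
why theta = 0 degrades there.

## Evaluation

Partition agreement uses pair counting: np1 (together/together), np2
(together/split), np3 (split/together), np4 (split/split); the Rand index
is `(np1+np4)/(np1+np2+np3+np4)`, precision `np1/(np1+np3)`, recall
`np1/(np1+np2)`, F1 their harmonic mean, all zero-denominator cases
defined as 0. Bi-cluster agreement uses the best-match mean Jaccard over
*gene sets only* (relevance: discovered against implanted; recovery: the
transpose) — the gene-sided score is implemented literally as the
benchmark formula states it; sample sets ride along in the objects but do
not enter.

When a benchmark prescribes how many bi-clusters a method reports,
`top_biclusters()` ranks the k x d blocks by per-cell sum-squared residue
and keeps the q most coherent; `extract_biclusters()` always returns the
full tiling.

## Problem sizes and determinism

All package tests and the acceptance script run at desk scale — matrices
up to 100 x 50, networks up to 200 genes, 10-seed repetitions —
which completes in a few minutes while still exercising every code path
at the conditions stated above. Every stochastic step (generators,
initializations, consensus runs) takes an explicit integer seed and is
bitwise reproducible under it; seeded calls restore the caller's RNG
state.

## Known limitations

* Checkerboard structure only: no overlapping or partial bi-clusters.
* Missing values are rejected at load time, not imputed.
* Multiplicative blocks are outside the residue nullspace and recovered
  only approximately.
* The continuous relaxation is not a clustering method by itself; the
  discrete refinement at hardening is what makes random initialization
  reliable.
* Consensus model selection over-favours stable under-clustering on very
  clean data (see above).
* theta is exposed, not selected: there is no principled rule to choose
  it, and the package does not pretend to supply one.
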