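# netbc

Network-aided bi-clustering of gene expression data.

`netbc` simultaneously partitions the genes and the samples of an
expression matrix into a checkerboard of non-overlapping bi-clusters, for
studies where every sample must receive a subtype and every gene a module
— cancer subtype discovery being the motivating case. Two ideas drive it:

1. **A sum-squared-residue objective.** With row indicators `R` (genes ×
   k), column indicators `C` (samples × d) and per-gene weights
   `W = diag(w)`, the method minimizes

   ```
   Φ(R, C) = ‖ (I − R(RᵀR)⁻¹Rᵀ) G (I − C(CᵀC)⁻¹Cᵀ) ‖²_W
   ```

   the weighted squared norm of the doubly centred residual. For hard
   indicators each entry is compared against its block's row mean, column
   mean and block mean, so blocks that are constant, row-constant,
   column-constant or additively coherent fit perfectly — the objective
   targets *coherent trends*, not just flat blocks. Minimization
   alternates KKT-derived multiplicative updates of `R` and `C`, then
   hardens to labels by argmax plus a discrete reassignment pass.

2. **Network-blended gene weights.** Each gene's weight solves the damped
   recursion `w = (1−θ)e + θ P D⁻¹ w`, where `e` is the gene's mean
   absolute expression deviation across samples, `P` the binary
   interaction network and `D` its degree matrix. `θ = 0` trusts
   expression variability alone, `θ = 0.85` (the conventional value)
   lets well-connected genes pull weight towards themselves, which
   protects the fit against high-variance junk genes.

The package also provides consensus-based selection of (k, d) scored by
the cophenetic correlation coefficient, generators for the classical
implanted-bi-cluster benchmarks (five block archetypes, graded Gaussian
noise, noisy-gene and network-perturbation stress protocols), and
clustering metrics (Rand index, pairwise precision/recall/F1, bi-cluster
relevance and recovery).

## Worked example

Simulate a 100 × 40 additive checkerboard with 3 gene and 3 sample
clusters, make the informative genes hubs of a synthetic network, corrupt
the 30 least-informative genes with uniform noise, and fit with
network-blended weights:

```r
library(netbc)

sim <- sim_checkerboard(m = 100, n = 40, k = 3, d = 3, type = "additive",
                        sigma = 0.1, seed = 42)
net <- sim_structured_network(100, informative = 1:70, p_hub = 0.2,
                              p_background = 0.01, seed = 42)
w <- gene_weights(sim$expr, net, theta = 0.85)
w
#> gene_weights: 100 genes, theta = 0.85, method = direct
#>   weight range: [0.5581, 1.541], mean 1

noisy <- inject_noisy_genes(sim$expr, w, n_noisy = 30, seed = 42)
fit <- netbc(noisy$expr, k = 3, d = 3,
             weights = gene_weights(noisy$expr, net, theta = 0.85),
             init = "kmeans", seed = 1)
fit
#> netbc fit: 100 genes x 40 samples into 3 x 3 checkerboard blocks
#>   objective 17112.1 after 300 iterations

evaluate_partition(sim$col_labels, fit$col_labels)
#> # A tibble: 1 × 4
#>      ri precision recall    f1
#>   <dbl>     <dbl>  <dbl> <dbl>
#> 1     1         1      1     1

extract_biclusters(fit)
#> bicluster_set with 9 bi-cluster(s)
#>   [1] 37 genes x 14 samples
#>   [2] 37 genes x 13 samples
#>   ...
```

Despite 30% of genes being pure noise, the network-weighted fit recovers
the sample subtypes exactly (Rand index 1). The same run with `theta = 0`
scores visibly worse, because uniform noise spanning the matrix range has
a *larger* expression deviation than real signal and gets up-weighted.

`autoplot(fit)` draws the objective trace; `autoplot(fit, expr, type =
"heatmap")` shows the reordered matrix; `tidy(fit)` and `glance(fit)`
return assignments and a one-row summary as tibbles.

A command-line front end with `run`, `weights`, `select`, `simulate` and
`evaluate` subcommands is installed at `inst/scripts/netbc.R` and works on
plain TSV/JSON files.

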