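# iterimpute

Self-consistent imputation of dropout events in single-cell RNA-seq count
matrices.

scRNA-seq protocols capture only a fraction of each cell's transcripts, so
truly expressed genes are often recorded as zeros ("dropout events") and
the count matrix is heavily zero-inflated. `iterimpute` identifies likely
dropouts and re-estimates them, organized around a *self-consistency*
criterion rather than label-based tuning: an imputation mapping *f* should
reproduce its own output. With X_out = f(X), the method requires

    selfconsistency(f; X) = ||X_out − f(X_out)||²_F / (M·N) < θ,

reported as its square root (an RMSE on log-scale expression, θ = 0.1 by
default), and iterates a single-pass core until the criterion holds.

The single pass works on the normalized log matrix X (median-library
scaling, log10(x + 1.01)):

1. **Dropout model** — per gene, a Gamma–Normal mixture
   π·Gamma(x; α, β) + (1−π)·Normal(x; μ, σ) fitted by EM; the posterior
   weight of the Gamma component at each entry is its dropout probability
   D_ij.
2. **Cell affinity** — an adaptive truncated Gaussian kernel on the
   principal-component coordinates of the cells:
   A_ij = exp(−Dist(i,j)/(2σ_i²)) for Dist(i,j) ≤ σ_i (else 0), with σ_i
   the distance to cell i's n-th nearest neighbour (n = 40).
3. **Weighted non-negative lasso** — entries with D_ij ≥ t (t = 0.5) are
   re-estimated per cell j by
   min_{B ≥ 0} ||(1−D_j)∘X_j − [(1−D_j̄)∘(A_jj̄ ⊙ X_j̄)]B||² + λ||B||₁,
   solved by compiled coordinate descent; trusted entries are returned
   bit-identical.

A Splat-style group-structured simulator with logistic mean-dependent
dropout (`simulate_counts()`) and an evaluation suite (RMSE, Pearson, ARI,
NMI, silhouette width, Ward hierarchical clustering) reproduce the
benchmark this method is usually assessed on.

## Worked example

```r
library(iterimpute)

sim <- simulate_counts(sim_params(n_genes = 300, n_cells = 60,
                                  dropout_mid = 2, seed = 7))
sim
#> sim_dataset: 300 genes x 60 cells, 3 groups
#>   realized dropout rate: 21.30% | zero rate: 24.64%

res <- iterimpute(sim$observed_counts,
                  config = impute_config(n_neighbor = 15), verbose = TRUE)
#> iteration 1: self-consistency RMSE 0.4314 (4316 entries imputed)
#> iteration 2: self-consistency RMSE 0.0427 (1909 entries imputed)

truth <- normalize_counts(sim$true_counts[rownames(res$imputed), ])
evaluate_imputation(res$imputed, truth, sim$labels)
#> evaluation_report: RMSE 0.2340 | Pearson 0.9557 | ARI 0.9496 | NMI 0.9394 | SW 0.1343
```

The trace shows the mapping approaching its fixed point: the first pass
changes the matrix substantially (RMSE 0.43 between input and output), the
second barely (0.04 < θ), so the result is declared self-consistent. The
evaluation compares against the pre-dropout ground truth on the same log
scale: Pearson 0.96 means the re-estimated entries track the true
expression closely, and ARI/NMI near 0.95 mean Ward clustering of the
imputed matrix essentially recovers the three simulated groups.

Command-line wrappers live in `exec/`: `iterimpute` (impute a CSV/TSV/MTX
matrix), `iterimpute-sim` (simulate), `iterimpute-eval` (evaluate against
ground truth).

## Acceptance script

`scripts/acceptance.R` re-runs the benchmark from scratch against the
installed package: it simulates the 3-group, 2000-gene, 150-cell world at
the three dropout severities (logistic shape −1, midpoints 5/3/2), runs the
full imputation loop (t = 0.5, n = 40, θ = 0.1, ≤ 10 iterations), and
measures the final self-consistency RMSE at the hardest setting, the median
Pearson correlation against ground truth over five seeds at the two easier
settings, and the best adjusted Rand index of Ward clustering (k = 3) at
the intermediate setting:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The vignette (`vignettes/self-consistent-imputation.Rmd`) documents the
model, the numerical choices, the simulator's assumptions, and the known
limitations — including what the default pipeline does and does not recover
at high dropout rates, and the role of the optional pre-smoothing hook.
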