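# markeropt

Marker gene set optimization for cell type annotation in single-cell and
single-nucleus RNA-seq.

Marker-based annotation scores every cell against curated per-type
marker gene lists and assigns the best-scoring type. The lists are the
model: a bad list mislabels cells no matter how good the data. This
package treats the marker set as a parameter to be *fitted*. It
provides:

- a vectorized enrichment scorer: per-gene z-scores across all cells,
  weighted by a specificity score
  θᵢ = (1/nᵢ − minⱼ 1/nⱼ) / (maxⱼ 1/nⱼ − minⱼ 1/nⱼ)
  (nᵢ = number of cell types using gene i), summed per type as
  E₍c,j₎ = |S_c|^(−1/2) Σ_{i∈S_c} θᵢ z᷉ᵢⱼ, with argmax assignment and an
  "unknown" rule for cells whose best score is not positive;
- a leave-one-cell-type-out (LOCTO) × K-fold cross-validated objective
  f(S) = (1/CK) Σ_c Σ_k f₍c,k₎(S), where each type's markers are masked
  in turn and its cells are expected to come back "unknown";
- Bayesian optimization of the marker set: a Gaussian-process surrogate
  over a mean-Jaccard set kernel k(S,S′) = exp(−γ(1−J̄)), Expected
  Improvement acquisition in closed form, and an EM proposal step that
  re-ranks genes by a specificity statistic on the induced assignment;
- a negative-binomial single-cell simulator with planted marker
  structure, so everything above is testable without downloads;
- IO for Matrix Market + sidecar and dense delimited expression
  matrices, JSON/CSV marker sets, and a permutation test for shifts in
  cell type composition between conditions (one-sided, cell- or
  sample-level, exact when enumerable).

## Worked example

```r
library(markeropt)

sim <- simulate_dataset(seed = 1)      # 5 types, 300 cells/type, 2000 genes,
                                       # 8 planted markers/type at log2FC 2
fit <- optimize_markers(sim$X, sim$labels, budget = 300, seed = 1)
fit
#> Marker-set optimization fit
#>   method: bo, budget: 300 evaluations, seed: 1
#>   best LOCTO x 5-fold objective f(S*) = 0.8473
#>   5 cell types, 40 genes in optimized universe

planted_recovery(fit$best_set, sim$markers)$recall
#> [1] 1

ann <- predict(fit, sim$X)
mean(ann$labels == sim$labels[names(ann$labels)])
#> [1] 0.9773333
```

The fit starts from 15 data-driven genes per type, prunes each list to
exactly the 8 planted markers (recall 1.0), and the optimized set
annotates 97.7% of cells correctly. `f(S*) = 0.847` is the LOCTO
cross-validated objective: it is deliberately below the plain accuracy
because for each masked type the objective asks that type's cells to be
labelled "unknown", a stricter demand than classifying them. Random
search at the same budget reaches only f ≈ 0.24.

Other entry points: `annotate()` (score any matrix with any marker
set), `cv_objective()` (score a fixed set), `composition_test()`
(proportion shifts between conditions), `count_configurations()` (exact
log10 size of the search space — about 2590.8 for a 5,000-gene pool,
1–30 markers per type, 33 types).

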