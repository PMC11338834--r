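# scdemon — single-cell decorrelated module networks

`scdemon` discovers gene co-expression modules in single-cell (and bulk)
expression matrices. It is aimed at analysts working with atlas-scale
snRNA-seq/scRNA-seq data who want gene programs — cell-type identity
modules, metabolic programs, stress responses — called directly from
gene–gene structure, without being dominated by the most abundant cell type
and without the spurious edges that sparse genes generate under a plain
correlation cutoff.

## The method

Given a cells × genes matrix *X* (*n* × *g*, non-centred) with thin SVD
*X = USVᵀ*, the ZCA-whitened (sample-decorrelated) gene–gene covariance
reduces analytically to

```
C = (g / n) · V Sᵖ Vᵀ
```

where the eigenvalue power *p* interpolates between full decorrelation
(*p* = 0) and the raw non-centred covariance (*p* = 2). After rescaling to a
correlation, every gene pair is z-scored against smoothed mean/s.d. surfaces
estimated in 2D bins of the two genes' log₁₀ expressed fractions — removing
the sparsity-driven inflation of correlation estimates. Z-scores are
averaged over bootstraps of experimental batches, thresholded (*z* > 4.5)
into graphs at *p* ∈ {0, 0.25, 0.5, 0.75, 1}, and the graphs are clustered
jointly as a multiplex (RBConfiguration quality, equal layer weights,
seeded Leiden/Louvain-style local moving) into one gene partition.
Components under 4 genes are pruned; modules under 10 genes are flagged,
not reported.

Downstream statistics: per-cell module scores, hypergeometric covariate
enrichment of module-high cells, module–module correlation networks on
aggregated scores (one-sided, BH-adjusted), DEG-to-module enrichment, and
Gaussian-smoothed contour surfaces for 2D embeddings.

A negative-binomial simulator with planted modules, imbalanced cell types,
batch effects and a sparsity gradient (`generate_synthetic()`) makes the
whole pipeline testable without any external data.

## Worked example

```r
library(scdemon)

sim <- generate_synthetic(synthetic_config(
  n_cells = 2500, n_genes = 400, module_sizes = rep(30L, 4L),
  n_batches = 3L, seed = 81))
cfg <- run_config(out_dir = "demo_out", k = 50L, n_boot = 3L,
                  resolution = 1.5, seed = 4L)
res <- run_pipeline(cfg, x = sim$x)
#> [io] normalizing to CP10K + log1p
#> [io] 349 genes pass the 5% sparsity filter
#> [zscore] 3 bootstraps x 5 powers, k = 50
#> [graph] edges per power: 50, 66, 93, 121, 142
#> [modules] 4 reported modules
#> [done] 7.0 s -> demo_out

evaluate_recovery(res$modules, sim$truth, res$graphs)
#> <scd_recovery> mean Jaccard = 0.675, ARI = 1.000, edge precision = 1.000, recall = 0.083
```

The four reported modules correspond to the four planted gene programs:
mean best-match Jaccard 0.68 means roughly two-thirds of each planted
module's genes are recovered in its matching called module (at this small
problem size; larger matrices recover more), edge precision 1.0 means no
thresholded edge joins genes from different planted programs (recall is low
here because only the strongest pairs clear z = 4.5 at 2,500 cells), and
ARI 1.0 says the two partitions agree perfectly on the genes both assign.
`demo_out/` then contains `modules.tsv` / `modules.gmt` (memberships, core
genes), per-power edge lists and Fruchterman–Reingold layouts, per-cell
`scores.tsv`, and a `manifest.json` from which the run can be reproduced
byte-for-byte.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/scdemon.R simulate --config scenario.yaml --out sim/
Rscript inst/cli/scdemon.R modules --matrix sim/matrix.mtx --meta sim/meta.tsv \
    --k 50 --boots 3 --resolution 1.5 --seed 4 --out run/
Rscript inst/cli/scdemon.R evaluate --found run/modules.tsv \
    --truth sim/truth_modules.tsv --out recovery.tsv
```

See `vignettes/module-discovery.Rmd` for the model, parameter guidance and
the generator's scope.

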