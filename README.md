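# fpcc — F-point transforms, PCCF similarity and PCA-F projections

`fpcc` is an R toolkit for clustering and visualizing gene expression
profiles measured over ordered time points (microarray, RNA-seq or SAGE
series; bulk or single-cell pseudotime courses). It is aimed at analysts
who need a similarity measure that captures expression *behavior* rather
than level, and a 2D map on which the resulting clusters remain
interpretable.

## The method

Each profile `X_i = (x_i1, …, x_in)` is row-normalized to a probability
vector `W_i` (after shifting any negative values to zero), and mapped to
its **F-point**: the modified cumulative probability of `W_i` — where the
current element gets half weight, `w'_t = w_1 + … + w_(t-1) + w_t/2` —
concatenated with the modified cumulative probability of the reversed
profile:

    F_i = (w'_1, …, w'_n, 1 − w'_n, …, 1 − w'_1)

Every F-point sums to `n`, has mean exactly 1/2, and is
complement-symmetric, giving all genes a common N-shaped geometry. On
F-points the package defines:

* **PCCF** — Pearson correlation of F-points, computed by its fixed-mean
  closed form `Σ(w'_is − ½)(w'_js − ½) / √(Σ(w'_is − ½)² Σ(w'_js − ½)²)`,
  identical to the full-vector correlation; with **PCCP**, **EuP**,
  **EuF** (and plain PCC / Euclidean) as comparison measures, each bound
  to its representation. `EuF = √2·EuP` holds identically.
* **K-means with measure plug-ins** (`km_fit`) — multi-restart Lloyd
  clustering under any of the six measures.
* **PCA-F / PCA-P / PCA-N** (`pca2`, `project_expression`) — centered
  covariance PCA of the F-points, P-points or normalized profiles, and
  **PCA-FO** (`pca_fo`), the rank-blend transform
  `score/max + rank/m` that spreads crowded PCA maps while preserving
  per-component order.
* **S1 / S2 silhouettes, D-plots, neighbor maps** (`silhouette_s1`,
  `silhouette_s2`, `d_plots`, `neighbor_map`) — cluster-quality and
  embedding-validity diagnostics.
* **Benchmark simulator** (`simulate_dataset1`, `simulate_blobs`) — the
  1500-point, 14-population Gaussian design used throughout the tests.

See the methods vignette (`vignettes/fpoint-clustering.Rmd`) for the
model, its assumptions, and the design decisions.

## Worked example

```r
library(fpcc)

d   <- simulate_dataset1(seed = 1)          # 1500 genes x 4 time points
mod <- dissimilarity_model("pccf")
fp  <- model_representation(mod, d$x)       # F-points (1500 x 8)

fit <- relabel_by_size(km_fit(fp, mod, k = 7, restarts = 50, seed = 1))
fit
#> <fpcc_kmeans> k = 7 measure = pccf restarts = 50
#>   objective: 2.373303
#>   sizes: 262 259 242 208 190 183 156

pr <- project_expression(d$x, "pca-f")
pr
#> <fpcc_projection> PCA-F on 1500 genes
#>   variance: 83.211% + 14.397% = 97.608%

silhouette_s1(fp, fit, mod)$s_value                            # 0.52663
silhouette_s2(fp, pr, mod, k = 7, restarts = 50, seed = 1)$s_value  # 0.45054

head(d_plots(fp, pr, k = 10), 2)
#>   b        d1       d2
#> 1 2 0.9995438 1.003534
#> 2 3 0.9995443 1.003105
```

The clustering objective is the total within-cluster dissimilarity
(`1 − PCCF` here) of the best restart. The projection line says the
first two principal components of the F-points carry 97.6% of their
variance, so the 2D map is a near-lossless summary. S1 scores the
7-cluster PCCF partition in its own geometry; S2 scores how well the
2D map's Euclidean clusters match the high-dimensional PCCF structure.
D-plot values near 1 mean the map preserves both local (d1) and global
(d2) neighbor structure.

A command-line interface wrapping the same functions is installed at
`inst/cli/fpcc` (subcommands `simulate`, `transform`, `cluster`,
`project`, `evaluate`, `run`), e.g.

```sh
Rscript inst/cli/fpcc cluster --measure pccf --k 8 --restarts 1000 \
        --seed 1 in.tsv out_labels.tsv
```

Input files are delimited text, genes in rows, gene id in the first
column, a header row of time-point labels.

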