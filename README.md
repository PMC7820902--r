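# minnetrank

Network propagation with minimum-strategy multi-omics integration for
cancer driver gene prioritization.

## The problem

Distinguishing the few **driver genes** that causally contribute to a
tumor from the large background of **passenger genes** is hard from any
single data type: mutation calls are sparse and noisy per patient, and
differential expression is dominated by downstream effects. `minnetrank`
combines both signals on a directed gene-interaction network, per
patient, and only promotes genes that are "double high" — close to that
patient's mutations *and* close to that patient's expression changes.
It is aimed at computational cancer-genomics analysts who have a somatic
mutation table (MAF), tumor/normal expression matrices, and an
interaction network, and want a cohort-level ranked driver-gene list
plus downstream benchmarking and survival stratification.

## The method

1. **Diffusion.** With adjacency `a_ij = 1` for an edge `j → i`, the
   normalized adjacency is

       A_norm[i, j] = (a_ij + a_ji) / (deg_out_j + deg_in_j)

   which mixes incoming and outgoing connectivity and is column
   stochastic. A random walk with restart probability `β` (default
   0.48) has the closed-form influence matrix

       D = β [I − (1 − β) A_norm]⁻¹

   computed once per network.

2. **Per-sample scores.** The mutation matrix `S^M` holds per-sample
   variant weights (0/1 under the uniform scheme; SIFT / PrDSM /
   PredCID deleteriousness scores under the weighted schemes). The
   expression matrix `S^E` holds the absolute log2 fold-change
   (ALFC) of each tumor sample against its paired normal, or against
   the mean of all normals when unpaired. Both are column-normalized,
   then diffused: `W^M = D S^M`, `W^E = D S^E`.

3. **Minimum integration and rank aggregation.**
   `W = pmin(W^M, W^E)` suppresses single-omics outliers; within each
   sample, genes are ranked by descending `W` (average ranks for ties),
   and the cohort-level ranking orders genes by their rank sum across
   samples.

Companion modules evaluate a ranking against a gold-standard gene list
(precision / recall / F1 curves and a partial AUC counting positives
above each of the top-n negatives), assess robustness by rerunning the
pipeline on random sample subsets, stratify patients into two survival
risk groups by k-means on the top-7 high-variance biomarker genes with
a log-rank test, and simulate cohorts with planted drivers.

## Worked example

A synthetic 200-gene network whose 5 hub genes are planted drivers,
with a 100-sample cohort:

```r
library(minnetrank)
fx  <- default_fixture(seed = 7)
D   <- compute_diffusion(normalize_adjacency(fx$network), beta = 0.48)
w   <- assign_variant_weights(fx$variants, weight_scheme("uniform"))
SM  <- build_mutation_scores(w, fx$network, sort(unique(fx$pairing$tumor)))
SE  <- compute_alfc(fx$tumor_expr, fx$normal_expr, fx$pairing, fx$network)
fit <- rank_genes(D, SM, SE, strategy = "min")
head(fit$ranking, 8)
#>   rank  gene  score
#> 1    1 g0194  327.5
#> 2    2 g0015  380.5
#> 3    3 g0042  392.5
#> 4    4 g0103  445.5
#> 5    5 g0159  455.5
#> 6    6 g0020 3267.5
#> 7    7 g0025 3316.5
#> 8    8 g0123 3470.5
fx$planted_drivers
#> [1] "g0015" "g0042" "g0103" "g0159" "g0194"
```

All five planted drivers occupy the top five positions (the `score`
column is the rank sum over the 100 samples — lower is better; note the
gap to rank 6). Evaluating against the planted drivers:

```r
precision_recall_f1(fit$ranking, fx$planted_drivers, n = 20)[c(5, 10, 20), ]
#>    top precision recall    f1
#> 5    5      1.00      1 1.000
#> 10  10      0.50      1 0.667
#> 20  20      0.25      1 0.400
partial_auc(fit$ranking, fx$planted_drivers, n = 20)
#> [1] 1
```

Precision at 5 is 1 (all top-5 genes are drivers) and the partial AUC
is 1 (every driver ranks above the 20 highest-ranked non-drivers).
Stratifying patients on the top-7 high-variance biomarkers:

```r
stratify_patients(fit$ranking, fx$tumor_expr, fx$survival, seed = 7)
#> Two-group survival stratification
#>   biomarkers: g0194, g0015, g0042, g0103, g0020, g0025, g0123
#>   group sizes: high_risk=88, low_risk=12
#>   log-rank chisq = 10.46, p = 0.00122
```

The two k-means groups separate significantly in survival (log-rank
p ≈ 0.001). An end-to-end run over files is available via
`run_pipeline(minnetrank_config(...))` or the thin CLI wrapper in
`inst/cli/minnetrank.R`.

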