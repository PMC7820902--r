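---
title: "Methods: network propagation with minimum-strategy integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation with minimum-strategy integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minnetrank)
```

## The model

`minnetrank` ranks candidate cancer driver genes by combining three
ideas: signal from a patient's somatic mutations and from their
differential expression should *reinforce* each other; a gene's
relevance should account for its *network neighborhood*, not just its
own measurements; and a cohort ranking should be an aggregate of
*per-patient* rankings rather than a fit to pooled data.

### Diffusion

Given a directed interaction network on $n$ genes with adjacency
$a_{ij} = 1$ when an edge $j \to i$ exists, we form the normalized
adjacency

$$A^{norm}_{ij} = \frac{a_{ij} + a_{ji}}{\deg^{out}_j + \deg^{in}_j},$$

which treats a gene's incoming and outgoing interactions
symmetrically while normalizing by its total connectivity. Every
column belonging to a gene with at least one edge sums to 1, so
$A^{norm}$ is column stochastic; isolated genes (possible only when a
network is constructed programmatically, since an edge-list loader
never produces them) get zero columns and can never receive score from
others. The influence matrix of a random walk with restart probability
$\beta$ is the closed form

$$D = \beta\,[I - (1-\beta)A^{norm}]^{-1},$$

equal to the Neumann series $\beta \sum_{k\ge0} (1-\beta)^k
(A^{norm})^k$: entry $(i,j)$ accumulates all walks from $j$ to $i$,
discounted by length. Column stochasticity of $A^{norm}$ implies
$\mathbf{1}^\top D = \mathbf{1}^\top$, so diffusion conserves each
sample's unit mass — a property the tests assert end to end.

### Per-sample scores

The mutation layer $S^M$ assigns each (gene, sample) cell the summed
weight of that sample's variants in that gene. Under the `uniform`
scheme the sum is clipped at 1, which reproduces the plain binary
mutated-or-not status; the weighted schemes substitute external
per-variant deleteriousness scores (SIFT for missense, PrDSM for
synonymous, PredCID for frameshift variants). The expression layer
$S^E$ is the absolute log2 fold-change of each tumor sample against
its paired normal, or against the mean of all normals when no pair
exists. Both layers are column-normalized to unit mass per sample.

### Integration and aggregation

After diffusion ($W^M = D S^M$, $W^E = D S^E$) the integrated score is
the elementwise minimum $W = \min(W^M, W^E)$. The minimum implements a
"double high" requirement: a high integrated score needs high diffused
relevance in *both* layers, which suppresses two characteristic
artifacts — genes whose only support is an isolated mutation in a
sparsely connected network region, and genes that are strongly
differentially expressed without any mutational support nearby.
Within each sample, genes are ranked by descending $W$ (ties receive
average ranks, keeping every column's rank sum at $n(n+1)/2$), and the
cohort ranking orders genes by ascending rank sum, ties broken
lexicographically.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.48 | restart probability; 1 = no diffusion, small values spread signal widely. The default balances local retention against network-scale diffusion; it is a property of the network, not of the omics data. |
| `pseudocount` | 0.5 | additive constant in the ALFC ratio; bounds the score for zero-expression genes while preserving monotonicity. On abundance-scale expression values (FPKM-like), 0.5 is below the noise floor. |
| `weight_scheme` | `uniform` | per-variant weighting; see `?weight_scheme`. |
| `prdsm_threshold` | 0.308 | deleteriousness cutoff for synonymous variants under the filtered scheme (strict `>`). |
| `top_n` | 50 | evaluation cutoff for precision/F1/partial AUC. |
| `top_k`, `sd_threshold` | 7, 5 | stratification: number of biomarkers and the minimum expression SD, on the expression matrix's own scale. |
| `repeats` | 10 | robustness subsets per size; sizes default to the 10, 25, 50, 100, … grid. |

## Design choices where the design was open

* **Both layers are column-normalized.** The elementwise minimum is
  only meaningful when the two layers live on a common scale; a
  normalized mutation layer against an unnormalized ALFC layer would
  let one layer dominate every cell by magnitude alone.
* **SIFT scores are used as supplied** (`sift_transform =
  "as_stated"`), although SIFT is conventionally *low* for deleterious
  variants. A `one_minus` option is provided for users who want
  deleteriousness-increasing weights; the default preserves the
  established behavior of this weighting scheme family.
* **Multiple variants per gene per sample sum their weights** (clipped
  at 1 under `uniform`): a heavier deleterious burden should inject
  more signal, while the clip keeps the unweighted path exactly
  binary.
* **Mixed cohorts use the sample intersection.** Mutation and
  expression cohorts often differ; the integrated analysis runs on
  samples with both data types, while single-layer analyses use their
  full cohort.
* **`mean_of_both` centrality** min-max rescales degree and
  betweenness to $[0,1]$ before averaging, because the two metrics
  have incomparable scales; betweenness is computed on the directed
  graph with unit weights.
* **Partial AUC universe.** The gold-set size $T$ counts gold genes
  restricted to the ranking's gene universe (configurable): genes that
  cannot appear in the ranking should not deflate the score. Positives
  and negatives are ordered strictly by rank position.
* **Min-source proportions are cell-weighted** (fraction of (gene,
  sample) cells, not a per-gene average), with exact ties counted
  toward both layers — the two proportions may exceed 1 jointly.
* **Stratification** z-scores each biomarker before k-means (genes
  passing an SD filter would otherwise dominate by scale), uses 25
  restarts under a fixed seed, and labels the *high-risk* group by
  survival (smaller Kaplan–Meier restricted mean up to the last time
  observed in both groups, ties toward more events) — never by cluster
  index.
* **`beta = 0` is rejected**: the resolvent can be singular for a
  column-stochastic matrix, and the full-diffusion limit has no
  operational use here.

## Numerical choices

The diffusion matrix is computed by a dense direct solve, adequate up
to networks of roughly 10–15k genes; an iterative fixed-point solver
(`method = "iterative"`, tolerance `1e-9`) is available for larger
networks and agrees with the direct solve to `1e-6` on test graphs.
The matrix can be cached on disk keyed by a content hash of the
network and `beta`. All gene orders are lexicographic and all
tie-breaks deterministic, so identical inputs yield byte-identical
output files. Robustness child seeds are a fixed arithmetic function
of (master seed, subset size, repeat index), so extending the size
grid never changes earlier draws.

## What the synthetic cohorts emulate — and what they do not

`simulate_network()` grows a directed preferential-attachment graph
with a designated hub set of elevated in- and out-degree, mirroring
the high connectivity of known cancer genes in curated networks.
`simulate_cohort()` plants drivers that mutate recurrently
(default probability 0.4 per sample against a 0.01 background), shifts
the expression of the drivers' *first neighbors* by ±2 on the log2
scale over a log-normal baseline with 0.5 SD noise, and draws
exponential survival with a three-fold hazard for patients carrying
two or more mutated drivers (20% uniform censoring). The
one-hop-only expression effect is deliberate: recovering the driver
itself from neighborhood signal is exactly what diffusion must do, so
the generator does not encode the method's answer. The default
fixture (200 genes, 5 hub drivers, 100 paired samples) was calibrated
once and frozen; under it the pipeline recovers all five drivers
within the top 20 across master seeds.

The simulator does **not** reproduce mutational signatures, copy
number or methylation events, expression covariance between genes,
batch effects, or the incompleteness of real interaction networks.
Passing tests on these fixtures therefore demonstrate the
correctness of the algorithmic chain and its statistical behavior
under the assumed generative structure — not clinical performance on
real cohorts.

## Problem sizes used by the test suite

The suite exercises exact oracles on graphs of up to 20 nodes
(truncated Neumann series), 200 random rankings of length ≤ 50 for the
partial-AUC enumeration, 100 log-rank simulations at 100 patients per
arm, and ten independent 200-gene / 100-sample end-to-end fixture
runs — sizes chosen so the whole suite runs in well under a minute
while every assertion remains sharp.

## Known limitations

* Genes absent from the interaction network can never be ranked; the
  loader reports how many variants or expressed genes were dropped.
* The ALFC definition needs at least one normal sample; cohorts
  without normals are rejected rather than silently scored.
* The `sd_threshold = 5` biomarker filter is scale-dependent; on
  log-scale expression matrices it must be lowered accordingly.
* Rank-sum aggregation weights every sample equally; heavily mutated
  samples are not down-weighted beyond their per-sample normalization.
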