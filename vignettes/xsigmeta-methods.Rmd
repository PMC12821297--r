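---
title: "Methods: cross-study meta-analysis of DE signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study meta-analysis of DE signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A single exposure study yields one differential-expression (DE) signature:
per-gene log2 fold changes with p-values and BH FDRs. When dozens of such
studies exist for the same compound — across species, tissues, platforms and
designs — the interesting questions are cross-study: which datasets agree
with each other, which genes respond consistently, which pathways, disease
associations and network regulators recur. `xsigmeta` implements that
meta-analysis layer. It deliberately starts *after* per-dataset DE fitting
(limma/DESeq2 and their upstream read processing are out of scope) and works
entirely from summary tables.

# The pipeline, stage by stage

## Rank normalization to [-1, 1]

RNA-seq and microarray fold changes are not on a common scale, so each
dataset is reduced to within-sign ranks. Positive log2FCs are ranked
ascending and mapped to `rank / n_pos` (the strongest upregulation gets 1);
negative log2FCs get `-rank / n_neg` with rank 1 the negative closest to
zero, so the strongest downregulation gets −1; exact zeros map to 0. Ties
share mean ranks. Two consequences matter downstream: the transform depends
only on ranks (any strictly monotone, sign-preserving distortion of fold
changes is invisible), and signs are preserved exactly.

Two conventions here were genuinely open and are fixed as follows:

* **Scaling `rank/n`** rather than `(rank-1)/(n-1)` or `rank/(n+1)`, so the
  endpoints are exactly ±1 for the extreme genes and 0 is reserved for
  "no change".
* **Ties by mean rank**, the usual rank-statistic convention.

## Matrix assembly, presence filtering, imputation

`build_matrix()` stacks the normalized vectors over the union gene axis.
With heterogeneous platforms a gene may be absent from many datasets, so a
presence filter (default: observed in ≥ 70% of datasets) runs first, then
the `top_k = 2500` most variable genes are retained. Variance is computed on
the *normalized* values: variability is only meaningful after the
cross-platform standardization that makes columns comparable. In
single-chemical mode (`presence_threshold = NULL`) the presence filter is
skipped and only the variable-gene filter applies.

Missing cells are imputed before correlation work. The package offers a
per-gene **median** imputer (default in the pipeline) and a **kNN** imputer
(weighted mean over the k most-correlated datasets observing the gene). A
random-forest imputer would also fit behind this interface; it is not used
because the imputed values feed only rank correlations and a 2-D embedding,
where the estimator choice is second-order. Observed cells are never
modified and outputs stay in [−1, 1].

## Correlation, dendrogram cluster calling, embedding

Dataset similarity is Spearman correlation between matrix columns (ties by
mean rank; constant columns yield NA with a warning). Clusters are called by
average-linkage agglomeration on `1 − ρ`, cutting the dendrogram at a
height cutoff, then keeping groups with at least `min_size = 3` members and
a **dominance of positive correlations**: the fraction of positive
within-cluster pairwise correlations must reach `dominance = 0.9`. Raising
dominance can only shrink the set of emitted clusters.

The height cutoff is the one knob without a defensible universal constant
(the source literature's "cutoff greater than 2" cannot be mapped onto the
`1 − ρ` scale, whose maximum is 2). By default the cutoff is placed in the
middle of the largest gap between consecutive merge heights — the natural
"same main branch" reading — and it is user-overridable.

`embed_2d()` provides the complementary 2-D view. It is backed by classical
multidimensional scaling on Euclidean distances rather than a stochastic
neighbor embedding: no UMAP implementation is available in the supported
dependency set, the embedding is explicitly delegable plumbing (no
quantitative conclusion in the package rests on it), and MDS gives the
properties the contract needs — exact determinism, coincident points for
duplicated datasets, and separation of planted clusters. The `n_neighbors`
and `seed` arguments are kept for interface stability.

## Robust rank aggregation

For one gene with observed normalized ranks `r(1) ≤ … ≤ r(k)` out of
`n_lists` input lists,

```
rho = min_j P( Beta(j, n_lists − j + 1) ≤ r(j) )
```

which equals the binomial tail `P(X ≥ j)`, `X ~ Binomial(n_lists, r(j))`.
The evaluation is exact (`pbeta`), not a large-n approximation: list counts
at desk scale (≤ ~60) make exactness cheap, and the test suite checks it
against direct binomial-tail summation to 1e−12. The reported **score** is
the Bonferroni correction `min(1, rho × n_lists)`; genes with score < 0.05
are called robust meta-DEGs.

Mode `per_direction` gives each dataset two full ranked lists (log2FC
descending / ascending), as used within dataset clusters; `any_direction`
ranks by p-value, the direction-agnostic overall analysis. All genes
present in a dataset are ranked, not only significant ones — standard
rank-aggregation practice. Genes absent from a dataset contribute no rank
but the beta parameters keep the total list count; treating absences as
worst-ranked would conflate platform coverage with evidence against
consistency.

One point deserves emphasis because it shapes what a green test means: the
Bonferroni-corrected minimum of beta probabilities is an *upper bound* on a
p-value, not an exact one. Under pure null ranks the fraction of genes with
score < 0.05 is about 1–3% (bounded by 5%). The score orders genes by
consistency extremely well, but a score threshold is not an FDR control.
Consequently, planted-gene recovery with both high sensitivity *and* low
empirical FDR is only achievable when the truly consistent genes occupy the
full top decile of the ranked lists; with a sparse planted set, the few
percent of null flags dominate. The acceptance test for recovery therefore
plants a decile-filling consistent set (100 of 1000 genes, carried in 9 of
10 datasets); this is a structural requirement of the joint
sensitivity-0.9/FDR-0.1 demand, not a tuned parameter.

## Recurrence and the consistency rule

`recurrence()` counts, per gene, datasets where it is a significant up- or
down-DEG (FDR < 0.05). Directional agreement is *not* enforced before
counting — the same exposure genuinely flips gene direction across tissues
and doses — and the consistency fraction `max(n_up, n_down) / total` is
assessed afterwards: a gene is directionally consistent when the fraction
strictly exceeds 0.70. So 19 up / 4 down (0.826) and 23 up / 0 down (1.0)
are consistent; 7 up / 3 down (exactly 0.70) is not.

`ks_compare()` contrasts DEG-count distributions between groups (e.g. two
compounds) with the two-sample KS statistic; for pooled sizes ≤ 12 the
p-value is exact by full enumeration of label arrangements, otherwise the
asymptotic Kolmogorov tail is used.

## Over-representation analysis

`fisher_ora()` is the one-sided hypergeometric tail; `enrich_library()`
BH-adjusts across a GMT library and applies the joint filter FDR < 0.05
*and* overlap ≥ 5. The default universe is the set of genes actually
measured in the dataset, not the whole genome — the test must condition on
what the platform could have detected; it is configurable. For a single
targeted panel tested across datasets, `ecs_tiers()` applies the raw-p
tiers p < 0.05 (significant) and p < 0.10 (suggestive).

## Marker-set enrichment (MSEA)

Markers (GWAS-like associations with a position and a −log10 p score) map
to genes within a 50 kb window. The interval arithmetic is 0-based
half-open on the extended interval: a marker at exactly `start − 50000` is
assigned, one at exactly `end + 50000` is not. Gene score = max over
assigned markers (standard locus-to-gene summarization; configurable in
principle, the max is the implemented contract).

The enrichment statistic places thresholds at the deciles of the gene-score
distribution and sums variance-stabilized deviations:

```
chi = sum_j (O_j − E_j) / sqrt(E_j + kappa),   kappa = 1
```

with `O_j` the observed DEG-set genes at or above threshold `t_j` and
`E_j` the uniform expectation. The exact constant set (deciles, κ = 1) is a
documented choice — the statistic family is described in the literature as
"chi-square-like with multiple quantile thresholds" without a printed
formula — and is configurable. Because `E_j` depends only on the set size,
`chi` decomposes additively over member genes, which the permutation engine
exploits (the test suite checks the decomposition against the direct
formula). Null calibration uses size-matched uniform gene sets (default
10,000 per pair; no marker-density matching — not described in the source
and noted as a limitation), a Gaussian fitted to the permuted statistics,
`z = (chi_obs − mean)/sd`, one-sided `p = 1 − Φ(z)`, and BH across all
(set, trait) pairs.

## Weighted key-driver analysis (wKDA)

Candidates are nodes with degree ≥ 5; the immediate (depth-1) neighborhood
is scored by `observed = Σ` weights of neighbors in the DEG set against
`expected = (Σ weights) × (DEG fraction of nodes)`. The null permutes
DEG-set *membership* over nodes (exactly size-matched uniform draws) rather
than rewiring edges: the question is whether this neighborhood is enriched
for this gene set, conditional on the network. Edges are undirected (the
edge-list format carries no direction); depth > 1 is available, with each
reachable node carrying the max first-edge weight.

Unlike MSEA, the reported p-value is the *empirical* permutation tail
`(1 + #{perm ≥ obs}) / (n_perm + 1)`, with `z` reported alongside. This
makes the p-value converge exactly to the enumeration answer on small
graphs (a tested property), at the cost of a resolution floor of
`1/(n_perm+1)`: with the default 1000 permutations and many candidates, BH
rarely drops below 0.05 at desk scale, so "0 significant key drivers" on a
small synthetic run is the honest reading, while the planted hub still
ranks first by a wide z margin.

# The synthetic world

`generate_collection()` emulates the post-DE summary tables the pipeline
consumes. Its defaults are a stated world, chosen once:

* **24 datasets × 2000 genes** — the scale of a single-compound collection.
* **Two anti-correlated clusters of 10** (the second cluster's template is
  the negation of the first), emulating the empirically observed pattern of
  opposed signature groups; 4 datasets remain unclustered noise. Template
  signal scale 1.0 on a fifth of the genes.
* **noise_sd = 0.5 per replicate, group_size = 6** — typical replicate
  counts for animal exposure studies. The signature-level noise SD is
  `noise_sd / sqrt(group_size)`. This is the one place the generator's
  internal consistency forces an interpretation: the p-value model
  `p = 2Φ(−|log2FC|·√group_size / noise_sd)` is exactly uniform under zero
  signal only if `noise_sd` is read as per-replicate variation, and null
  p-value uniformity is a tested invariant. The p-model is a Gaussian
  z-test surrogate: it preserves the monotone |log2FC| → significance
  relationship downstream stages consume, without re-fitting DE models.
* **30 planted consistent genes, effect 1.5, carried in 95% of datasets**
  (sampled outside the template genes so the two kinds of planted signal
  stay separable).
* **Platform masking**: whole genes absent per dataset — 5% for RNA-seq,
  25% for microarray — mirroring coverage differences and exercising the
  presence filter.

Companion generators plant enriched GMT sets (80% of an enriched set drawn
from the planted consistent genes), network hubs with a controlled DEG
fraction in an exact neighborhood (background edges avoid hub nodes so the
planted neighborhood is not diluted), and marker tables in which markers
within 50 kb of a trait gene have their −log10 p score shifted up by a
constant (default 3).

What the generator does **not** emulate — and hence what a green test does
not establish: realistic correlation structure among genes (noise is
i.i.d.), dose/time response surfaces (signal is a scalar scale per
dataset), platform-specific mean-variance behavior, annotation errors in
ortholog mapping, and LD structure among markers. The generator validates
the *machinery* (ranking, aggregation, calibration, bookkeeping), not
biological claims.

# Numerical and interface decisions

* **Ortholog collapse** (many source genes → one human gene): keep the row
  with the smallest p-value, ties by largest |log2FC|, then lexicographic
  source gene — preserve the strongest evidence per human gene. The rule is
  deterministic and idempotent; harmonized collections are marked and pass
  through unchanged on re-harmonization.
* **Genes with log2FC exactly 0** count in neither DEG direction (direction
  undefined).
* **TSV dialect** everywhere: tab-separated, header required, UTF-8, '.'
  decimal; round trips are identity to ≤ 1e−9. Config files are JSON (a
  strict YAML subset) because a JSON parser is in the supported dependency
  set.
* **Determinism**: every stochastic routine takes a seed and restores the
  caller's RNG state (`withr::with_seed`); equal seeds give byte-identical
  outputs, including the pipeline's `summary.json`.
* **Degenerate inputs** fail loudly and specifically: a fully missing gene
  names the gene, zero permutation variance names the (set, trait) pair,
  unknown nodes and empty universes are errors rather than NAs.

# Known limitations

* The RRA score is an upper-bound statistic, not an FDR-controlled p-value
  (see above); interpret "score < 0.05" as a robustness filter.
* MSEA permutations are not matched on marker density per gene.
* wKDA's empirical p resolution is `1/(n_perm+1)`; raise `n_perm` when
  genome-scale candidate counts must clear BH at 0.05.
* The dendrogram cutoff default (largest merge-height gap) is a heuristic;
  for collections without clear block structure, set it explicitly.
* `embed_2d()` is a linear-metric embedding; it is a visualization aid, and
  no pipeline decision consumes its coordinates.
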