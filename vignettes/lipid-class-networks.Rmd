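---
title: "Lipid class prediction from intensity networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid class prediction from intensity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipidGGM)
```

This vignette is the package's account of the science behind its
functions: the model, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

# The model

## Why a Gaussian graphical model

In untargeted LC-MS lipidomics, features of the same lipid class are
co-regulated: after conditioning on the rest of the lipidome, members of
a class remain mutually dependent, while spurious marginal correlations
(shared global abundance, indirect paths) are conditioned away. A GGM —
the undirected network whose edges are non-zero partial correlations —
is therefore the natural structure in which "neighbour" means
"biochemically related", and lipid class information localises in
network neighbourhoods. The package estimates the GGM from the intensity
matrix alone; no annotations are needed at any point.

## GGM estimation

`preprocessIntensities()` treats zeros as non-detects (missing),
excludes features missing in more than 10% of samples
(`maxMissingFrac = 0.10`), log-transforms (natural log; the base only
rescales and partial correlations are affine-invariant), and imputes the
remainder by k-nearest-neighbour imputation over samples (`imputeK = 5`,
Euclidean distance on co-observed entries rescaled for missingness,
uniform weights). The order — filter, then log, then impute — keeps the
imputation on the scale the network is estimated on.

`estimatePartialCorrelations()` uses linear shrinkage of the correlation
matrix toward the identity with the analytic-optimal intensity
(the ratio of the summed sampling variances of the empirical
correlations to their summed squares, clamped to [0, 1]), then derives
partial correlations from the standardized inverse. With many more
features than samples the shrinkage intensity is substantial (λ ≈ 0.5 on
the default synthetic study); this is the regime the estimator is built
for and is deterministic — no resampling, no tuning path.

`selectEdges()` assigns each off-diagonal partial correlation a p-value
under the null density f0(r; κ) ∝ (1 − r²)^((κ−3)/2), i.e. r² ~
Beta(1/2, (κ−1)/2). The effective degree of freedom κ is fitted by
maximum likelihood *truncated to the bulk* (|r| ≤ 4 robust scales, MAD
start): on data with real structure an untruncated fit lets the signal
tail widen the null by ~20% and costs true edges. Edges are kept where
the empirical-Bayes local false discovery rate (η₀·f0/f̂, with f̂ a kernel
density of the observed partial correlations, made monotone in |r|) is
at most `edgeAlpha = 0.05`; a Benjamini–Hochberg mode on the analytic
p-values is provided both as a config choice (`method = "bh"`) and as an
automatic fallback when the null fit degenerates (very small feature
sets). Downstream scoring uses the largest connected component
(`mainSubgraph()`), with ties broken toward the component containing the
lexicographically smallest feature id.

## Tentative structure matching

`matchFeatures()` compares observed to theoretical masses with a
*closed* ppm interval whose denominator is the theoretical mass —
conventions that matter for boundary behaviour and are fixed here once.
Grouped (analyte-deconvoluted) tables match neutral mass against
monoisotopic mass; ungrouped tables match m/z against
`(M + shift)/|z|` for every enabled ion form. The adduct table is plain
editable data (`defaultAdducts()`, `readAdducts()`); the proton mass is
fixed at 1.00727646677 Da.

Which ion forms beyond the primary `[M+H]+`/`[M−H]−` are plausible is
inferred from the data (`inferIonTypes()`): pairwise m/z differences of
features co-eluting within 1 s are pooled, a Gaussian kernel density is
estimated over (0, 60] Da, and an ion form is enabled when its
characteristic difference from the primary adduct lies within 0.01 Da of
a local density maximum exceeding 3× a reference level. Two numerical
choices deviate from generic defaults deliberately: the kernel bandwidth
equals the mass tolerance (0.01 Da) because adduct-difference spectra
are mixtures of near-delta spikes for which global bandwidth rules
(designed for smooth unimodal densities) smear peaks by orders of
magnitude more than the tolerance; and the reference level is the median
density floored at 1.5× the uniform level, so a single stray difference
cannot impersonate a peak. All three knobs are arguments.

`rtLogpFilter()` exploits the monotone hydrophobicity–retention
relationship of reversed-phase chromatography: a monotone non-decreasing
(pool-adjacent-violators) regression of entry logP on feature rt is
calibrated on features with exactly one logP-bearing match (at least 10
required, otherwise the filter disables itself with a warning), and
matches outside the central 95% band of absolute calibration residuals
are removed. Entries without logP always pass, and a feature's last
match is never removed unless `strict = TRUE` — the filter is meant to
prune implausible alternatives, not to unannotate features.

## Class scoring

The three score components and their defaults (`rtWindow = 50` s,
`alphaSelf = 5`) are given in the README. Design points that were
genuinely open and are fixed here (each toggleable):

* **Two-hop membership.** Any node reachable by a two-step path is
  scored in S2 even if it is also a direct neighbour — the most literal
  reading of "features connected by two-step paths"
  (`includeOneHop = TRUE`).
* **Intermediates.** The retention-time window applies to scored
  endpoints, not to the intermediate node of a two-hop path
  (`rtFilterIntermediates = FALSE`): the intermediate only carries
  correlation evidence, it is not itself claimed to share the class.
* **Multi-match neighbours** contribute full weight to each matched
  subclass; the indicator formulation is evaluated per class, with no
  splitting.
* **Empty max.** S_self uses max = 0 when no neighbour supports the
  feature's own match: an unsupported self-match should not score.
* **Ties** are reported (`tied = TRUE`), not silently resolved; a
  lexicographic tie-break is available for strictly deterministic
  pipelines.

## Quality scores

The LSI needs a notion of "k nearest neighbours" that is comparable
across features despite very different network degrees, so neighbours
are taken in a 2-D embedding of the min-max scaled absolute weighted
adjacency matrix under the cosine metric. The package embeds by
classical multidimensional scaling of those cosine distances: it is
deterministic, needs no tuning, and preserves exactly the property the
LSI consumes (small distances between nodes with similar adjacency
profiles). The conventional neighbour-count parameter of manifold
embeddings — 2% of the feature count, floored at 2 — and a
minimum-distance parameter of 1 are recorded in the embedding's
parameters for provenance. LSI uses k = 5 embedded neighbours;
unclassified neighbours are dropped from the proportions (proportions
must sum to 1 over actual classes), and a feature whose neighbours are
all unclassified has undefined LSI.

PCOR is the top score over the top-`K = 10` score mass; both LSI
(min-max scaled) and PCOR (uniform quantile transform, average ranks on
ties) are mapped to [0, 1]. The product score multiplies the
*post-transform* variants and is quantile-transformed again; a raw×raw
variant is available (`useTransformed = FALSE`) since either reading is
defensible. Quality scores are data-set-relative by construction
(rank-based); they are not transferable across assays.

## Baseline, evaluation, enrichment

The closest-m/z baseline searches at 10 ppm over the full configured
ion-form table, takes the minimal-|ppm| match, and treats candidates
within 1e−9 ppm of the minimum as exact ties (a float-equality guard
that captures identical molecular formulas). Ties are resolved uniformly
at random per seed; metrics are aggregated as mean ± SEM across seeds
(1000 by default).

Evaluation counts annotated-but-unpredicted features as errors in
accuracy and micro F1 — coverage differences must not inflate metrics.
Predictions whose subclass is absent from the annotated set enter the
hierarchical confusion matrix as "Other: correct main class" or
"Other: incorrect main class". The binomial 1-NN clustering test uses
σ = sqrt(μ0(1−μ0)/n), a one-tailed upper Z-test and BH adjustment across
classes (the adjustment procedure is a package choice, consistent with
the enrichment module).

Enrichment fits, per feature, a logistic regression of phenotype on
log-intensity plus covariates and combines the Wald p-values per
subclass with T = −2 Σ ln p. Because multiple ion rows of one analyte
are strongly correlated, the χ² reference for T is wrong; the null is
built instead from B = 10 000 phenotype-label permutations (covariates
stay attached to their samples — only the labels move), with the *same*
permutations shared across classes so the joint null preserves
inter-class correlation. The empirical p-value uses the add-one
estimator, bounded below by 1/(B+1), with BH across tested classes;
testing requires ≥ 15 features per class for predicted classes (≥ 3 is
the recommended setting for sparse ground-truth annotations). The
permutation refits run in compiled code (RcppArmadillo IRLS);
(quasi-)separated fits are refit with a small ridge and flagged, and
non-converged or constant-feature fits report p = 1 — conservative for
an enrichment statistic. Ranked class lists are compared by the
cumulative rolling Jaccard curve, its trapezoidal AUC normalised by the
maximum area, and a permutation p-value (B = 1000) from reshuffling one
list.

# The synthetic study

`generateDataset()` is the package's study-condition definition, not a
convenience fixture. Defaults: 6 subclasses (two per main class) × 40
analytes, 200 samples, adjacent-analyte partial correlation 0.4, 15%
cross-class identical-mass entries, 2 ion forms per analyte
(`[M+H]+`, `[M+Na]+` at a 0.35 intensity ratio, log-normal ion noise
sd 0.15), class retention windows of ±20 s around centres spaced over
100–700 s, ~1 ppm mass error, 5% missingness completely at random, and
an optional phenotype shifting chosen classes on the log scale, with
age/sex covariates drawn independently.

Two structural choices deserve their rationale:

* **Within-class dependence is a two-banded correlation structure**, not
  a bare first-order chain. Analytes are ordered (as by acyl chain
  length) and correlate with their two nearest class neighbours; the
  band heights are calibrated numerically so the *population partial
  correlation between adjacent analytes equals the configured target*
  (0.4 by default). A bare chain is a spanning tree: at these data
  dimensions each link is recovered with roughly 90–95% probability, so
  a 239-link chain breaks in ~10 places and the main subgraph collapses
  to ~10% of features — a topology no real lipidome exhibits. The
  banded structure provides the redundant local co-regulation that real
  class blocks have, while hitting the same pcor target.
* **Cross-class coupling is weak but non-zero.** Band entries crossing a
  class boundary are scaled by `interBlockPcor / withinPcor` (0.75 by
  default, a handful of pairs per boundary). Exactly zero coupling would
  split the GGM into one component per class, whereas real lipidomic
  GGMs are a single main subgraph covering >90% of features; the weak
  coupling reproduces that, and within-class edges still dominate the
  selected edge set by two orders of magnitude.

What the generator does *not* emulate: structured (intensity-dependent)
missingness, isotope envelopes, in-source fragmentation (the
diacylglycerol-fragment/estolide confound is a database-side ambiguity,
partially exercised through mass collisions and database pruning in the
tests), chromatographic drift, and covariate-phenotype confounding.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under honest but idealised conditions — not field
performance on any real assay.

# Problem sizes and tolerances in the test suite

The suite exercises conditional-independence recovery at n = 5000 on 3
variables, block-structure recovery at n = 500 on 40 variables,
false-edge control on 200 × 200 pure noise, the full default study
(480 ions × 200 samples) end to end across 3 generator seeds with the
closest-m/z baseline aggregated over 100 tie seeds, enrichment
calibration over 50 replicates of 20 classes at B = 500 permutations,
and 1000-seed baseline tie aggregation. Stochastic checks fix their
seeds; tolerances follow the sampling noise of each statistic (e.g.
3·SEM for tie-resolution means, ±0.1 for shrinkage-attenuated pcor
recovery at n = 500).

# Known limitations

* Predictions exist only inside the main subgraph; features that the
  network cannot place are reported unclassified rather than guessed.
* The scoring propagates database matches — with a sparse or biased
  database, guilt-by-association can propagate a wrong but
  mass-plausible class with high confidence; the product quality score
  is the designed guard (it is markedly lower on wrong predictions in
  the incomplete-database tests).
* Shrinkage attenuates partial correlations when features vastly
  outnumber samples; edge recovery, and with it coverage, degrades below
  roughly 100 samples.
* Quality scores are rank-based within one data set and must not be
  compared across assays.
* The enrichment model supports a binary phenotype with numeric/binary
  covariates; multi-level outcomes and mixed models are out of scope.
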