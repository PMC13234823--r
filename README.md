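# lipidGGM

Network-based lipid class prediction for untargeted LC-MS feature tables.

## The problem

Untargeted lipidomics detects thousands of MS1 features — (m/z, retention
time) signals with per-sample intensities — but only a small fraction ever
receives a structural annotation, because MS2 spectra are acquired
sparsely and spectral libraries are incomplete. Yet lipid class membership
is strongly encoded in the data themselves: lipids of the same class
co-regulate (their intensities are conditionally dependent) and co-elute
(class-specific retention behaviour in reversed-phase chromatography).

`lipidGGM` exploits this by combining two weak sources of evidence into
one strong one:

1. a **Gaussian graphical model (GGM)** estimated from feature
   intensities, whose edges are shrinkage partial correlations
   ρ surviving an empirical-Bayes multiple-testing procedure
   (α = 0.05), and
2. **accurate-mass matching** of features against an LMSD-style lipid
   structure database (±5 ppm, configurable ion forms).

For a feature *f* in the main subgraph of the GGM, each lipid subclass
*c* is scored by guilt-by-association:

    S1(c,f)   = Σ_{i ∈ N1(f)}  1{match(i) = c} · |ρ_{f,i}|
    w_{f,j}   = max_{i ∈ N1(f)} |ρ_{f,i}| · |ρ_{i,j}|
    S2(c,f)   = Σ_{j ∈ N2(f)}  1{match(j) = c} · w_{f,j}
    S_self(c,f) = α · max_{i ∈ N1(f)} { |ρ_{f,i}| : match(i) = c },  f matches c
    S(c,f)    = S1 + S2 + S_self

with neighbours restricted to a ±50 s retention-time window and α = 5 by
default. The top-scoring subclass is the prediction; the main class
follows from the database ontology. Two quality scores accompany every
prediction: a local Simpson's index (LSI) of subclass homogeneity among
the feature's 5 nearest neighbours in a 2-D embedding of the network, and
a PCOR score (top score normalised by the top-10 score mass), plus their
quantile-transformed product.

The package also provides the closest-m/z baseline (10 ppm accurate-mass
search with randomized tie resolution over many seeds), hierarchical
confusion matrices and classification metrics, a permuted
feature-to-node negative control, a binomial 1-NN embedding clustering
test, and a lipid class-level enrichment analysis: per-feature logistic
regression against a phenotype followed by an empirical Fisher's method
(T = −2 Σ ln p) whose null distribution is built from phenotype
permutations, preserving inter-feature correlation, with BH correction
and rolling-Jaccard ranking concordance between analyses.

A synthetic-study generator (`syntheticConfig()`, `generateDataset()`)
emulates block-correlated class structure, class retention windows,
adduct multiplicity, mass collisions, missingness and phenotype effects,
so the full workflow is testable without any external data.

## Worked example

```r
library(lipidGGM)

cfg <- syntheticConfig(seed = 1)      # 6 subclasses x 40 analytes, n = 200
ds  <- generateDataset(cfg)
ds$featureSet
#> LipidFeatureSet: 480 features x 200 samples
#>   polarity: positive (ungrouped ions)
#>   rt range: 80.5 - 719.6 s;  m/z range: 403.2888 - 1021.8864
#>   missing intensities: 5.0%

res <- runClassPrediction(ds$featureSet, ds$db)
res$network
#> PcorNetwork: 479 nodes, 1364 edges
#>   |rho| range: 0.0493 - 0.27
#>   n samples: 200 ; shrinkage lambda: 0.5097

head(res$predictions[, 1:5], 4)
#>   feature_id   subclass  main_class    score  tied
#> 1   F0001_MH Subclass01 MainClass01 1.837879 FALSE
#> 2  F0001_MNa Subclass01 MainClass01 1.824033 FALSE
#> 3   F0002_MH Subclass01 MainClass01 1.718699 FALSE
#> 4  F0002_MNa Subclass01 MainClass01 1.753842 FALSE

truthReport(ds, res$predictions)
#> $subclass_accuracy    [1] 0.9979167
#> $main_class_accuracy  [1] 0.9979167

# the conventional closest-m/z search is capped by isomeric mass ties
bl <- repeatClosestMz(ds$featureSet, ds$db, ds$annotations, nSeeds = 100)
subset(bl, level == "subclass" & metric == "accuracy")
#>      level   metric      mean         sem
#> 1 subclass accuracy 0.8629792 0.001038444
```

Network class scoring recovers 99.8% of the planted subclasses (one
feature is lost to the missingness filter), while the closest-m/z
baseline plateaus at ~86%: the generator plants identical-mass isomer
pairs across classes, which an accurate-mass search can only resolve by
guessing, but the network disambiguates through neighbours.

A command-line interface wraps the same functions
(`inst/scripts/lipidggm-cli.R` with subcommands `simulate`, `predict`,
`baseline`, `evaluate`, `enrich`, `concordance`).

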