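# otubench

Benchmarking multivariate ANOVA-like statistical methods for microbiome
intervention studies.

Dietary (and other) intervention trials produce OTU count tables from
small, designed experiments — a few dozen samples crossed over two or more
factors (diet, dose, period, subject). Many statistical routes exist for
asking "did the intervention change the community, and which taxa
changed?", and they frequently disagree. `otubench` implements, in one
tested pipeline, the main contenders and a simulation harness for
comparing them, for biostatisticians and bioinformaticians who need to
choose (or defend) an analysis strategy for such designs.

## What is implemented

**Compositional preprocessing.** Counts are closed to relative abundances;
OTUs are kept when their relative abundance exceeds 0.005% in at least one
sample *and* they are present in at least 50% of the samples of at least
one group; zeros are replaced multiplicatively (each zero in sample *i*
becomes 0.65 × the detection limit 1/depth<sub>i</sub>, with non-zero
parts rescaled so ratios are preserved); the centred log-ratio transform
maps each sample to `clr(x)_j = log x_j − mean_k log x_k`.

**Community-level tests.** For a clr matrix **X** and model terms
*t = 1…T* the ANOVA partition **X** = **M** + Σ<sub>t</sub>
**E**<sub>t</sub> + **R** gives per-term sums of squares
‖**E**<sub>t</sub>‖² and effect sizes 100·SSQ<sub>t</sub>/SSQ<sub>tot</sub>:

- **ASCA** — sequential partition of the centred clr matrix, permutation
  p-values (999 permutations), PCA scores/loadings per effect matrix;
- **50-50 MANOVA** — partial (adjusted) sums of squares on the autoscaled
  clr matrix, with an F-type statistic evaluated in the principal-component
  subspace holding ≥50% of the variance, tested by permutation;
- **PERMANOVA** — the same partition applied to a Gower-centred distance
  matrix (Euclidean on clr by default), with pseudo-F permutation tests;
- **ANOSIM** — rank-based R statistic on a combined one-way factor.

**OTU-level procedures** (each returns a ranking table with the method's
own significance rule): SIMPER contributions to Bray-Curtis dissimilarity
with permutation p-values; per-OTU F tests with rotation-based familywise
adjustment; PLS-DA with VIP scores thresholded by uninformative-variable
elimination (UVE); the ANCOM W statistic (number of rejected pairwise
log-ratio tests per OTU); a Dirichlet Monte-Carlo clr test
(Dirichlet(counts + 0.5) posteriors, expected p-values); and a
negative-binomial GLM Wald test with median-of-ratios size factors and
trend-shrunken dispersions.

**Simulator + harness.** A Gamma / multivariate-hypergeometric count
simulator (per-OTU, per-group Gamma intensities; counts drawn without
replacement so each sample sums exactly to its sequencing depth), four
named fold-change scenarios (`few_low`, `few_high`, `many_low`,
`many_high`: 10 or 254 OTUs changed by uniform log2 fold changes in [3,4]
or [8,9] in one diet level), and an evaluation harness computing community
detection rates, TPR = TP/P, TNR = TN/N against the simulation truth,
pairwise Spearman rank agreement, and abundance-dependence diagnostics.

## Worked example

Simulate one `few_high` data set (10 OTUs spiked by 2^[8,9] in diet level
A), preprocess it, and analyse it:

```r
library(otubench)
template <- make_default_template(n_otus = 120, n_per_cell = 4,
                                  depth_mean = 2e4, seed = 8)
inj <- apply_scenario(template, scenario_preset("few_high", seed = 8))
ds  <- sample_counts(inj$params, seed = 9, truth = inj$truth)
#> <sim_dataset> 24 samples x 120 OTUs, 10 true positives

cells  <- combine_factors(ds$metadata, c("diet", "dose"))
prep   <- preprocess_counts(ds$counts, cells)
design <- build_design(ds$metadata, "diet*dose")

fit <- asca(prep$clr, design, n_perm = 999, seed = 10)
tidy(fit)
#> # A tibble: 4 x 5
#>   term         df    ss explained_variance_pct p_value
#> 1 diet          2 2239.                  35.3    0.001
#> 2 dose          1  213.                   3.36   0.697
#> 3 diet:dose     2  369.                   5.82   0.943
#> 4 residuals    18 3521.                  55.5   NA
```

The spiked diet effect explains ~35% of the clr variance and is highly
significant, while the (truly null) dose main effect and interaction are
not. OTU-level rotation tests then rank the changed OTUs first:

```r
rot <- rotation_pvalues(prep$clr, design, "diet", n_rot = 999, seed = 11)
head(tidy(rot)[order(rot$rank), ], 3)
#>   otu_id    statistic  rank significant     f        p_raw p_adjusted
#> 1 OTU030 0.0000000139     1 TRUE         58.2 0.0000000139      0.001
#> 2 OTU077 0.0000000420     2 TRUE         50.4 0.0000000420      0.001
#> 3 OTU091 0.0000000930     3 TRUE         45.4 0.0000000930      0.001

tpr_tnr(setNames(rot$significant, rot$otu_id), ds$truth[rot$otu_id])
#> # A tibble: 1 x 6
#>     tpr   tnr    tp     p    tn     n
#> 1   0.8 0.667     8    10    72   108
```

8 of the 10 planted OTUs are recovered at p < 0.01 (TPR 0.8). The reduced
TNR illustrates a real phenomenon this package makes visible: spiking a
few OTUs by ~2^8.5 shifts *all* relative abundances (counts are
compositional), so unchanged OTUs genuinely move too — see the vignette
for the full analysis.

Multi-method comparison over simulated scenario batches:

```r
run <- run_benchmark(make_default_template(seed = 1),
                     scenarios = c("few_low", "many_high"),
                     n_datasets = 30, seed = 1)
summarize_benchmark(run)   # detection, TPR/TNR, Spearman, abundance tables
autoplot(run, "detection")
```

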