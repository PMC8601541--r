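---
title: "Models, simulator and design choices in otubench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulator and design choices in otubench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`otubench` compares ANOVA-like multivariate methods on OTU tables from
designed intervention experiments. This vignette explains the statistical
content: the preprocessing chain, each method's model and assumptions, the
count simulator, the tunable parameters with their defaults, the numerical
conventions, and the open design points we had to decide — together with
what the simulation results do and do not demonstrate about real data.

## The data and the preprocessing chain

The raw object is a samples × OTUs matrix of sequencing counts. Counts are
*compositional*: the sequencing depth is an instrument property, so only
relative abundances carry biological signal, and increasing one taxon
necessarily decreases the relative abundance of all others. All linear
multivariate methods here therefore operate on the centred log-ratio (clr)
transform, `clr(x)_j = log x_j − mean_k log x_k`, which is invariant to
per-sample scaling and maps compositions to a zero-row-sum Euclidean
space.

The chain, applied identically to experimental and simulated data:

1. **Closure**: divide each sample by its depth.
2. **Filter**: keep OTU *j* when (a) its relative abundance exceeds
   `min_rel = 5e-5` (0.005%) in at least one sample — strict inequality —
   and (b) it is non-zero in at least `prevalence = 0.5` of the samples of
   at least one group — inclusive inequality, evaluated within each group
   so that group-specific taxa survive. Filtering precedes zero
   replacement.
3. **Zero replacement** (count-zero multiplicative): each zero in sample
   *i* becomes `delta_frac = 0.65` times the detection limit
   (1/depth when counts are known, else the smallest positive part), and
   the non-zero parts are rescaled multiplicatively. This preserves every
   ratio between observed parts — the property that matters for log-ratio
   analysis — and re-closes each row exactly. A warning is raised if the
   imputed value exceeds an observed one.
4. **clr**, then column **centring** (ASCA, distances) or **autoscaling**
   (50-50 MANOVA, rotation tests). Autoscaling gives every OTU equal
   weight; without it the analysis is dominated by the abundant, variable
   OTUs. Columns with essentially zero variance (sd < 1e-12) are left
   centred with a warning.

## Community-level models

Let **X** (n × p, p ≫ n) be the processed clr matrix and let the design
carry terms *t* (main effects, interactions, optionally a fixed subject
block). With sum-to-zero contrasts, **X** decomposes into per-term effect
matrices plus residuals; on balanced designs the term and residual sums of
squares add exactly to the total, and the *effect size* of a term is
100·SSQ_t/SSQ_total.

* **ASCA** uses the sequential (Type I) partition of the centred matrix and
  assesses each term by permuting sample rows and recomputing its SSQ; PCA
  of each effect matrix yields scores and loadings for interpretation.
* **50-50 MANOVA** uses partial (adjusted) SSQ on the autoscaled matrix.
  Classical MANOVA fails when p > n; the 50-50 construction evaluates an
  F-type ratio in the subspace of the leading principal components that
  carry at least `pc_fraction = 0.5` of the variance. Row permutation
  leaves the PC directions of X unchanged (X'X is permutation-invariant),
  so the permutation null is computed exactly in that fixed subspace. For
  a single response the statistic reduces algebraically to the classical
  ANOVA F.
* **PERMANOVA** partitions the Gower-centred matrix of −½d²; with
  Euclidean distances on centred clr data the partition is algebraically
  identical to the direct one (a property the test suite asserts to 1e-6),
  which is why these columns agree so closely in practice.
* **ANOSIM** is one-way only; multi-factor designs are collapsed to a
  combined cell factor. Its "effect size" is reported as 100·R for
  comparability, a reporting convention rather than an explained variance.

Permutation p-values use the add-one convention (1 + b)/(1 + m), so p is
never zero; with exhaustive enumeration (available for n ≤ 8) the p-value
is the exact enumeration probability. Free permutation of rows is used for
all terms — the simplest scheme that is exact for one-factor nulls and a
good approximation for the balanced crossed designs targeted here;
restricted permutation schemes are out of scope.

## OTU-level procedures

* **Rotation/F tests**: per-OTU partial F statistics; raw p-values are
  parametric, and familywise-adjusted p-values come from a max-statistic
  rotation test (random orthogonal rotations of the hypothesis⊕residual
  coordinates, exact under Gaussian errors). Adjusted p is floored at the
  raw p so monotonicity holds exactly. Ranking and the 0.01 significance
  rule use the raw p.
* **SIMPER**: per-OTU contributions to the mean between-group Bray-Curtis
  dissimilarity (they sum to it exactly); the p-value is the permutation
  probability of a larger contribution.
* **PLS-DA/VIP/UVE** (the OTU arm of ASCA): PLS regression of a two-class
  dummy on the diet effect matrix plus residuals; VIP scores satisfy
  mean(VIP²) = 1. The component count is picked by 10-fold cross-validated
  classification error, capped at 5. UVE appends one noise variable per
  real OTU (an independent permutation of that column, preserving its
  marginal distribution), and an OTU is significant when its VIP exceeds
  the maximal noise VIP in ≥95% of 100 repetitions. For two-level factors
  OTUs are ranked by the first-component loading magnitude of the effect
  matrix; for multilevel factors by |PLS regression coefficient|.
* **ANCOM W**: for every ordered OTU pair, the log-ratio is regressed on
  the factor (+ additive covariates); within each OTU the p-values are
  BH-adjusted (within-OTU scope, the original construction) and W counts
  rejections at 0.05. All pairwise tests are computed in closed form from
  two p × p cross-product matrices. The significance threshold is
  `0.6 · (m − 1)` — a fraction of the maximal attainable W. An empirical
  60th-percentile rule is also offered (`w_rule = "quantile"`), but it
  flags ~40% of all OTUs by construction, which is incompatible with the
  near-perfect specificity this family of methods is reported to have; the
  fraction-of-maximum rule is the default for that reason.
* **Dirichlet Monte-Carlo clr test**: `n_mc = 128` posterior compositions
  per sample from Dirichlet(counts + 0.5), clr per instance, per-OTU
  F tests per instance; the reported statistics are the expected raw and
  expected BH-adjusted p-values. As counts grow the posterior concentrates
  and the expected p converges to the plain clr F-test p.
* **NB-GLM Wald test**: a deliberately simple count model —
  median-of-ratios size factors, per-OTU ML dispersion given closed-form
  cell-mean fits, log-space shrinkage of dispersions halfway toward a
  parametric trend `a0 + a1/μ`, and a Wald test of one level contrast.
  The Wald statistic is referred to a t distribution with residual df
  rather than the normal: at n ≈ 12–48 this keeps the null rejection rate
  near nominal, where the normal reference is visibly anti-conservative.
  There is no Cox-Reid adjustment, outlier refitting or LFC shrinkage.

Significance rules for benchmarking: p < 0.01 for the p-value methods,
W ≥ 0.6(m−1) for ANCOM, ≥95/100 UVE selections for ASCA.

## The simulator

Counts are generated in two stages: the expected relative intensity of
OTU *j* in group *g* is Gamma(shape, rate) distributed, and a sample of
depth N is drawn from an urn with `round(λ_j/Σλ · 10^6)` items per OTU by
sequential conditional hypergeometric draws — a multivariate
hypergeometric sample, so counts sum *exactly* to N (a property asserted
in the tests, and the qualitative difference from Poisson-type
simulators). Depths are log-normal (mean 5·10⁴, CV 0.25) or resampled
from a template. `estimate_params()` recovers Gamma parameters from a real
table by moment matching (shape = m²/v, rate = m/v per OTU and group, the
variance floored at m²·10⁻⁴ to avoid degenerate infinite shapes).

`make_default_template()` provides a fully synthetic template so that the
whole repository is testable without any external data: 507 OTUs with
log-normal mean intensities (sdlog 2, giving a few dominant OTUs above 1%
and a long rare tail), per-OTU Gamma shapes uniform on [0.1, 1.5]
(biological CVs of roughly 80–320%), and a 3-diet × 2-dose design with 8
samples per cell. The sample size and dispersion were fixed by two
published constraints on the scenario outcomes: the community effect size
of the weakest scenario is about 5%, and of the strongest 30–35%. With a
2-df diet term the null expectation of the explained variance is
2/(n−1), so ~5% is only attainable at n ≈ 48; and with n = 48 the chosen
dispersion range reproduces both reported effect sizes. These template
constants are study conditions, set once and not revisited.

Scenarios multiply the intensity means of `n_da` randomly chosen OTUs by
2^U[low, high] in every cell of one diet level (the first, by default;
the dose factor is never touched) and re-normalise each group's
intensities. Re-normalisation makes the compositional knock-on explicit,
but it is not optional in substance: closed sampling normalises
intensities regardless, so spiking mass into some OTUs necessarily
depresses the relative abundance of all others. A `renormalize = FALSE`
switch documents the convention.

### What the simulator does not emulate

No sequencing error or chimeras, no phylogenetic or ecological correlation
structure between OTUs beyond the compositional constraint, no
subject-level random effects or longitudinal autocorrelation, and no
zero-inflation beyond what low intensities and finite depth produce.
Passing benchmarks here therefore demonstrate correctness of the methods
and their behaviour under a *clean* two-factor design with heavy-tailed,
overdispersed, compositionally-closed counts — not performance under the
messier correlation structure of real gut communities.

### The compositional knock-on, specificity, and what "true negative" means

In the `many_high` scenario, half the OTUs gain ~2^8.5 intensity, so the
unchanged OTUs lose ~2^7 of *relative* abundance in the affected group.
They are unchanged in absolute intensity but strongly changed in every
observable (relative) sense. Methods that test relative abundances then
flag them — and under the labels of the simulation truth this counts
against specificity. In our runs the TNR of several procedures
deteriorates markedly in the `many`/`high` scenarios for exactly this
reason, while the `few` scenarios (10 OTUs, ~2% of total mass) are nearly
knock-on-free and all methods keep TNR ≥ 0.95 there. We report this as a
property of the simulation design rather than hiding it: with half the
community differential, "differentially abundant relative to what?" has
no answer a compositional method can be blamed for. The clr-based
community tests are unaffected in their *null* calibration (the test
suite checks type-I error for every p-producing method on effect-free
simulations).

### The ANCOM abundance diagnostic

ANCOM's W is structurally tied to abundance: abundant OTUs have
well-estimated log-ratios and end up with either very high W (if changed)
or very low W (if demonstrably stable), while rare OTUs hover in the
noisy middle. A plain rank correlation between W and abundance cannot see
this V-shape (it averages the two arms away), so the harness quantifies
the pattern as the Spearman correlation between log mean abundance and
the *extremity* |W − median(W)|, which is positive when abundant OTUs
occupy the extremes. The plain signed correlation is also reported.

## Numerical conventions and degenerate inputs

* Permutation p-values: add-one convention; exhaustive enumeration for
  n ≤ 8 uses the exact enumeration probability (identity included).
* Seeds: every randomised function takes an explicit integer seed; batch
  runs derive per-dataset seeds from the master seed by a counter scheme,
  so adding methods does not perturb the simulation streams and reruns
  are bit-identical.
* Aliased design columns (e.g. subject within diet in crossover layouts)
  are dropped by QR pivoting with a message; fully aliased terms are an
  error naming the term.
* Ties in rankings: average ranks, everywhere.
* Threshold boundaries: abundance filter strict (>), prevalence and the
  ANCOM/UVE thresholds inclusive (≥); all unit-tested.
* Degenerate cases: all-zero samples are an error at closure; an all-zero
  OTU is removed by the filter; constant clr columns are centred but not
  scaled; a Gamma shape of 0 marks an OTU structurally absent from a
  group; urn overflow (depth exceeding urn size) doubles the urn scale
  with a message.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the benchmark at 30 data
sets per scenario for community detection and rank agreement, 6 per
scenario for the full OTU-method error rates (significance rules at their
defaults, 999 permutations), and 150 effect-free data sets at reduced
dimension (30 OTUs) for the type-I calibration checks. These sizes give
binomial standard errors of ~7 points on a detection percentage and were
chosen to keep a complete run at desk scale; `run_benchmark()` takes
`n_datasets = 100` for the full-size design.

## Known limitations

* The 50-50 MANOVA here follows the retained-PC contract (≥50% variance,
  permutation p); it is validated against the univariate reduction and
  null calibration, not against any particular reference implementation's
  buffer-dimension bookkeeping.
* The NB-GLM is intentionally minimal (see above) and should not be read
  as a reimplementation of any specific differential-expression tool.
* ANCOM is the W-counting construction only — no structural-zero
  detection, no nonparametric pairwise tests.
* Free permutation is approximate for testing one term in the presence of
  strong other effects; for the balanced designs simulated here the
  approximation is good (verified by calibration), but heavily unbalanced
  designs would need restricted schemes.
* UVE-thresholded VIP selection loses power when a large fraction of OTUs
  is informative (the noise VIP ceiling rises with them); this is visible
  in the `many` scenarios and is a property of the selection rule.
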