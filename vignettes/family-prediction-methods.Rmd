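---
title: "Methods: genome-wide family prediction from pooled genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide family prediction from pooled genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the design decisions behind `gwfp`, and states precisely what
the synthetic-data generator does and does not emulate.

## The setting

The unit of analysis is an open-pollinated half-sib **family pool**: DNA of
all individuals of a family is pooled before genotyping-by-sequencing, so a
family's genotype at a biallelic SNP is an *allele frequency*, estimated as
the alternative-read fraction. Phenotypes are recorded per individual over
repeated harvest clippings (wet season: clippings 2, 3, 7, 8, 9; dry: 4, 5,
6; plus totals "T") for five traits (GM, DM, RG, LDM, SDM), averaged per
family and Min–Max scaled per trait-clipping. Prediction is therefore
family-level regression of a scaled family mean on a [0, 1]-valued
frequency matrix **Z** — no allelic dosages are called at any point.

## Genotype processing

* **Depth rule** (`min_depth = 20`): applied per (marker, family) cell —
  the per-genotype convention of standard VCF filtering tools — setting the
  cell missing; a `depth_mode = "site_mean"` switch instead drops whole
  markers by mean depth, since the wording "minimum sequencing depth of 20
  reads" admits both readings.
* **Filter order**: depth → (biallelic, enforced by the VCF reader) →
  missingness (`max_missing = 0.25` per site) → redundancy. Redundant
  markers (frequency vectors identical within 1e-12, including their
  missingness pattern) are removed keeping the *first in (chromosome,
  position) order* — a deterministic tie-break.
* **Imputation** strictly after all filters, by the site mean of the
  non-missing frequencies. An all-missing marker is an error by
  construction (`max_missing < 1` guarantees a donor).
* **PCA** is computed on centered, *unscaled* frequencies (all entries
  already share one scale); component signs are fixed by making each
  component's largest-magnitude loading positive.

## Heritability

Per trait, `reml_variance_components()` fits `y = Xr + Zg + e` (fixed block
effects, random family effects) by **EM-REML** on the mixed-model
equations. EM was chosen over faster Newton-type algorithms because its
REML log-likelihood is monotonically nondecreasing, which the test suite
asserts step by step; the likelihood is evaluated cheaply through the
family-block structure of V (Z'Z is diagonal), never via an n × n solve.
Convergence: relative change of both components < 1e-8, or a flat
log-likelihood (relative change < 1e-10, the practical fixed point when a
component creeps toward a zero boundary, where EM's geometric rate would
otherwise never satisfy the component criterion); hard cap 10,000
iterations, with the last iterate attached to the error condition.

Family-mean heritability is h² = σ²g / (σ²g + σ²e/ñ), ñ the harmonic mean
family size. A narrow-sense report divides σ²g by a **relationship
coefficient** (default 0.25, the diploid half-sib value): the correct
coefficient for autotetraploid half-sibs is genuinely unsettled, so it is a
parameter, and both corrected and uncorrected values are always reported.

## Prediction engines

All hyperparameters default to the study values and are overridable via
`model_spec()`:

| model | key settings |
|---|---|
| RKHS | Gaussian kernel `exp(-d²/q)`; Gibbs sampler, 20,000 iter / burn-in 2,000 / thin 5 |
| BRR | common normal shrinkage prior; same MCMC schedule |
| SVM | radial kernel, γ = 1/(p·σ²_Z), cost 1, ε = 0.1 |
| RF | 100 trees, variance split, min split 2 / leaf 1, bootstrap, no depth cap |
| AB | AdaBoost.R2, depth-3 tree base learner, linear loss, ≤ 50 stages |
| MLP | one hidden layer, 100 ReLU units, L-BFGS, L2 = 0.001 |

**BRR** is a per-marker Gibbs sampler (RcppArmadillo): `y = μ + Zβ + e`
with β\_j ~ N(0, σ²β) and scaled-inverse-χ² hyperpriors (df 5, scales
matched to 50% of the response variance — the convention of the standard
Bayesian regression packages; overridable). **RKHS** samples in the
eigenbasis of K, where the coefficients decouple and every update is O(n);
test-family predictions use K\_test,train · K⁻¹\_train · ū. The
bandwidth q defaults to the **median off-diagonal squared distance**
(the study does not state its value; overridable). With variance
components *fixed*, both posterior means collapse to ridge
(Z'Z + λI)⁻¹Z'y and kernel ridge K(K + λI)⁻¹y — the module's central
correctness oracle, run without an intercept because the closed forms
carry none (`include_mu = FALSE`).

AdaBoost.R2 and the ReLU MLP are implemented in the package (no installed
R implementation provides Drucker's R2 scheme or a ReLU single-layer
quasi-Newton regressor); SVM uses libsvm via e1071, forests use ranger.

**Cross-validation**: fresh random partition into k = 5 near-equal folds
per repetition; PA and MSE are computed on the **pooled** out-of-fold
predictions of a repetition (`pa_mode = "pooled"`), because fold-level
correlations on 10 families are unstable; a `per_fold_mean` mode is
provided since the aggregation order is not dictated by the design. A
degenerate PA (constant vector) is recorded as 0 with a flag rather than
dropped, keeping repetition counts balanced for the ANOVA. Note that
repetitions share the one dataset, so on a fixed pure-noise response the
repetition mean concentrates on that draw's chance correlation with Z (±
~0.15 at n = 50) — only the average over independent datasets is centered
on zero; the tests respect this distinction.

**Model comparison**: one-way ANOVA on repetition-level values, Tukey HSD,
and an insert-absorb compact letter display with "a" on the highest mean.
For PA the best scenarios are those whose letters contain "a"; for MSE
(lower is better) those containing the last letter in use.

## Feature selection and major markers

FS-1 is gradient tree boosting (squared error, learning rate 0.1, 100
stages, trees capped at 3 leaves — fitted with xgboost, lossguide growth,
regularization terms zeroed), FS-2 extremely randomized trees, FS-3 random
forest (both 100 trees, all features per split, via ranger). A marker is
*selected* iff its impurity importance is strictly positive
(`selection_rule = "positive"`): the criterion is not stated in the study,
and positive importance reproduces the characteristic set-size ordering
(boosting's 3-leaf trees touch few hundred features; forests touch most).
FI-1/FI-2 are the ≥2-of-3 and 3-of-3 intersections, kept in genome order.

Gini importance on FI-2 is the rf-selector forest's impurity importance
normalized to sum 1; ties are broken by genome order. The major set is the
top 3 markers extended while the cumulative importance is below 0.5 — by
construction minimal whenever it exceeds 3 markers.

## Linkage and network

A gene is linked to a marker when its annotated span *intersects* the
marker's ±5,000 bp window ("overlap" anchor; a "start" anchor is provided
because an alignment-based annotation could arguably be tested by its
start coordinate only). BED input is converted to 1-based inclusive
coordinates internally; intersection uses GenomicRanges.

The coexpression network uses the **highest reciprocal rank**: each gene
ranks all others by descending Pearson r (ties broken by gene order, so
the network is deterministic), HRR(i,j) = max of the two directed ranks,
edge kept iff HRR ≤ 30. The "limit of 30 edges" is read as the HRR rank
cutoff — the convention of the HRR method itself — not a post-hoc cap of
30 edges per node; a `top_edges` mode implements the other reading.
Seed-set expansion adds genes with r ≥ 0.9 to some seed and Bonferroni
adjusted p ≤ 0.01, the multiplier being the number of tested pairs.
Seasonal subnetworks re-run the two-step neighborhood from
season-restricted seeds; genes associated only with total ("T") columns
seed neither network, since totals are not season-specific. Hubs are
degrees above the Tukey fence Q3 + 1.5·IQR — the study says only "outlier
values", and its numeric cutoffs ("> 4", "> 40") are data outcomes, not
rules — computed on the extracted trait subnetwork. Term enrichment is the
classic hypergeometric upper tail at raw p < 0.01 (no multiplicity
correction there, matching the stated procedure; Bonferroni applies only
to the correlation expansion).

## The synthetic-data generator

The generator's defaults *are* the study conditions: 50 families, 9
chromosomes, mean GBS depth 60 with negative-binomial dispersion, 10%
missing cells (as depth-0 cells, the form GBS missingness takes, applied
before filters), 33 trait-clippings with heritability targets spread over
[0.44, 0.92], 11 expression samples. Sizes used in tests are smaller
(500–2,000 markers, 1–3 traits, 10 CV repetitions) and are stated in each
test; they keep every recovery property intact because marker effects are
sparse by design.

Choices where the design was open:

* **Family frequencies** are Beta-distributed around a founder frequency
  drawn from U(0.05, 0.95), concentration 10: no family-genetics
  generative law is given for autotetraploid half-sib pools, and the Beta
  keeps [0, 1] support with tunable between-family variance. The
  within-family variance split (`within_family_frac`) is likewise a
  parameter, not an asserted coefficient.
* **Trait correlations are induced by QTL sharing**, not correlated noise:
  a common QTL subset carries a variance share equal to `trait_corr`, so
  feature selection has a recoverable shared-marker signal. `trait_corr`
  targets the correlation of family *genetic values*; observed family-mean
  correlations are attenuated by √(h²ᵢh²ⱼ) (~0.5 under the default
  heritability grid). Matching the observed ≈0.7 on phenotype means would
  require a genetic correlation above 1 under a uniform heritability grid
  over [0.44, 0.92], so the genetic-value interpretation is the coherent
  one. With a single simulated trait, sharing is undefined and tests use
  `trait_corr = 1`.
* **No linkage disequilibrium**: markers are independent, so "a selected
  marker within 5 kb of a planted QTL" effectively means recovering the
  QTL marker itself — a *stricter* recovery criterion than real data
  would pose. Consequently, models on the complete data have almost no
  signal (the kernel is noise-dominated), which makes the
  selection-improves-prediction trend pronounced; passing these tests
  shows the selection machinery works, not that CD-based prediction would
  be weak on real, LD-structured genomes.
* One global seed; each stage derives its stream by a fixed offset, making
  every fixture byte-identical under a fixed configuration.

What the generator does **not** emulate: linkage-disequilibrium haplotype
structure, tetraploid dosage genotypes, sequence-level reads (FASTQ),
population stratification, or genotype-by-environment interaction across
clippings.

## Bundled benchmark tables

`gwfp_benchmark()` ships the published 50-family benchmark tables as plain
TSVs. `aggregate_model_comparison()` reproduces their printed aggregates
exactly under one specific order of operations: percent differences per
clipping from the table-precision values, per-phenotype means of the
*unrounded* percentages, overall mean = mean of the five phenotype means,
rounded only for display. This order was verified arithmetically against
the printed overall values (6.9% PA gain, −22.6% MSE change); other orders
do not reproduce them.

## Known limitations

* EM-REML is slow near zero-variance boundaries (hence the likelihood
  fixed-point stop) and handles a single random effect; no spatial trend
  correction or multi-trait models.
* The enrichment test is the plain hypergeometric, without the
  topology-aware decorrelation of dedicated GO tools.
* The MLP mirrors the stated architecture but, like any untuned neural
  network at n = 50, it is expected to underperform the other engines.
* Interfaces are R functions plus `run_pipeline()`/`pipeline_report()`;
  there is no shell entry point, as the package targets interactive and
  scripted R analysis.
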