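---
title: "Models and methods behind the onecarbon pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the onecarbon pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onecarbon)
```

`onecarbon` analyses targeted-metabolomics panels of B-vitamin-related
compounds and one-carbon-metabolism genotypes in case-control brain cohorts.
This vignette explains the statistical models, the preprocessing rules, the
synthetic-data generator that stands in for real cohorts, and the design
choices made where the methodology was genuinely open.

## The synthetic cohort

The generator emulates a post-mortem brain-bank study: five groups (36
healthy controls HC-CN, 14 PD-CN, 19 PD-MCI, 32 PD-D, 35 AD-D; n = 136 at
cortex scale), elderly ages (mean 81, SD 6 years), roughly balanced
sociodemographics, four comorbidity flags, short log-normal post-mortem
intervals (median about 3 hours) and 4–18 years of freezer storage. Half of
the PD subjects are acutely levodopa-exposed at death, which elevates their
tissue DOPA by 3 control SDs on the log scale. Where the study design fixes
a quantity (group sizes, the LOD and percentile constants, the GP penalty
and budgets) the generator uses it; remaining distribution parameters were
chosen once as values a brain-bank cohort plausibly shows and are not tuned.

Concentrations are simulated log-normally: `log C = baseline + β·SD_m +
plate offset + N(0, SD_m)`, with planted effects `β` expressed in units of
the metabolite's control-level biological SD. Log-normality makes the
Box-Cox stage meaningful (the estimated λ concentrates near 0) and keeps
concentrations positive. Each plate carries ≥3 blanks, ≥3 QC replicates and
≥7 calibrators placed on a known quadratic instrument response; plate
assignment is stratified by group so batch effects do not confound group
contrasts.

Genotypes are drawn under Hardy-Weinberg equilibrium at the specified minor
allele frequencies. Linkage disequilibrium pairs are generated by explicit
haplotype pools: the four haplotype frequencies are solved exactly from the
two MAFs and the target D′ (coupling or repulsion phase), and each subject
draws two haplotypes. This yields the exact target D′ in expectation — in
particular, a repulsion-phase pair at D′ = 1 carries no double-minor
haplotype, reproducing the mutual-exclusivity pattern (no Het-Hm or Hm-Hm
genotype combinations) that motivates the LD module.

What the generator does *not* emulate: correlated metabolite panels
(metabolites are independent given the design), non-Gaussian biological
tails, genotyping error, population structure, or any relationship between
covariates and metabolite levels unless planted. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness to real-data pathologies.

## Preprocessing rules

* **Calibration.** Per plate and metabolite, a least-squares quadratic
  `signal = a + b·C + c·C²` fitted to the calibrator wells and inverted on
  the monotone branch covering the calibrated range. Fewer than three
  distinct calibrator concentrations trigger an identity fallback
  (uncalibrated relative mode), mirroring assays that lack external
  standards; relative comparisons remain valid because all downstream
  statistics are control-standardized.
* **Limit of detection.** `LOD = mean + 3.09 × SD` of the plate's blank
  signals — the parametric 99.9th percentile under normality (sample SD,
  ddof = 1). A metabolite is excluded when strictly more than half of its
  sample wells fall below their plate LOD ("majority" read strictly).
* **Plate normalization.** Two-pass, group-respecting: per-group means are
  estimated on pooled data and subtracted; within each plate the residuals
  are centred on their mean and rescaled by the pooled-to-plate residual SD
  ratio; group means are added back. Moment-based (mean/SD) alignment was
  chosen over median/MAD because it removes a pure plate offset exactly and
  is idempotent up to floating-point error on balanced designs; remote
  outliers that would distort moments are handled by the later Tukey stage.
  Plates with fewer than three samples are left unadjusted with a warning.
* **Box-Cox.** λ maximizes the profile Gaussian log-likelihood on [−3, 3];
  the transform is `(x^λ − 1)/λ`, `log x` at λ = 0. Values are shifted by
  `1 − min` when non-positive (shift recorded in the metadata). λ is
  profiled with group × plate cell means in the likelihood (Box-Cox
  regression), so genuine location differences do not masquerade as
  skewness. The chain order is Box-Cox → normalize: concentrations are
  approximately log-normal with multiplicative plate offsets, so
  transforming first makes the offsets additive on a near-Gaussian scale,
  where the plate normalization removes them exactly. Normalizing on the raw
  concentration scale instead biases λ̂ upward (additive adjustment of a
  log-normal yields a shifted log-normal) and measurably attenuates planted
  group effects; the recovery experiments in the test suite are sensitive to
  this.
* **Tukey fencing.** Values outside `[Q1 − 3·IQR, Q3 + 3·IQR]` are clamped
  to the nearer fence (winsorized, not removed, so n is preserved and the
  variance is not strongly reduced). Quartiles use linear interpolation of
  order statistics (type 7); the convention matters because the fences
  depend on it, so it is fixed and tested. The operation never changes rank
  order and is idempotent.
* **Standardization.** `z = (x − mean(controls))/SD(controls)` with sample
  SD, so regression coefficients read as shifts in control SDs.
* **Imputation.** Covariates: conditional mean given (group, sex), falling
  back to the group mean and then the grand mean for empty cells.
  Non-detected metabolite peaks: half of the smallest detected value.
* **Rare SNPs.** Retained only if the alternate allele is present in ≥5
  subjects; carriers are counted by default ("samples" read as subjects),
  with allele counting exposed as an option.
* **Levodopa indicators.** A PD subject is L+ when log-DOPA exceeds the
  parametric 95th percentile of controls (mean + 1.6449·SD); the flag is
  split into PD-D×L+ and PD-ND×L+ indicator covariates so the
  exposure-by-dementia interaction is estimable. Controls are never flagged.

## Group-heteroscedastic regression

`hetlm()` fits `y = Xβ + ε` with `SD(ε_i) = σ · m_g(i)` by full maximum
likelihood: weighted least squares given the per-group variances, group
variances from the weighted residuals, iterated until the log-likelihood is
stable (relative tolerance 1e-8, at most 200 iterations). The reference
group's multiplier is fixed at 1, and multipliers are reported as relative
residual SDs. ML (not REML) keeps nested log-likelihoods comparable; the
homoscedastic fit is a special case, so the heteroscedastic log-likelihood
always dominates it.

Inference uses Wald t statistics with `df = n − p` and a covariance matrix
on the unbiased residual-variance scale `n/(n − p)`. Two consequences: with
a single variance group the fit reproduces ordinary least squares exactly —
coefficients, standard errors and p-values — and the small-sample
anti-conservatism of pure-ML standard errors is removed (the differential
pipeline's null type-I rate is about 5.5% at α = 0.05; the uncorrected ML
scale gives about 7.6%). t rather than normal reference is a choice, not a
claim about the original analysis.

Differential analysis fits one model per metabolite with group indicators
(reference HC-CN), age, sex, education, BMI, the two levodopa indicators,
four comorbidity flags and log-transformed post-mortem interval and storage
(logs capture exponential time-related decay), with group-specific residual
variance. Merged contrasts (e.g. all demented subjects) are fitted by
recoding the group factor. FDR families are one per group contrast across
metabolites — the family structure of a heatmap column — because the family
boundaries are a convention, they are configurable. The significance
conventions are FDR ≤ 0.05 for metabolomic and q ≤ 0.10 for genomic
effects. Storey q-values use the smoother π₀ estimate (spline over λ =
0.05…0.95, evaluated at λ = 0.95, clamped to (0, 1]); with π₀ = 1 they
reduce exactly to Benjamini-Hochberg, and below 20 p-values the function
falls back to BH because π₀ cannot be estimated stably.

Collinearity gates: maximum absolute pairwise Pearson correlation and
adjusted GVIF (determinant-ratio formula, `GVIF^(1/(2·df))`). On the
package's own default synthetic design both gates pass the conventional
bounds (max |r| < 0.6, adjusted GVIF < 1.5), which the tests assert.

## SNP analysis

Subgroup scans use Wilcoxon-Mann-Whitney tests on allele counts (treating
0/1/2 as ordinal retains Het/Hm gradients that collapsing to carrier status
would discard). For combined n ≤ 16 the exact permutation distribution is
enumerated; otherwise a tie- and continuity-corrected normal approximation
is used. The approximation's agreement with the exact branch (within 0.02)
holds for tie-free data; with heavily tied genotype vectors no normal
approximation achieves that bound, which is why small tied samples are
routed to the exact branch.

Inheritance-model selection fits the response on dominant (`g ≥ 1`),
recessive (`g = 2`) and additive (`g`) codings, each adjusted for sex, age,
log post-mortem interval and log storage, and selects minimum BIC. All three
codings spend one parameter, so the BIC comparison reduces to a likelihood
comparison — this is documented and tested. Ties prefer additive (the
conventional default), then dominant; the recessive model is dropped when no
homozygote is present; acutely levodopa-exposed samples are excluded from
Hcy/betaine association because the exposure perturbs both compounds.

Two-locus LD uses EM over the double-heterozygote phase ambiguity
(convergence when the largest frequency change is below 1e-10); with no
double heterozygotes EM equals direct haplotype counting. D′ is reported as
the Lewontin magnitude |D|/Dmax with the phase sign carried separately; the
significance test is χ² = 2N·r² on 1 df (the standard composite test — the
choice of test is a convention and exposed as such).

## Composite scores

Risk sets are derived from the association step, never hard-coded: SNPs
q ≤ 0.10 associated with higher Hcy or lower betaine are risk; the converse
directions protection; vitamins FDR ≤ 0.05 negatively associated with Hcy or
positively with betaine enter the vitamin set. A SNP significant for both
responses in a consistent direction counts once; conflicting directions drop
it with a warning. Scores count met criteria under each SNP's chosen model
(additive SNPs count carriers by default; allele counting is an option), and
the vitamin score counts panel members below z = −1.6449 (the parametric
control 5th percentile, displayed as −1.64). Missing genotypes rescale the
score over the observed set members, so missingness does not deflate the
burden — with complete genotypes scores are integers bounded by the set
sizes. Group comparisons report Δ% against the control mean with two-sided
WMW p-values; a zero control mean switches to an absolute difference with a
flag.

## The genetic-programming classifier

Operands are Boolean threshold tests — metabolite z ≥ t for t ∈
{−2, −1, 0, 1, 2} control SDs, allele count g ≥ t for t ∈ {0, 1, 2} — plus
numeric allele-count operands. Operators are NOT/OR/AND and
ADD/SUB/MUL/NEG. Typing is total: Booleans evaluate as 0/1, numerics
coerce to Boolean via "> 0", and the root is coerced to the class label.
The comparator direction (≥) is a fixed convention recorded in the
serialized trees.

Fitness is the mean of the two per-class accuracies minus 0.05 per operand
— parsimony pressure is exact and linear, so adding a prediction-neutral
operand costs exactly 0.05. During evolution a uniform noise term on
[0, amp] perturbs fitness at selection only, with amp decreasing linearly
from 0.10 to 0 over the first half of the generations (simulated-annealing
style); reported fitness is always noise-free. Selection is tournament
(size 4) with offspring produced by crossover (0.6), subtree mutation (0.3)
and fresh random individuals (0.1); one elite is copied per generation;
tree depth is capped at 6 to bound evaluation cost (the penalty already
discourages size). The full-scale budget is population 100,000 × 100
generations × best of 10 runs; the package's scaled-down preset
(2,000 × 20 × 3) preserves the dynamics at test-friendly cost, and the
recovery experiments in the test suite use 5,000 × 30 × 5. Cross-validation
is stratified k-fold with evolution repeated per fold.

All stochastic components run off a single integer seed; the same seed
reproduces the same best tree.

## Numerical and degenerate-input conventions

Zero control SD, all-missing metabolites, monomorphic loci in LD, empty
comparison groups and rank-deficient designs raise explicit errors; constant
covariates are dropped from designs; a constant response makes all
inheritance codings equivalent and the tie rule returns additive. IGLS
non-convergence is flagged on the fit rather than raised. The Box-Cox shift,
quartile convention, LODs, λ and winsorization counts are all recorded in
the processed-matrix metadata.

## Problem sizes used by the checks

The test-suite and acceptance-script workloads were sized as the smallest
replicate counts at which the monte-carlo bounds are stable: 50 pipeline
replicates at n = 136 for effect recovery, 50 × n = 2000 for the variance
multiplier, 100 seeds for Box-Cox and model selection, 100 null seeds for
type-I calibration, and 5–10 seeds at population 5,000 × 30 generations ×
5 runs for GP rule recovery.

## Known limitations

The heteroscedastic model assumes independent Gaussian errors within group;
no random effects or survival outcomes are supported. LD handling is
two-locus only, with no phasing beyond the EM resolution and no
population-structure correction (single-ancestry cohorts). GP fitness is
strictly two-class. The synthetic generator's independence assumptions mean
calibration results speak to the estimators, not to correlated real-world
panels.
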