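# onecarbon

Association analysis of B-vitamin-related compounds and one-carbon-metabolism
genetics in post-mortem brain cohorts — as a fully synthetic, testable R
pipeline.

## The problem

Elevated homocysteine (Hcy) and depleted methyl-donor pools are implicated in
dementia, both in Alzheimer's disease (AD-D) and in Parkinson's disease with
dementia (PD-D). Studying this in brain tissue means analysing targeted
LC-MS/MS panels of B-vitamin actives (PLP, THF, MTHF, methylcobalamin,
thiamine phosphates, pantothenate, biotin, ...) together with genotypes of
one-carbon-metabolism genes (MTHFR, MTR, MTRR, TYMS, BHMT, ...), across
case-control groups with unequal variability, plate batch effects, acute
levodopa exposure in PD, and post-mortem tissue covariates.

`onecarbon` implements that entire analysis chain for methodologists and
metabolomics analysts:

* **Synthetic cohorts** — subject tables, raw assay plates (blanks, QC,
  calibrators, planted group effects in control-SD units, plate offsets),
  genotypes with Hardy-Weinberg sampling and exact haplotype-pool linkage
  disequilibrium (LD), and planted classification rules. Every downstream
  stage is testable without any data download.
* **Preprocessing** — quadratic calibration with identity fallback; limits of
  detection from blanks, `LOD = mean + 3.09 × SD` (the parametric 99.9th
  percentile); exclusion of metabolites in the majority below LOD;
  group-respecting plate normalization; Box-Cox transformation by profile
  likelihood; Tukey fencing (k = 3, winsorized); standardization to the
  control distribution; conditional-mean and half-minimum imputation;
  rare-SNP filtering; levodopa-exposure indicators from tissue DOPA.
* **Heteroscedastic regression** — `hetlm()` fits y = Xβ + ε with
  SD(ε) = σ·m(group) by full maximum likelihood (iterated GLS), the
  multiplier of the reference group fixed at 1. Standardization makes each β
  a shift in control SDs. Collinearity gates (max Pearson |r|, adjusted
  GVIF), Benjamini-Hochberg FDR and Storey q-values included.
* **SNP analysis** — Wilcoxon-Mann-Whitney subgroup scans (exact permutation
  for small samples), dominant/recessive/additive inheritance-model selection
  by BIC, and two-locus LD statistics (EM haplotype frequencies, D, D′, r,
  χ²) from unphased genotypes.
* **Composite scores** — SNP risk, SNP protection and B-vitamin risk counts
  from the significant directional associations with Hcy/betaine, compared
  per group against controls as Δ% with WMW p-values.
* **Combinatorial classification** — a genetic-programming expression-tree
  classifier over metabolite-threshold and allele-count operands, with a
  5-percentage-point parsimony penalty per operand, annealed selection noise,
  best-of-runs selection, and stratified k-fold cross-validation.

## Worked example

```r
library(onecarbon)

subjects <- generate_subjects(cohort_config(seed = 7))
assay <- generate_raw_assay(subjects,
                            list(effect_spec("biotin", "AD-D", -0.73)),
                            seed = 7)
pm <- preprocess_assay(assay, subjects)
diff <- run_differential(pm, subjects)
subset(diff, response == "biotin")
```

```
   response   term        beta        se          p       fdr
9    biotin   AD-D -0.58890483 0.2632751 0.02715931 0.2987524
10   biotin  PD-CN  0.07425221 0.3621961 0.83791802 0.9907592
11   biotin   PD-D -0.15283126 0.3726679 0.68246963 0.7959116
12   biotin PD-MCI  0.11832710 0.3821531 0.75738183 0.8331200
```

The planted −0.73 control-SD deficit in AD-D biotin is recovered as
β = −0.59 ± 0.26 in this single cohort (one draw at n = 136; across 100
replicates the mean estimate is within 0.01 SD of the planted value), while
the unplanted PD contrasts stay at noise level. The `fdr` column is the
Benjamini-Hochberg adjustment across the metabolite panel within each group
contrast.

The whole chain, including SNP association, composite scores and the GP
classifier, runs as one reproducible pipeline:

```r
run_dir <- run_pipeline(default_run_config(seed = 1))
write_report(run_dir)
```

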