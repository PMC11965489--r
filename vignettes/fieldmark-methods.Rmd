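---
title: "Methods: epigenetic field-defect signatures in fieldmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic field-defect signatures in fieldmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fieldmark implements a family of DNA-methylation biomarkers of *field
cancerization*: the idea that a carcinogenic exposure reprograms not only
the organ at risk but also distant, easily sampled "surrogate" tissues, so
that methylation read-outs in cervix, oviduct or blood can report on
mammary-gland cancer risk. The package covers four biomarkers — a
pan-tissue carcinogen-exposure signature, reference-based cell-type
composition, a mitotic clock, and methylation at progesterone-receptor
binding sites (PRBS) — together with the upstream quality control, the
cross-platform harmonization needed to build reference panels, tumor-free
survival analysis of biomarker strata, and a synthetic-data generator that
makes the entire pipeline testable without any external download.

All computations operate on beta values: per-CpG methylation fractions in
$[0,1]$, arranged as a CpG $\times$ sample matrix. Sample metadata, score
tables, fraction estimates and survival summaries are tibbles, so the
user-facing surface composes with dplyr/tidyr; Cox fits have
`tidy()`/`glance()` methods and result objects have `autoplot()` methods.

## Quality control

`apply_failure_cascade()` implements the standard array QC sequence. A
measurement is *failed* when its detection p-value exceeds
`detection_p_max` (default 0.01); failed betas become missing. Removal
then proceeds in a fixed order: samples whose failed fraction exceeds 10%
are dropped first, then probes whose failed fraction — recomputed over the
*retained* samples — exceeds 10%. The order matters only in edge cases,
but fixing it (samples before probes, probe fractions recomputed) makes
the cascade deterministic and idempotent, and both properties are tested.
All three thresholds are strict inequalities: a sample at exactly a 10%
failure rate, or a median log2 intensity of exactly 9.5 in
`filter_low_intensity_samples()`, is retained. Intensities are interpreted
on the log2 scale, the customary scale on which 9.5 is a meaningful array
cutoff.

`pc_covariate_check()` guards against technical confounding: the 1000
most variable probes (sample standard deviation, $n-1$ denominator, ties
broken by CpG id for determinism) enter a PCA, and each of the top 10
components is tested against each covariate — Pearson's correlation test
for numeric covariates, Kruskal-Wallis for categorical ones. P-values are
reported raw: the table is an inspection device, not an inference, so no
multiplicity correction is applied. Constant covariates are skipped with
a warning.

## Cross-platform harmonization

Reference methylomes come from a mix of arrays, WGBS and RRBS. Sequencing
betas are read proportions and therefore mode at exactly 0 and 1, while
array betas mode at interior values (0.017 and 0.955 on this array family)
because background intensity pulls both tails inward.
`estimate_beta_modes()` locates the two modes by kernel density
estimation, taking the highest density maximum on each side of 0.5 and
erring on unimodal input. `derive_mode_matching_transform()` then solves
the unique line through the two mode pairs,

$$\beta_{\text{adj}} = \frac{t_{hi}-t_{lo}}{s_{hi}-s_{lo}}\,\beta
  + t_{lo} - \text{slope}\cdot s_{lo},$$

which for sequencing modes $(0,1)$ and array modes $(0.017, 0.955)$ gives
$\beta_{\text{adj}} = 0.938\,\beta + 0.017$. Applying it
(`harmonize_sequencing_betas()`) preserves the ordering of beta values
(positive slope) and maps the source modes onto the target modes exactly;
output is clamped to $[0,1]$, a no-op for this transform but a guard for
user-supplied lines. `filter_cross_platform_cpgs()` restricts analysis to
CpGs present on the array, covered in every RRBS dataset (RRBS covers only
~8% of array CpGs), and missing in at most 10% of samples overall.

## Reference panels and deconvolution

Markers for a cell type are CpGs that separate it from everything else.
`rank_markers()` computes, per CpG, the mean-beta difference between the
target type and all other samples and a two-sided Wilcoxon rank-sum
p-value (exact when the smaller group has $\le 8$ samples and there are no
ties, normal approximation with tie and continuity corrections otherwise).
CpGs are ranked by descending $|\Delta\beta|$ and ascending $p$ with
average ranks for ties; the two rankings are combined by their geometric
mean, and the lowest combined ranks are selected, ties broken by larger
$|\Delta\beta|$ then CpG id. `build_panel()` unions the per-type
selections (so a panel can hold fewer than types $\times$ `n_top_per_type`
rows when selections overlap) and fills each entry with the type's mean
beta at that CpG. Default panel sizes are 100 markers per type for the
primary (epithelial / fibroblast / fat / immune) and epithelial-subtype
panels and 50 for immune subtypes; all are parameters, and the panel
accepts any labeled sample collection and type list — including an
immune panel with or without an MDSC column, which is why no type list is
hard-coded.

`deconvolve()` estimates composition by constrained projection: each
sample's betas at the panel CpGs are regressed onto the panel columns by
non-negative least squares and the coefficients renormalized to sum to 1.
We chose this contract because it is exactly testable — mixture recovery
on simulated data has a ground truth — whereas robust-regression variants
differ only in their outlier behavior. Fractions below $10^{-6}$ are
snapped to zero and the vector renormalized, so downstream ratios are not
driven by numerical dust. Samples must cover at least 80% of the panel
CpGs (configurable); rank-deficient panels (collinear columns) are
rejected. `hierarchical_deconvolve()` splits one parent type: subtype
fractions estimated against a subtype panel are rescaled to sum to the
parent's primary-panel fraction, so the expanded vector still sums to 1.
The luminal-progenitor proportion reported for mammary gland is the
`"luminal_progenitor"` column of the hierarchical fit with parent
`"epithelial"`; the blood summary is the granulocyte/lymphocyte ratio,
with class membership configurable (default granulocytes = neutrophil +
MDSC when present; lymphocytes = B, NK, CD4 T, CD8 T).

## The carcinogen signature

Within each tissue of a discovery cohort, `rank_tissue_cpgs()` ranks CpGs
by the signed difference in mean beta between exposed and unexposed
samples — descending for the hyper ranking, ascending for the hypo
ranking. Keeping two signed rankings per tissue (rather than one
$|\Delta\beta|$ ranking split afterwards) is the only reading under which
separate "top hyper-methylated" and "top hypo-methylated" pan-tissue
lists are well defined, so that is the implemented and documented
contract. `combine_rankings_geometric()` aggregates each ranking across
tissues by the per-CpG geometric mean of ranks, re-ranked ascending — a
rank-aggregation scheme that rewards consistency across tissues over a
single extreme tissue. The top $k = 1000$ CpGs of each combined ranking
form the signature. The two sets can in principle intersect after
combination; the fixed resolution is to remove shared CpGs from both and
refill each from the next ranks until disjoint, which the constructor
logs. Tumor samples are excluded before ranking: the signature is meant
to capture systemic field effects in normal tissue, not tumor biology.

The raw score of a sample is
$\overline{\beta}_{\text{hyper}} - \overline{\beta}_{\text{hypo}}$;
scaled scores subtract the mean and divide by the sample standard
deviation ($n-1$) of the raw scores of healthy mammary-gland discovery
samples. A new cohort is always scored with the stored discovery scaling
— no re-fitting — so scores are comparable across cohorts. Scoring
requires 80% coverage of the signature CpGs (configurable floor).

## Mitotic clock and PRBS score

Both are flat CpG sets scored by their mean beta
(`score_cpg_set()`), which is guaranteed to lie in $[0,1]$.
`select_mitotic_clock_cpgs()` builds the clock set: human polycomb-group
target genes are mapped to mouse homologs through a user-supplied map,
CpGs within 200 bp of any mapped gene's TSS are collected (inclusive on
both ends), and the set is restricted to CpGs with mean methylation below
10% in every listed fetal tissue — CpGs that start life unmethylated and
accumulate methylation with cell division, making their mean a replicative
age proxy. The homolog map, TSS table and fetal reference are inputs, not
embedded resources: the counts obtained with the real annotations (about
1200 genes and 1400 clock CpGs) are reproducible only with those files.
`select_prbs_cpgs()` intersects the CpG annotation with ChIP-seq peak
intervals, interpreting BED as 0-based half-open and CpG positions as
1-based: a position $p$ overlaps $[\text{start}, \text{end})$ exactly when
$\text{start} < p \le \text{end}$, and the boundary case is tested
explicitly against a nested-loop oracle.

## Survival analysis

Records carry time (days from pellet implantation) and an event flag
(1 = tumor first measured; sacrifice without a measured tumor, including
tumors found only at necropsy, is censored by caller contract).
`km_estimate()` is the product-limit estimator; `median_split()` labels
subjects above the median score "high" and everything else — including
ties at the median — "low", a deterministic, conservative convention;
`cox_single()` fits a single-covariate proportional-hazards model with the
Efron approximation for ties (tied event times are common in small rodent
cohorts with interval follow-up) and reports the Wald 95% CI
$\exp(\hat\beta \pm 1.96\,\text{SE})$; `logrank_test()` gives the 1-df
observed-minus-expected test. Monotone partial likelihood (complete
separation) is flagged on the fit rather than silently reported. These
standard estimators are delegated to the survival package behind the
package's interfaces; the package's own tests verify the Cox coefficient
against a brute-force partial-likelihood maximization and the log-rank
level against label permutation.

## The synthetic-data generator

`scenario_config()` fixes the simulated study design; its defaults are
the conditions the rest of the package is tested under:

* nine normal tissues (mammary gland, cervix, oviduct, blood, adipose,
  kidney, liver, lung, spleen) sampled from each mouse; 9 mice per
  exposure group, mirroring a 9 vs 9 discovery design;
* a bimodal CpG background with array modes at 0.017/0.955; planted
  exposure effects of 0.2 beta units at 1500 hyper and 1500 hypo CpGs
  (hyper effects planted at unmethylated CpGs and hypo at methylated
  ones, so shifts are not clipped by the unit interval), consistent
  across tissues; truncated Gaussian measurement noise with SD 0.01 on
  the beta scale, applied after the mean structure and clamped to
  $[0,1]$ — noise lives on the beta scale because every downstream
  statistic does;
* an optional intervention arm that attenuates the planted exposure
  effect by 50% — a free parameter chosen once to emulate a partially
  protective intervention, not an estimate;
* exponential tumor latencies with hazard
  $h_0 \exp(\gamma \cdot \text{score})$, $h_0 = 0.02$/day and
  $\gamma = 1.1$, administratively censored at 161 days (23 weeks);
* sequencing platforms modeled as per-CpG binomial read sampling
  (default depth 30), which produces exact atoms at 0 and 1; RRBS covers
  a configurable 8% of CpGs; cell-type mixtures drawn from a
  Dirichlet (concentration 1) with the true fractions always returned.

The per-CpG exposure effect size is a free parameter of the simulation:
the real per-CpG effect sizes are unknown, so 0.2 at SD 0.01 was fixed
once as a clearly detectable but not degenerate planted signal. A single
scenario seed fans out to fixed per-stage child seeds, so each stage is
independently reproducible and identical seeds give byte-identical
output.

What the generator does *not* emulate — probe chemistry, bisulfite
conversion error, spatially correlated methylation, batch structure,
realistic tissue-specific methylome differences beyond small random
offsets — bounds what passing tests show: they validate the pipeline's
algebra, determinism and statistical calibration, not its behavior on
real arrays.

## Numerical choices and problem sizes

Mode finding uses a kernel density on a grid extending slightly beyond
$[0,1]$ so boundary atoms register as maxima. Rank ties always use
average ranks. Geometric means of ranks are computed in log space. The
signature scaling requires at least two healthy anchor samples with
nonzero score variance and errors otherwise. Deconvolution tolerances
(fraction snap $10^{-6}$, renormalization to 1 within $10^{-9}$) are
fixed, not tuned.

The test suite exercises the pipeline at reduced but structurally
faithful sizes, chosen once as the smallest scales at which each
property is meaningful: signature construction at 10,000 CpGs over the
full nine-tissue design; type-I-error suites at 2,000 CpGs and three
tissues over 200 replicate seeds with out-of-sample scoring (scoring the
discovery set itself would be biased by CpG selection even under the
null); Cox recovery at $n = 200$ subjects over 100 seeds; deconvolution
recovery with four cell types and 50 Dirichlet mixtures at noise SD 0.02.

## Known limitations

The deconvolution is plain non-negative least squares: no robust
weighting, no partial-correlation mode. The Cox module is deliberately
single-covariate (the analysis it supports compares median-split strata);
there is no multivariable adjustment, diagnostics, or competing-risk
handling. QC intensity filtering expects precomputed median intensities
rather than raw array files, and normalization (background/dye correction,
BMIQ) is upstream of this package: it consumes normalized betas.
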