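---
title: "QC and standardisation of aptamer proteomics of synovial fluid: methods"
author: "somaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC and standardisation of aptamer proteomics of synovial fluid: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaqc)
```

## The problem

Aptamer panels report relative fluorescence units (RFU) per SOMAmer
reagent per well. When the matrix is synovial fluid (SF) rather than the
plasma the platform was tuned for, three families of nuisance variation
dominate:

1. **Assay-level effects** — well-to-well hybridisation efficiency,
   between-plate intensity, and per-(plate, SOMAmer) calibration drift.
2. **A processing-batch artefact** — a "bimodal" state in which a large
   subset of SOMAmers flips between a high and a low intensity regime
   depending on the laboratory processing batch.
3. **Intracellular contamination** — a per-sample burden of intracellular
   protein (cell lysis at aspiration, incomplete centrifugation,
   microvesicles) that can dominate the leading principal component and
   swamp subtler biology.

`somaqc` implements the corresponding pipeline:
standardise → log → detect/correct the bimodal and plate effects →
(optionally) adjust for the intracellular protein score → filter.
Co-primary outputs with and without the IPS adjustment are produced,
because the intracellular signal may itself carry biology and adjusting
for it is not obviously right; keeping both branches defers that decision
to downstream analyses.

## Standardisation

All standardisation acts on **linear** RFU; the exact estimators are
medians of ratios:

* *Hybridisation normalisation.* For each plate, the reference for
  hybridisation control $h$ is $r_h$, the median of its RFU across the
  plate's wells. Each well $w$ is rescaled by
  $s_w = \mathrm{median}_h\, (r_h / \mathrm{RFU}_{wh})$. After the
  operation the per-well median of those ratios is exactly 1.
* *Plate scaling.* With calibrator reference $\mathrm{ref}_p$ and plate
  calibrator median $m_{qp}$, each plate is rescaled by
  $SF_q = \mathrm{median}_p\,(\mathrm{ref}_p / m_{qp})$ — one factor per
  plate (a per-dilution-bin variant was considered and not needed for a
  single-run design).
* *Calibration.* Per plate and SOMAmer,
  $cal_{qp} = \mathrm{ref}_p / m_{qp}$, which forces every plate's
  calibrator median onto the reference exactly. References come from the
  annotation when supplied; otherwise the across-plate median of plate
  calibrator medians serves as a single-run self-reference.
* *Median signal normalisation* (per sample within dilution bin, within
  sample-role groups) is implemented but **off by default**: on SF,
  between-sample total-signal differences carry real biology (notably the
  intracellular burden), and rescaling samples to a common median profile
  demonstrably moves the data away from the generating truth in the
  synthetic benchmark. A config flag re-enables it for comparison runs.

The log transform is natural-log by default (configurable); all linear
factors are returned, strictly positive, and re-applying them to the raw
data reproduces the standardised data exactly.

## Repeatability metrics

%CV is `100 * sd / mean` (sample SD) over pooled replicate wells on linear
standardised RFU, the platform convention. The non-technical variance
fraction uses $V_{pooled}/V_{total}$ computed on log values, with
$V_{total}$ taken over the individual (non-pooled) study samples. Two
algebraic forms of the estimator circulate in the field's reports:
$R^2 = 1 - (V_p/V_t)^2$ and $R^2 = (1 - V_p/V_t)^2$. Both are implemented;
`nontechnical_r2()` defaults to the former, while the filter battery uses
the latter — the form given where the filter itself is defined — which is
also markedly more robust at realistic replicate counts: with 22 pooled
replicates the chi-square noise of $V_p$ gives a purely-technical SOMAmer
(true ratio near 1) a ~16% chance per group of slipping below the removal
boundary under the first form, versus under 0.1% for the second. The form
used is recorded in the filter report.

## The intracellular protein score

From $n$ paired aliquots of the same SF split at collection — one
centrifuged ("spun"), one not — the per-SOMAmer weight is the paired
Cohen's d of the log difference,
$d_p = \overline{\Delta}_p / s_{\Delta_p}$ with
$\Delta_{jp} = \log C^{unspun}_{jp} - \log C^{spun}_{jp}$
(the paired $d_z$ form; a pooled-SD variant is available). SOMAmers with
zero-variance differences are excluded rather than capped, avoiding
infinite weights. A sample's score is $IPS_i = \sum_p d_p C_{ip}$, so
higher scores mean more intracellular signal. Weights are estimated once
on the paired subset and frozen; scoring never re-estimates.

Adjustment is per-SOMAmer ordinary least squares on the centred score
(intercept included, one simple regression per SOMAmer): each value is
replaced by its residual plus the SOMAmer's mean, which zeroes the sample
covariance with the score exactly while preserving means. The same
machinery (`covariate_adjust()`) handles arbitrary continuous covariates
jointly.

In the pipeline the score is computed on the **batch-corrected** data: the
bimodal artefact would otherwise leak into the score through the affected
SOMAmers' weights.

## Bimodal detection and batch correction

PCA (centred, unscaled — unscaled because the artefact and the
intracellular signal live on the raw log scale, and scaling would dilute
them) is fitted on study and pooled wells only; calibrators, plasma QC and
blanks describe a different fluid. A one-dimensional two-component
Gaussian mixture with distinct variances and free mixing weight is fitted
to PC2 by EM: means initialised at the 25th/75th percentiles, four seeded
random restarts, best likelihood kept, convergence at a log-likelihood
change below 1e-8 or 500 iterations. Assignment is by maximum posterior;
exact ties go to the lower-mean component and are flagged.

Before correcting, the two-component fit is compared with a single
Gaussian by BIC. If one component wins, `correct_bimodal_and_plate()`
skips the status pass: an assignment on unimodal scores merely splits a
continuum, and "correcting" it would strip genuine variance along that
axis. (At the design's scale — more samples than SOMAmers — null PC2
score distributions are close to Gaussian and the check behaves; in
small-sample regimes where n is far below the SOMAmer count, bulk
eigenvector scores are platykurtic and any unimodality test is
unreliable.)

ComBat is implemented from first principles in its standard parametric
empirical-Bayes form: per-SOMAmer standardisation around the
batch-size-weighted grand mean and pooled variance (covariates, when
protected, retained in the standardisation), normal/inverse-gamma priors
across SOMAmers fitted by the method of moments, shrunken location/scale
$(\gamma^*, \delta^*)$ by the usual iterative conditional updates
(tolerance 1e-4), then back-transformation. The test suite pins the
implementation elementwise (max |diff| ≈ 1e-14) against `sva::ComBat`
over randomised fixtures, with and without a protected covariate. Two
properties worth stating precisely: the grand mean is preserved exactly
only in the no-shrinkage limit (the suite checks |γ*−γ̂| < 1e-3 at 10⁴
samples per batch); and under a *homogeneous* batch effect (identical for
every SOMAmer) the prior absorbs the common component into its mean, so
per-SOMAmer residual differences equal to the estimation noise remain —
this is the intended empirical-Bayes behaviour, not a defect, and the
reference implementation does the same.

"Correcting status and plate at the same time" is implemented as two
sequential ComBat passes (status, then plate) since ComBat takes a single
batch factor; an interaction-batch mode (status × plate) is available.

## Filters

SOMAmer filters run before sample filters:

1. control reagents: non-human organism or type in {spuriomer,
   hybridisation control elution, deprecated, non-biotin, non-cleavable};
2. confounder association: per-SOMAmer simple OLS slope tests against
   each pre-specified confounder (sample age and freeze-thaw count by
   default), Bonferroni-adjusted across SOMAmers within confounder,
   removed at adjusted p < 0.05;
3. repeatability: removed if R² < 0.5 in *either* pooled group (strict
   inequality).

Sample filters (study and pooled wells only; control wells exempt):
vendor QC flag; more than 25% of protein values outside the limits of
detection (lower LOD = blank median + 4.9 × unscaled MAD from the plate's
three blanks, upper LOD 80,000 RFU; LOD and total-RFU on the linear
standardised scale); total RFU beyond 5 SD of the study-sample
distribution; and finally PC-space outliers — beyond 5 SD on any of the
top PCs covering 80% of variance, with the PCA refitted after the earlier
removals (a radial variant is available). Boundary conventions are strict
throughout. The ordered `filter_report` records parameters, removed IDs
and survivor counts per step.

## The synthetic study design

`synth_config()` defaults encode the design the pipeline targets: a
single run of 22 sequential 96-well plates, each carrying 83 participant
SF wells, one pooled-OA and one pooled-injury replicate, five plasma
calibrators, three plasma QC wells and three blanks; 18 spun/unspun pairs
for the IPS weights (generate the paired set with the *same seed* so both
datasets share one SOMAmer universe). Log-scale RFU is assembled as
baseline + intracellular term + bimodal term + plate + well + covariate
effects + biological and replicate noise; one master seed drives
fixed-offset sub-streams per effect, so switching one effect off leaves
every other draw unchanged (enabling ablation tests).

Defaults, with units and the reasoning behind them:

* 400 human protein SOMAmers (+6 hybridisation controls, +12 control
  reagents) — a desk-scale stand-in for the full panel that keeps the
  suite fast while leaving all rank conditions (n samples > n SOMAmers)
  as in the real design;
* baseline log-RFU ~ N(log 2000, 0.9) — the dilution-bin system
  compresses measured RFU to a few decades regardless of true abundance;
* intracellular score u ~ LogNormal(0, 0.4) with loadings decreasing in
  abundance (logistic in abundance rank, scale 0.8 log units) — yields a
  dominant PC1 (≈50–60% of variance) most correlated with low-abundance
  SOMAmers, and a right tail of genuinely extreme samples;
* bimodal artefact: 35% of SOMAmers, 0.8 log-unit high/low gap with
  random per-SOMAmer sign, status flipping between processing batches
  (2 plates per batch, flip probability 0.5) — puts the artefact
  unambiguously on PC2 (≈7% of variance) above the planted failure
  directions;
* plate factors ~ N(0, 0.1), per-(plate, SOMAmer) calibration residuals
  ~ N(0, 0.12), well factors ~ N(0, 0.15) plus a 0.1 column gradient —
  scanner-level effects large enough that each standardisation step has a
  decisively positive variance budget (well factors of ±15% sit inside
  vendor-accepted hybridisation ranges);
* biological noise 0.3 and replicate noise 0.1 (log units); pooled wells
  are replicates of fixed mixtures (no biological noise);
* planted failures sized to be unambiguous under the filter definitions:
  10 LOD-failing samples (35% of protein values one log unit below the
  blank floor), 5 PC outliers (±2 log units along a random direction over
  the lower-abundance half, leaving totals untouched), 3 total-RFU
  outliers (×8 well overload — large in total signal yet under the 25%
  out-of-detection-range rule), 2 vendor flags; 30 low-repeatability
  SOMAmers (replicate noise ×5, no biological loading), 30 + 20
  age/freeze-thaw-associated SOMAmers (slopes 0.065 per year and 0.15 per
  cycle), 10 blood-linked SOMAmers plus an HBA analyte (0.8 log per
  visual-staining grade step).

What the generator does *not* emulate: real protein biology and
cross-reactivity, disease effects beyond group labels, vendor-specific
normalisation metadata, and inter-run (multi-batch) calibration. Passing
tests therefore demonstrate that each stage recovers the structure it is
defined against, not that the pipeline is optimal for any particular real
cohort.

Because the intracellular factor is log-normal, a real 22-plate-scale run
contains genuine >5 SD samples in both the total-RFU and PC-score
distributions. The filter battery removes them alongside the planted
failures; in truth-scored runs this appears as a handful of "false"
positives (specificity ≈ 0.99 rather than 1.0) and is the correct reading
of the 5 SD rules, not an error. Pooled-replicate %CV on the synthetic
design sits near 25–38% — above the 11–16% a real run shows — because the
planted bimodal artefact (which the standardisation stage, measured by
%CV, is not meant to remove) contributes replicate variance until ComBat
runs.

## Numerical choices and degenerate inputs

Tolerances: calibration fixed points hold to 1e-9 relative; IPS
residualisation zeroes covariances to 1e-10; ComBat conditional updates
converge at 1e-4 (matching the reference); EM at 1e-8. PCA uses the SVD
with a deterministic sign convention (largest-magnitude loading element
positive), making results platform-stable. Degenerate inputs error
informatively: zero hybridisation controls or calibrator medians, plates
with fewer than three blanks, constant IPS, singleton batches, constant
matrices in PCA, non-positive values under the log. The GMM flags an
all-equal input as non-converged with posteriors 0.5 rather than fitting.

## Known limitations

* Sequential (status, then plate) ComBat is an approximation to a joint
  correction; the interaction mode trades that for smaller batches.
* The BIC bimodality check is a guard, not a test of record, and is
  unreliable when samples are far fewer than SOMAmers.
* The PC-outlier rule is per-component (the radial rule is available);
  with hundreds of retained components a few tail removals per thousand
  samples are expected by chance.
* LOD semantics assume blank wells receive the same well/plate factors as
  study wells, which the standardisation guarantees internally but which
  must hold for imported data too.
* `umap_embed()` is visualisation-only and delegated to an external
  implementation; no quantitative contract depends on it.

## Problem sizes used in the test suite

Unit tests run on constructed micro-fixtures and 2–4-plate synthetic
datasets; the end-to-end checks use one 22-plate dataset (2112 wells ×
418 SOMAmers) with its 18-pair companion, which keeps the complete suite
within a couple of minutes on a single core while exercising the same
n > p regime as the full design.
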