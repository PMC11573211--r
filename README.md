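# somaqc

Quality control and standardisation for aptamer-based (SomaScan-style)
proteomics of synovial fluid (SF).

Synovial fluid is a non-standard matrix on aptamer platforms: plate- and
well-level technical variation, a processing-batch "bimodal" intensity
artefact, and a large, sample-specific contribution of intracellular
proteins (from cell lysis, residual cells, or microvesicles) all sit on top
of the biology of interest. `somaqc` implements an end-to-end, auditable QC
pipeline for such data, aimed at analysts preparing multi-plate SomaScan
runs of SF (or similar fluids) for downstream discovery work:

* **ADAT-style I/O** — a tab-delimited container for the RFU matrix
  (samples x SOMAmers) with SOMAmer and sample annotation blocks, a
  transform provenance log, and a configurable field-name alias table.
* **Standardisation** on linear RFU — hybridisation-control normalisation
  (per-well scale `s_w = median_h(r_h / RFU_wh)` against per-plate
  references `r_h`), plate scaling from plasma calibrators
  (`SF_q = median_p(ref_p / m_qp)`), and per-SOMAmer plate calibration
  (`cal_qp = ref_p / m_qp`). Median signal normalisation is implemented but
  excluded from the default pipeline: on SF it strips genuine
  between-sample signal (it is available for comparison runs).
* **Repeatability metrics** — per-SOMAmer %CV (`100·sd/mean`) of pooled
  replicate wells and the non-technical variance fraction R² from
  `V_pooled / V_total`, in both published forms
  (`1 − (V_p/V_t)²` and `(1 − V_p/V_t)²`).
* **Intracellular Protein Score (IPS)** — per-sample
  `IPS_i = Σ_p d_p · C_ip`, where `C_ip` is the log concentration and `d_p`
  the paired Cohen's d (d_z) of the unspun-minus-spun log difference across
  paired SF aliquots; linear-model adjustment residualises every SOMAmer on
  the centred score.
* **Bimodal batch detection and ComBat** — a two-component Gaussian
  mixture (EM, quantile initialisation, seeded restarts, BIC check against
  a single Gaussian) classifies samples into high/low status on PC2, and a
  from-scratch parametric empirical-Bayes ComBat removes status and plate
  effects (location and scale) — verified elementwise against
  `sva::ComBat`.
* **Filter battery** — SOMAmer filters (control/non-human reagents,
  Bonferroni-adjusted confounder association, R² < 50% in either pooled
  group) and sample filters (vendor QC flag, >25% of values outside the
  limits of detection, 5 SD total-RFU outliers, 5 SD PC-space outliers),
  with per-plate lower LOD `median(blanks) + 4.9 · MAD(blanks)` (unscaled
  MAD, three blanks per plate) and an 80,000 RFU upper LOD, all recorded in
  an ordered `filter_report`.
* **Synthetic data generator** — multi-plate datasets with the full plate
  design (83 study wells, pooled OA and injury replicates, 5 calibrators,
  3 plasma QC, 3 blanks per 96-well plate) and planted intracellular,
  bimodal, plate, well, blood, sample-age, freeze-thaw and bad-sample/
  bad-SOMAmer structure, plus a ground-truth record, so every stage is
  testable without access to consortium data.

## Worked example

```r
library(somaqc)

g      <- generate_dataset(synth_config(seed = 1))          # 22 plates
paired <- generate_paired_spun_unspun(synth_config(seed = 1), 18)

res <- run_pipeline(pipeline_config(g$dataset, paired$dataset))
print(res)
#> pipeline_result with branches: without_ips, with_ips
#>   without_ips  1831 samples x 320 SOMAmers after filtering
#>   with_ips     1834 samples x 320 SOMAmers after filtering

print(res$branches$without_ips$report)
#> filter_report:
#>   control_somamers         removed   18 somamers -> 1870 samples x 400 SOMAmers
#>   confounder_association   removed   50 somamers -> 1870 samples x 350 SOMAmers
#>   low_r2                   removed   30 somamers -> 1870 samples x 320 SOMAmers
#>   vendor_flag              removed    2 samples  -> 1868 samples x 320 SOMAmers
#>   lod_fraction             removed   11 samples  -> 1857 samples x 320 SOMAmers
#>   total_rfu                removed    9 samples  -> 1848 samples x 320 SOMAmers
#>   pca_outlier              removed   17 samples  -> 1831 samples x 320 SOMAmers
#>   surviving: 1831 samples x 320 SOMAmers
```

Starting from 1870 study + pooled wells and 418 SOMAmers, the run removes
the planted control reagents (18), confounder-associated SOMAmers (50) and
low-repeatability SOMAmers (30), then the flagged, detection-limit,
total-intensity and PC-outlier samples. Every planted bad sample is caught;
the handful of extra sample removals are genuine 5-SD tail samples of the
heavy-tailed intracellular factor, which the paper's rules would also
remove. The co-primary `with_ips` branch additionally residualises every
SOMAmer on the intracellular score before filtering:

```r
ips <- compute_ips(res$corrected, res$ips_model)
cor(ips, fit_pca(res$corrected)$scores[, 1])
#> [1] 0.9998485       # the score is essentially PC1 before adjustment
```

A thin command-line wrapper is installed at `inst/cli/sf-somaqc`
(`simulate`, `standardise`, `metrics`, `run`).

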