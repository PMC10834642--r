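---
title: "Single-marker quantification and fingerprint similarity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification and fingerprint similarity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saikoqams)
```

## The problem

Quality evaluation of a multi-component herbal material such as Bupleuri
Radix (*Bupleurum chinense* DC. root) faces a practical bottleneck: the
conventional external standard method (ESM) needs a pure, affordable
reference standard for every analyte, and several saikosaponins are scarce
and expensive. Quantitative analysis of multiple components by a single
marker (QAMS) removes that bottleneck: one cheap, abundant standard — here
saikosaponin d — anchors the quantification of the whole panel through
pre-established relative calibration factors (RCFs). A chromatographic
fingerprint complements the targeted assay by scoring each batch's whole
common-peak profile against a consensus reference.

This package implements that computation end to end and, because the
original instrument data are not public, pairs it with a synthetic
generator that reproduces the statistical structure the analysis assumes.
All empirical statements below are exactly what the test suite and
`scripts/acceptance.R` compute.

## The model

**Detector response.** Each analyte $i$ responds linearly within its
declared range: $A_i = m_i C_i + b_i$, with the seven response lines,
retention times, linear ranges, and detection channels of
`default_analytes()` (saikosaponin b2 at 254 nm, the rest at 210 nm).

**Relative calibration factor.** For internal reference $s$ and analyte
$i$ measured at matched gradient levels,
$$F_{si} = \frac{C_s / A_s}{C_i / A_i} = \frac{A_i\,C_s}{A_s\,C_i},$$
averaged arithmetically over the gradient levels (`compute_rcf`). The
factor of the reference against itself is exactly 1 at every level.

**Single-marker quantification.** Only the reference's curve is inverted:
$C_s = (A_s - b_s)/m_s$, then
$$C_i = \frac{A_i\,C_s}{A_s\,F_{si}}$$
(`quantify_qams`). Content in the dried material follows from the workup:
$W_i = C_i V / M$ with $V = 25$ mL extract and $M = 1.0$ g sample,
reported in mg/g (`content`).

**Validation statistics.** Linearity is the squared Pearson correlation of
the (concentration, area) points; LOD and LOQ are the concentrations whose
peak height reaches 3 and 10 times the baseline noise sd (so LOQ/LOD is
10/3 by construction); precision, stability and repeatability are relative
standard deviations (`rsd`, sample sd over mean); spike recovery is
`100 * (spiked - base) / added`.

**Fingerprint.** Peaks matched across all batches within a 0.1-min
retention window (single-linkage grouping; one peak per sample per group;
a group must appear in *every* batch to count as common) form the
common-peak set. The reference fingerprint is the per-peak median area,
and each batch scores the congruence (cosine) coefficient
$$S = \frac{\sum_k x_k r_k}{\sqrt{\sum_k x_k^2 \sum_k r_k^2}},$$
which is dilution-invariant and lies in $[0,1]$ for non-negative data.
Pearson correlation is available as an alternative metric.

**Chemometrics.** The batches × analytes content matrix is autoscaled
(contents span an order of magnitude across the panel, so unit-variance
scaling is required for every analyte to contribute), then analysed by PCA
(eigendecomposition of the correlation structure, component signs fixed so
the largest-magnitude loading is positive) and by agglomerative
hierarchical clustering with Ward linkage on Euclidean distances — the
typical defaults of the statistical software used in this field, kept
configurable.

## What the generator emulates

`sim_config()` fixes the study conditions:

* **Responses and layout** — the seven response lines, retention times and
  linear ranges above; Gaussian peaks of sigma 0.05 min (a visually
  realistic width for a 31-min sub-2-µm-particle run; the width only
  matters for rendering and peak detection, not for the factor algebra).
* **Noise** — multiplicative lognormal area noise, CV 0.02 by default,
  chosen to match replicate-injection RSDs of 1–3%; retention jitter sd
  0.02 min; white baseline noise sd 4000 detector units, which puts the
  simulated signal-to-noise LODs at the sub-µg/mL order of the real assay.
* **Condition effects** — area scales proportionally with injection volume
  and inversely with flow rate (band loading and dilution), exactly;
  temperature shifts retention by −0.02 min/°C from 35 °C and the second
  column by +0.15 min; a 0.5% per-(condition, analyte) multiplicative
  wobble represents run-to-run detector fluctuation. Because a common
  per-condition scale cancels in the factor, the wobble is the *only*
  source of RCF variability across the grid — any map preserving
  per-condition proportionality across analytes leaves the factors exactly
  constant. The instrument study never quantified its own retention/area
  shifts (only the resulting factor RSDs), so these magnitudes are
  modelling choices.
* **Batch structure** — 20 batches with the production-region coordinates
  of the panel, grouped into latitude bands (south < 35°N, mid 35–38°N,
  north > 38°N). True concentrations sit at 45% of each linear range,
  scaled by multiplicative group effects 1.25 / 1.00 / 0.75 (southern
  batches richest, matching the latitude sensitivity of saikosaponin
  accumulation) with 8% within-group lognormal heterogeneity — a
  between-group shift of roughly three within-group standard deviations,
  comfortably above the 2× regime the clustering stage is specified to
  resolve. Values are clamped to stay strictly inside the linear ranges.
* **Extra peaks** — 10 non-target peaks at fixed retention times away from
  every target, with 25% between-batch lognormal composition variation, so
  fingerprints carry 17 common peaks (7 targets + 10 extras) and batch
  similarities stay below 1.

What it does **not** emulate: gradient-elution chemistry, PDA or MS
spectra, co-elution/overlapping targets, baseline drift, missing or
spurious peaks, and extraction-yield variation. Passing tests therefore
demonstrate the *computational* correctness and the stability of the
method under the stated noise regime — not robustness to pathological real
chromatograms.

## Numerical and design choices

* **RCF gradient span.** Factors are determined from 6 levels spanning the
  *upper 80%* of each linear range (`span = c(0.2, 1)` in
  `simulate_condition_grid`), i.e. working concentrations. With the
  panel's nonzero intercepts the per-level factor at the very bottom of a
  range is dominated by the intercept (for saikosaponin a at 7.6 µg/mL the
  area is 5224 against an intercept of −10091, pushing the per-level
  factor to 0.35 versus ≈0.93 elsewhere); averaging such levels into the
  factor would bias single-marker results by >10% at working
  concentrations. Restricting factor determination to working levels is
  standard practice and keeps the per-level variation small, which is the
  premise of the method. Calibration *curves* for ESM still span the full
  range (`span = c(0, 1)` is the `simulate_calibration_series` default).
* **Curve fitting** is unweighted OLS; R² is the squared Pearson r.
* **Signal-to-noise** uses peak height over the sd of the baseline noise
  (peak-to-peak conventions exist; the sd convention is documented here).
* **Reference selection** screens every candidate at max per-analyte RCF
  RSD < 5%, then ranks the stable candidates by availability (saikosaponin
  d first: most abundant in the root, cheapest standard), with the summary
  RSD and then the name breaking ties. A strict RSD-first lexicographic
  ordering is available (`order_by = "rsd"`); it is not the default
  because at 0.5% wobble the candidates' RSDs are statistically
  indistinguishable, making the RSD-first winner seed noise rather than a
  property of the compounds.
* **Degenerate inputs** fail loudly: out-of-range concentrations in the
  generator, < 3 calibration points or zero variance, non-positive areas
  or concentrations in the factor, a missing reference peak, unmatched
  (sample, analyte) pairs in the comparison, and constant analyte columns
  in PCA are all errors. Below-LOQ results are flagged but reported.
  Quantification of the panel deliberately includes all six non-reference
  analytes (one published account mentions "five"; the panel has six).
* **Common-peak tie-breaks**: within a retention group each sample
  contributes its peak nearest the group median; consensus retention is
  the median of members; zero common peaks is a valid result.
* **Clustering cut.** `hca_contents` defaults to 4 groups — the dendrogram
  cut used in the original geographic study — while `run_pipeline` passes
  3, the number of latitude bands the generator actually encodes.

## Problem sizes

The default study is 20 batches × 17 peaks; the condition grid is 11
unique conditions × 7 analytes × 6 levels; repetition-based checks
(linearity, precision) use 100 seeded repetitions, and group-recovery
checks 20 generator seeds. These sizes reproduce every bound stably in
seconds while matching the original design (n = 6 replicate injections,
6-level gradients, 2 + 4 + 4 + 4 condition grids).

## Known limitations

* Factors inherit a small concentration dependence from the intercepts;
  the gradient mean documents and accepts it rather than modelling it.
* The published batch similarities (which ranged down to 0.64) derive from
  physical chromatograms that are not public; the synthetic similarities
  (≈0.97–1.0) reflect the generator's composition variance, and no attempt
  is made to reproduce the original per-batch values.
* No chromatographic alignment (COW/DTW), baseline-drift correction of
  synthetic data, uncertainty propagation on factors, or multi-reference
  consensus quantification.
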