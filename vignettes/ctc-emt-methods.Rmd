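---
title: "Methods: single-cell immunofluorescence quantification and EMT scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell immunofluorescence quantification and EMT scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcEMT)
```

# Scientific problem

Circulating tumor cells (CTCs) recovered from the blood of metastatic
breast-cancer patients are identified on cytospin slides by multi-channel
immunofluorescence: a nuclear stain (DAPI), pan-keratin (epithelial
marker), vimentin (mesenchymal marker) and CD45 (leukocyte marker). Two
questions drive the analysis this package implements:

1. **Per-cell phenotype.** Where does each CTC sit on the
   epithelial–mesenchymal transition (EMT) axis? This is scored by the
   ratio of vimentin to keratin expression (the *vim/K index*) against
   cut-offs derived from reference cell lines.
2. **Patient stratification.** Does the keratin expression of a patient's
   CTCs carry prognostic information? Patients are split into high-keratin
   (HK) and low-keratin (LK) groups by a pooled-median rule and compared
   on overall survival.

Because single-cell fluorescence values are only meaningful when the
detector responds linearly, the package also includes a calibration stage
that determines the usable photomultiplier (PMT) voltage range from a
fluorescent-bead dilution series.

All stages are validated end-to-end against a synthetic-data module whose
generators produce bead series, reference cell-line marker tables,
cytospin images with pixel-level ground truth, and patient cohorts.

# Quantification model: CTCF

Per-cell expression is measured as **Corrected Total Cell Fluorescence**:

$$\mathrm{CTCF} = \mathrm{IntegratedDensity} - \mathrm{Area} \times \mathrm{MeanBackground}$$

where IntegratedDensity is the sum of pixel intensities over the cell
region, Area the region's pixel count, and MeanBackground the estimated
per-pixel background of that channel. The per-cell *mean intensity* is
CTCF / Area; the identity `mean_intensity * area == ctcf` holds exactly
for every record and is asserted in the test suite, together with
additivity of CTCF over a partition of a region and equivalence with
naive per-pixel summation.

CTCF may be negative when a cell is dimmer than the background estimate;
negative values are preserved in the records (clamping would bias
population means upward). Only when forming the vim/K ratio are negative
intensities clamped to zero, because a ratio of signed noise is not
interpretable.

## Segmentation and cell identification

`segment_cells()` finds nuclei by Otsu thresholding of the DAPI channel,
labels connected components, and expands each nucleus into a measurement
region by a fixed dilation margin (default 6 px) with
nearest-nucleus assignment so that neighbouring regions never overlap.
Regions outside a plausible area range (default 50–5000 px) are dropped.
Background per channel is the median over the complement of all cell
regions — a robust choice that tolerates a minority of bright pixels.

A cell is called a CTC when it is DAPI-positive (nuclear mean intensity
above twice the DAPI background) and **CD45-negative**. The CD45-negative
threshold is data-driven: per-cell CD45 intensities are split by 2-means
clustering on a square-root scale (variance-stabilizing, so that large
dim cells and small bright cells separate correctly), and the threshold
is the smaller of the bright cluster's 5th percentile and its minimum.
Two guards avoid pathological splits: if clustering cannot separate the
populations, or if even the *dim* cluster sits far above the CD45
channel background (no true negative population present), the rule falls
back to an absolute threshold of 3x background with a warning. Keratin is
deliberately **never** used as an identification gate — mesenchymal CTCs
may be keratin-low, and gating on keratin would bias the EMT index.

# The vim/K EMT index

For each CTC the index is

$$r = \frac{\max(\bar I_{\mathrm{vim}}, 0)}{\max(\bar I_{\mathrm{K}}, 0)}$$

using background-corrected mean intensities. A denominator floor
(default: 1% of the median keratin intensity of an epithelial reference
population, via `default_denom_floor()`) marks ratios with effectively
zero keratin as undefined (`NA`) rather than letting them explode.

Cut-offs come from reference cell populations, not from fitted
distributions:

* `epithelial_upper` — the **maximum** vim/K ratio observed in an
  epithelial reference line (built-in profile: MCF-7, range 0.12–0.49);
* the **mesenchymal band** — the observed range of a mesenchymal
  reference line (built-in profile: Hs578T, range 5.47–38.88).

Classification is three-way: `ratio <= epithelial_upper` is
*epithelial* (boundary inclusive), `ratio >= mesenchymal_lower` is
*mesenchymal*, anything in between is *intermediate*. Ratios above the
mesenchymal reference maximum remain *mesenchymal* but carry an
`above_reference` QC flag, because they fall outside the calibrated
reference support.

```{r cutoffs}
cuts <- emt_cutoffs(0.49, 5.47, 38.88)
classify_emt(c(0.19, 1.57, 13.14), cuts)$emt_class
```

# Detector calibration

`generate_beads()` simulates a bead dilution series (default nominal
levels 100/33/10/3%, three replicates) across PMT voltages 450–600 V.
The underlying model is exponential gain in voltage with a soft
saturation ceiling above a saturation voltage (default 560 V):
below saturation the expected intensity is proportional to the nominal
level, above it the response is compressed through
$m = C\,(1 - e^{-E/C})$. Multiplicative noise has a 2% CV.

`fit_linearity()` regresses measured intensity on nominal level per
voltage, and `linear_range()` reports the highest voltage such that all
voltages up to it have $R^2 \ge$ a threshold (default 0.99) — a
*cumulative* rule, so a single saturated voltage caps the usable range.
With the default generator, 450–550 V are linear
($R^2 > 0.999$) and 600 V is not ($R^2 \approx 0.95$), so the linear
range is 550 V. `check_in_range()` then verifies that per-cell mean
intensities fall inside the bead-calibrated intensity span at the
working voltage.

# Synthetic data generators

The generators are the package's validation substrate: their defaults
define the reference study conditions, and every analysis claim is
tested against them.

## Reference cell lines

`cell_line_profiles()` ships profiles for MCF-7, T47D, MDA-MB-231,
Hs578T, EGF-treated MCF-7 and a CTC-like mixture. Each profile records
the keratin and vimentin mean, SD, and the observed vim/K ratio range of
the reference population. `generate_cellline_cells()` draws per-cell
(keratin, vimentin) pairs from a **moment-matched bivariate lognormal**
(Gaussian copula over lognormal marginals): fluorescence intensities are
strictly positive and right-skewed, which a Gaussian cannot represent
without truncation artefacts.

Two numerical refinements matter:

* **Correlation calibration.** The marker correlation is not directly
  published for these populations, but the mean of the lognormal ratio
  $V/K$ depends on it in closed form:
  $E[V/K] = (m_V/m_K)\exp(\sigma_K^2 - \rho\,\sigma_V\sigma_K)$.
  `calibrate_marker_correlation()` inverts this so each profile's
  delivered ratio mean matches its recorded population ratio mean.
* **Truncation pre-compensation.** Cells whose ratio falls outside the
  profile's `ratio_range` are rejected (bounded attempts per cell, with
  an informative error for infeasible profiles). Rejection truncates the
  distribution and would bias the delivered moments by a few percent, so
  the generator pre-compensates the input moments with a fixed-point
  iteration over the closed-form truncated-lognormal moments — the
  *delivered* sample then matches the profile's means and SDs.

## Cytospin images

`generate_cytospin_image()` plants CTCs and PBMCs as soft-edged discs
(logistic edge falloff, width 0.5 px) at non-overlapping positions on a
constant background (default 200 counts) with Gaussian read noise
(default SD 10) in a 16-bit range. Disc weights are normalized to sum to
one so the planted per-cell channel totals are conserved exactly —
this makes pixel-accurate recovery checks possible. CTC discs carry
keratin and vimentin drawn from a cell-line profile (scaled by
`intensity_scale`, default 30 counts per intensity unit) and no CD45;
PBMC discs carry CD45 and vimentin and no keratin; every cell has a
DAPI-bright nucleus at 70% of the cell radius.

## Patient cohorts

`generate_cohort()` simulates a cohort (default 61 patients, 2–40 CTCs
each) with per-patient CTC keratin values drawn from lognormals whose
means differ by triple-negative status (defaults: mean 122.4, SD 99.98
for triple-negative; 175.0, SD 128.0 otherwise), and exponential
survival times whose rates are set from target one-year survival
probabilities per keratin group (defaults 0.733 HK, 0.462 LK) with
uniform censoring. The HK/LK labels used for survival generation are
derived *inside* the generator with the same pooled-median rule the
analysis applies, so the generator and the analysis cannot drift apart.

# The HK/LK stratification rule

* The split point is the **pooled median** of all CTC keratin values
  across the cohort (not a per-patient median).
* A CTC is "high" iff its keratin is **strictly above** the pooled
  median.
* A patient is HK iff **strictly more than 50%** of their CTCs are high;
  an exact 50/50 split is LK. This tie policy makes the rule a partition
  and is asserted property-based (partition, strict majority,
  permutation invariance) in the tests.

Group analyses follow classical workflows: an F-test decides between
pooled and Welch two-sample t-tests for keratin by covariate; a 2x2
Pearson chi-squared test (no continuity correction) for the association
of HK/LK with binary covariates; Kaplan-Meier estimates with a log-rank
test for survival (degenerate configurations return `NA` rather than
failing); and Kruskal-Wallis with tie-corrected, Bonferroni-adjusted
Dunn post-hoc z-tests for comparing three or more cell populations.

# Limitations

* Synthetic cells are soft discs: no touching/overlapping cells,
  irregular morphologies, uneven illumination, or staining artefacts, so
  segmentation performance on the synthetic fixtures is an upper bound
  for real slides.
* Cut-offs are sample extrema of the reference populations, so they
  inherit the references' sampling variability; the package reports,
  rather than models, values above the mesenchymal reference maximum.
* The cohort generator emulates the *structure* of a patient cohort
  (group separation, survival difference, censoring); it does not model
  treatment lines, competing risks, or longitudinal sampling.
* The bead model's soft-saturation form is a convenient stand-in for
  detector nonlinearity; only the location of the linearity breakpoint,
  not the exact saturated response, should be interpreted.
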