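---
title: "Methods: translocation scoring, ERES colocalization, and the synthetic assay model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translocation scoring, ERES colocalization, and the synthetic assay model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translocatr)
```

`translocatr` quantifies two readouts of ATF6α trafficking in multichannel
fluorescence imaging: how much of the protein's signal has moved from the
endoplasmic reticulum into the nucleus (the screening statistic of a
plate-based assay), and how strongly it is enriched in ER exit sites
(ERES) relative to COPII markers. This vignette records the models,
parameter choices and numerical decisions behind each stage, what the
synthetic generator does and does not emulate, and the sizes at which the
package's tests exercise each claim.

## 1. Per-cell nuclear:ER ratio

Each field carries a DAPI channel (nucleus), an ER-marker channel (GRP94
or calnexin), and the ATF6 channel (GFP fusion, FLAG tag or endogenous
stain). Segmentation is deterministic and classical:

* **Nuclei** — median background subtraction, global Otsu threshold,
  hole filling, distance-transform watershed declumping, then an area gate
  of 40–400 µm² (plausible U2-OS nuclei; both bounds are arguments).
* **Cells / ER region** — Otsu on the background-subtracted ER marker
  defines ER-positive pixels; the union of that region and the nuclei is
  partitioned among cells by seeded propagation from the nucleus labels
  (the CellProfiler propagate metric, `lambda = 1e-4`). A cell's ER mask
  is its assigned ER-positive pixels minus its nucleus, so the two masks
  are disjoint by construction — an invariant asserted on every output.

The per-cell score is the ratio of mean ATF6 intensity over the nucleus
mask to mean ATF6 intensity over the ER mask. Ratios are unitless and
insensitive to global intensity scale, which is why the pipeline accepts
8/16-bit and float images interchangeably. Cells touching the field border
are excluded from scoring by default (partial cells bias region means);
cells with non-positive ER mean are dropped and counted.

No mitotic or apoptotic cell filter is applied; nothing in the assay
description defines one, and the area gate already removes most debris
and clumps.

## 2. Plate-adaptive activation threshold

The activated/inactive boundary is derived per plate from one stressed
(e.g. 100 nM thapsigargin) and one unstressed control: both ratio sets are
histogrammed on common bins of width 0.05 starting at 0, counts are
normalized to each population's size, and the threshold is the lower edge
of the lowest bin with left edge > 1 where the stressed frequency strictly
exceeds the unstressed frequency.

Decisions worth recording:

* **Frequencies, not raw counts.** Control wells differ in cell number;
  comparing per-bin relative frequencies makes the rule invariant to that.
  A raw-count mode remains available (`mode = "count"`).
* **Right-closed bins.** Bins are `(lo, hi]`, so a ratio lying exactly on
  a bin boundary belongs to the lower bin; a point mass at 2.5 with bin
  width 0.1 therefore qualifies the bin whose lower edge is 2.4. Bin
  indices are computed as `ceiling(ratio / width - 1e-9)`; the small
  epsilon keeps exact multiples of the width on the intended side of the
  boundary in floating point.
* **Run guard.** A single noisy bin can satisfy the rule spuriously. The
  anchor bin must qualify strictly, and the next `run_length - 1 = 2` bins
  must not fall back below the unstressed curve (non-strict `>=`). The
  successor condition is deliberately non-strict: past the stressed
  population's support both histograms are empty, and empty-vs-empty
  should not disqualify a genuine crossing. Setting `run_length = 1`
  disables the guard.
* **Lower edge, per plate.** The threshold is reported as the qualifying
  bin's lower edge together with its bin width, and is never shared across
  plates.
* **Strict inequalities throughout.** A cell whose ratio equals the
  threshold counts as inactive; derivation requires the bin's left edge to
  exceed 1 strictly, so every successful derivation returns a value > 1.

If no bin qualifies — as when stressed and unstressed populations are
identical — derivation fails loudly, naming both wells: that is the
signature of a failed stressed control, not a condition to paper over.

## 3. Percent activation and hit calling

Percent activation is the percentage of a well's cells with ratio strictly
above the plate threshold; wells below 50 cells are flagged (the binomial
noise on a percentage grows fast below that). Hits are test wells whose
percent activation lies more than three *sample* standard deviations
(n−1 denominator, hence at least two stressed-control wells) below the
stressed-control mean — a suppression screen, so the rule is one-sided
downward. `call_hits()` is idempotent: re-running it on its own output
changes nothing.

Under Gaussian well-to-well noise with `n_c` control wells, the exact
false-hit probability of the rule is `P(T < -3 / sqrt(1 + 1/n_c))` with
`T ~ t(n_c - 1)` — the closed form the acceptance suite checks the
Monte-Carlo false-hit rate against (1000 simulated null plates, 8 control
and 8 test wells each).

## 4. ERES detection and within-ERES correlation

The Sec31A and Sec16 channels are median-background-subtracted (clamped at
zero) and multiplied pixelwise. Without the background step the product of
two positive backgrounds would be globally non-zero and the double-positive
logic of the product mask would fail; raw, uncorrected channels are still
used for all intensity measurements within detected objects.

Detection on the product image:

1. Gaussian pre-smoothing, σ = 0.7 px, suppresses single-pixel shot noise
   before thresholding (set `smooth_sigma = 0` to disable).
2. Global Otsu threshold (per slice; the product image is bimodal —
   background near zero against double-positive puncta).
3. Connected components, then **per-clump declumping**: watershed runs on
   each component separately, normalized to that component's own peak, so
   whether a dim punctum survives or a clump splits does not depend on how
   bright other spots in the field are. The `declump_tolerance` of 0.2 is
   therefore a fraction of each clump's own dynamic range.
4. Object pixel sets are the *raw* above-threshold pixels, assigned to the
   declumped seeds by seeded propagation. This keeps the measured area
   independent of the smoothing kernel: smoothing can neither inflate a
   sub-resolution speck past the lower gate nor clip a dim spot whose
   smoothed support is narrower than its raw support.
5. Size gate: the equivalent diameter (diameter of the circle with the
   object's area — the standard operationalization of "diameter" for
   irregular components) must lie in 0.167–1.67 µm. The gate is asserted
   as an invariant on every run, and the acceptance suite measures the
   realized window edges by sweeping planted disk sizes through the
   detector.

Objects are assigned to the cell containing their centroid; centroids on
background give `cell_id` 0 and are excluded from per-cell statistics.
Correlation between two fluorophores is the Pearson correlation over all
pixels of a cell's retained ERES in one slice, pooled across objects.
Per-object correlation on 3–10-pixel spots is numerically unstable, which
is why pooling is the default; `by = "object"` computes per-object r and
averages for comparison. Slices with fewer than 3 pooled pixels or a
constant channel are skipped and counted. Per-slice r values aggregate to
a per-cell mean and SD, per-cell means to treatment tables, and per-cell
means within an experiment to experiment-level means — each level an exact
arithmetic mean of the level below, asserted in tests. Slices are analyzed
independently in 2D; there is no volumetric segmentation.

## 5. The synthetic scene model

The generator exists so every stage has a recoverable target. It emulates:

* **Cell geometry** — nucleus as a disk inside a larger cell disk; the
  annulus is the ER region, with multiplicative lognormal texture
  (σ_log = 0.3) on the ER marker. The scoring uses region means only, so
  finer ER morphology would add realism without adding test power.
* **Translocation** — each cell is activated with probability
  `activated_fraction`; its true nuclear:ER ratio is lognormal with median
  0.8 (inactive, ER-retained) or 2.5 (activated, nuclear) and σ_log = 0.2.
  These medians reproduce the overlapping unimodal/bimodal histograms the
  threshold rule has to handle; before noise, the rendered ATF6 channel
  satisfies mean(nucleus)/mean(ER) = true ratio exactly.
* **ERES** — diffraction-limited puncta rendered as 2D Gaussians with
  FWHM equal to the nominal diameter, amplitudes lognormal (σ_log = 0.35)
  around a mean peak of 150 counts, centers at least 1.6 µm apart within
  the ER annulus. A punctum is double-positive with probability
  `coloc_fraction`; single-positive puncta land in exactly one channel.
* **Correlated ATF6 signal** — inside double-positive puncta the ATF6
  channel is `base + scale · (ρ z + sqrt(1 − ρ²) ε)`, where z is the
  standardized noise-free Sec31A signal on those pixels and ε is standard
  normal: Gaussian-copula mixing with expectation ρ for the pixelwise
  Pearson correlation. At ρ = 1 with noise off the relation is affine and
  the sample correlation is exactly 1.
* **Noise** — Poisson shot noise at `photon_scale` detected photons per
  intensity unit, then additive Gaussian read noise (SD 2 counts), over a
  constant background of 10 counts in every channel.
  `photon_scale_for_snr()` inverts this model so tests can state scenes by
  SNR. Setting all three to zero yields exact construction identities.

Default geometry follows the two imaging regimes of the assay: 0.65 µm/px
with 30 µm cells for plate-scale translocation scoring (20x EMCCD), and
0.11 µm/px for ERES work (100x). The microscope's true pixel size is never
assumed — it is a required configuration value.

What the generator does **not** emulate: photobleaching, stage drift, z
point-spread, cell motion, mitotic figures, plate-edge effects, or
non-disk cell shapes. Tests passing on these scenes therefore demonstrate
the correctness of the *measurement logic* under controlled truth, not
robustness to every artifact of real microscopy.

Two measurement-level points deserve emphasis:

* **Photon noise attenuates pixelwise correlation.** Independent noise in
  both channels dilutes the correlation of the underlying signals, so on
  noisy scenes the estimator correctly reports less than the generator's
  target ρ. Correlation *recovery* is therefore measured on noise-free
  scenes over known punctum masks (±0.05 at ≥ 2000 pooled pixels, the
  Fisher-z sampling error at that n), while the noisy, detection-based
  path is checked for strict monotonicity of estimated r in the target ρ.
* **Threshold/percent-activation recovery is measured at the ratio
  level.** The generator's `simulate_well_ratios()` draws per-cell ratios
  from the same model the image renderer uses (plus 5% lognormal
  measurement error) without rendering pixels, so a 24-well plate at 300
  cells/well is simulated in milliseconds. The image → segmentation →
  scoring path is exercised end-to-end separately at smaller n; the
  plate-scale recovery claim (mean absolute error ≤ 5 percentage points
  across activated fractions 0–1) is about the scoring rules, not about
  segmentation, which has its own recovery criteria.

## 6. Statistical reporting

Group comparisons use the classical pooled-variance (Student) unpaired
two-tailed t-test — consistent with reporting an F-test of equal variances
alongside; Welch's form is available by flag. One-way ANOVA is the
fixed-effects F with (k−1, N−k) degrees of freedom; on two groups it
equals the squared t exactly, an identity the tests assert to 1e-10. The
F-test of variances reports the larger-over-smaller variance ratio with a
two-tailed p. Degenerate inputs follow explicit conventions rather than
erroring mid-pipeline: identical constant groups give statistic 0 and
p = 1 (t, ANOVA) or F = 1 and p = 1, always flagged `degenerate`. Raw
p-values are reported without multiple-testing correction, and the run
metadata says so.

Box-plot summaries report quartiles with whiskers at the minimum and
maximum of the data; group means are drawn with t-based 95% confidence
limits. Figures come from `autoplot()` / `plot_*()` functions;
`render_report()` writes figures, full-precision CSV tables and a
run-metadata YAML (seed, configuration hash, package version).

## 7. Problem sizes and runtime

The test suite builds every fixture in code at run time: 512–640 px
translocation fields with 8–30 cells, 360–460 px ERES fields with 15–60
puncta, 1000-plate Monte-Carlo null for the hit rule, 1200–2000-replicate
null simulations per statistical test, and a ~200-point disk-size sweep
for the gate window. The full suite runs in under a minute on one CPU;
the calibration script in about twenty seconds.

## 8. Known limitations

* Segmentation is intensity-based; heavily confluent cultures or
  off-focus fields would need retuned area gates or different methods.
* The ERES diameter gate measures area above an automatic threshold, so
  the detected equivalent diameter of a Gaussian spot depends mildly on
  its contrast; the gate-edge sweep quantifies the realized window.
* Correlations are computed in 2D per slice; axial structure is summarized
  only through per-cell means over slices.
* OME-XML metadata is not parsed; channel order and pixel size come from
  configuration, which is also the honest mode of operation when
  acquisition metadata is untrustworthy.
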