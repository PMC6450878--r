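---
title: "Quantifying protein recruitment to clustered integrin tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein recruitment to clustered integrin tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticr)
```

## The measurement

Chimeric receptors that fuse the extracellular IgV-like domain of CEACAM3
to the cytoplasmic tail of an integrin β subunit can be clustered at will
with multivalent ligands — CEACAM-binding bacteria or antibody-coated
beads. If a fluorescently tagged cytosolic protein of interest (POI)
binds the clustered tail, it accumulates locally at the attachment site.
`opticr` quantifies that accumulation per cell with a single ratio:

$$ R \;=\; \frac{\max_{\,\mathrm{ROI2}}\; I_{\mathrm{POI}}}{\operatorname{mean}_{\,\mathrm{ROI1}}\; I_{\mathrm{POI}}} $$

where ROI1 is the whole-cell region (drawn from the POI channel) and ROI2
is the attachment-site region (drawn from the clustered-receptor
channel). `R` is the fold difference between the brightest POI pixel at
the site and the average POI fluorescence of the cell; a cell is scored
*positive* for recruitment at `R >= 2`, i.e. a two-fold local enrichment
over the mean cellular distribution. Condition-level results are the mean
`R` with a 95% confidence interval and the percentage of positive cells,
compared across conditions by one-way ANOVA with Bonferroni-corrected
post-hoc tests against a control.

The statistic makes three assumptions worth keeping in mind:

* **Ratios are scale-free but not offset-free.** `R` is invariant under
  multiplicative intensity changes (laser power, exposure), but any
  additive offset `b` pulls it toward 1: the recoverable value becomes
  `(E·c + b)/(c + b)` for a true enrichment `E` over baseline `c`. No
  background subtraction is applied by default because the measurement
  protocol this implements uses raw intensities; a field with substantial
  background should be corrected before quantification.
* **The numerator is a maximum over raw pixels.** Shot noise therefore
  biases `R` upward by an amount that grows with ROI2 area and noise
  level; comparisons are made against matched controls quantified the
  same way, which is exactly how the assay is used.
* **One value per cell.** All attachment sites of a cell are unioned into
  one ROI2 and the maximum is taken over the union, so multi-site cells
  contribute a single data point. Per-site scoring is possible by calling
  `compute_ratio()` on individual components.

## The synthetic-data generator

No public image data accompanies the assay, so the package ships a
generator (`optic_params()`, `simulate_field()`, `simulate_cohort()`)
that renders fields with known ground truth. A field contains:

* one adherent cell, a disk of radius `cell_radius` (default 60 px in a
  256 × 256 field) with uniform POI baseline `c = baseline_intensity`
  (default 60 photons/pixel, a moderate fill of an 8-bit range);
* one receptor cluster at the cell perimeter — either a `microcolony`
  (default: 4 spots of radius 4 px strung along the perimeter arc) or a
  `bead` (one disk of radius 6 px). The attachment angle is drawn from
  the field seed by default (`cluster_angle = "random"`);
* POI enrichment `E·c` rendered on the part of the cluster footprint
  outside the cell outline — the corona of recruited protein around a
  microbe sitting atop the cell edge. This choice keeps the mean over the
  full cell footprint exactly `c + b` and makes the ground-truth ratio
  exactly `(E·c + b)/(c + b)` (and exactly `E` when `b = 0`), so
  parameter-recovery tests have an analytic target with no
  discretization error. It also mirrors the observation that the
  attachment-site ROI may poke beyond the cell outline;
* a receptor channel concentrated at the cluster
  (`receptor_gain × c`, default gain 6) over a dim diffuse pool on the
  cell (`receptor_membrane_frac`, default 5% of the cluster level), and a
  bacteria channel nonzero only on the cluster footprint;
* image formation: Gaussian PSF blur (`psf_sigma`, default 2 px) applied
  to the ideal intensities, then Poisson shot noise, then Gaussian read
  noise (`gaussian_read_sd`, default 2), then optional quantization to
  `bit_depth` levels (off by default so analytic cases stay exact; 8 bit
  mirrors the acquisition being emulated). Blur precedes noise because
  imaging is photon-limited at the detector.

Identical parameters (including the seed) give bit-identical fields.
Cohorts derive per-field seeds from one master seed and label fields with
a pseudo-experiment of origin cycling over three replicates, so the
aggregation path over "n cells from three independent experiments" is
exercised; no batch effect is simulated by default
(`experiment_factor` provides a multiplicative one if wanted).

What the generator does **not** emulate: real cell morphology (cells are
disks, not spread lamellipodia), intracellular POI texture, chromatic
offsets or Airy rings, 3-D structure, bleed-through, or the true unknown
background and SNR of the original acquisitions — none of which are
stated in the protocol this follows, so defaults were chosen for
testability rather than fidelity. Passing tests therefore demonstrate
that the estimator and statistics behave correctly on images whose
ground truth is known, not that segmentation would be adequate on any
particular real data set.

A note on scale: the acquisition being emulated uses 1024 × 1024 fields;
the default 256 × 256 keeps simulation-heavy test suites fast, and all
geometry parameters are in pixels, so the full-scale setting is available
by passing `field_shape = c(1024L, 1024L)` with proportionally scaled
radii. The footprint radii were chosen so that the enrichment patch
(several microns across, like a recruitment zone around a microcolony) is
large relative to the PSF; a patch at the PSF scale would be attenuated
into the noise and is not what the assay images show.

## Automated ROIs

The original ROIs were hand-drawn; `opticr` automates them:

* `segment_cell()` (ROI1): Gaussian smoothing (sigma 2 px), Otsu
  threshold on the min–max-normalized image (making the result exactly
  invariant under multiplicative scaling), hole filling, largest
  connected component of at least `min_area` (default 500 px). Failure
  modes (constant image, nothing large enough) raise a `no-cell` error.
* `segment_clusters()` (ROI2): pixels strictly above the 0.995 intensity
  quantile of the receptor channel, dilated by 3 px (the micron scale of
  a bacterium), keeping components that touch the dilated cell mask and
  unioning them. A quantile rule is used instead of Otsu because cluster
  pixels are a tiny area fraction, where Otsu is unstable. A light
  pre-smoothing (sigma 1.5 px) is applied before thresholding so that
  shot-noise singletons do not fragment the site into spurious
  components; with smoothing off the rule reduces to the plain quantile
  threshold. A cell with no surviving component raises a `no-cluster`
  error, which cohort quantification records as an exclusion — mirroring
  the convention that only cells with receptor-bound particles are
  scored.

The hand-drawn originals have no reproducible rule, so adequacy of the
automated stand-ins is established only against simulator ground truth
(intersection-over-union of the cell mask, pixel coverage of the cluster
mask, and the fraction of analysable fields), in the test suite.

## Statistics

`summarize_condition()` reports mean `R` with a Student-t interval
(`mean ± t(0.975, n−1) · sd/√n`); the measurement protocol does not state
its interval method, and a t-interval is the conventional reading of
"mean and 95% CI" whiskers. With all values identical the interval
degenerates to the mean. `percent_positive` is exactly
`100 × mean(positive)`.

`anova_with_bonferroni()` fits a standard one-way ANOVA and then tests
each condition against the reference using the pooled error term (MSE,
residual df) — the classical Bonferroni post-hoc procedure. The
correction multiplies raw p-values by the number of comparisons
*performed*: versus-reference only by default, because that is how the
assay's contrasts are reported ("differences from the control"), with
`all_pairs = TRUE` available; whether the original correction spanned
all pairs is not stated, so versus-control is the package's default.
Cells are pooled across pseudo-experiments without a mixed model,
matching the source analysis; the experiment label is retained in the
records for sensitivity analyses.

## Motif scanning

Talin binds the membrane-proximal `N-P-x-[Y/F]` motif of integrin β
cytoplasmic tails; a membrane-distal `N-x-x-[Y/F]` motif (the
kindlin-associated site) usually follows. `find_motifs()` reports both
classes in precursor numbering (1-based, counting the signal peptide —
the convention in which the human β1 NPxY tyrosine is Y783), carried by
the `start_index` of each `tail_sequence`.

Disambiguation needs care because in several tails the distal motif is
itself of `NPxY` form (β1's distal NPKY, for example). The rule adopted:
the **first** `NPx[Y/F]` match is the membrane-proximal hit, unless it is
the last `Nxx[Y/F]` match of the tail *and* lies in the C-terminal half —
then it is classified as membrane-distal. The first `Nxx[Y/F]` match
after the proximal hit (or, with no proximal hit, the first in the
C-terminal half) is the membrane-distal hit, and each occurrence is
reported under exactly one class. This makes a proximal-site point
mutation (Y783A) lose the proximal hit rather than promoting the distal
NPKY into its place, which matches how such mutants are interpreted.

`apply_mutation()` verifies the reference residue at the stated precursor
position before substituting, which guards against numbering-offset
mistakes.

The packaged FASTA fixtures come in two files. `tails_human_core.fa`
holds the human β1, β2 and β3 tails, reconstructed from the published
construct primer translations (the β2 entry is verified end-to-end by its
primers; β1 matches its construct boundary E762–K798 and the canonical
tail sequence). `tails_extended_synthetic.fa` holds best-effort stand-ins
for human β5–β8 and the two *Capsaspora owczarzaki* tails: they preserve
the documented motif architecture (proximal NPxY/F present in β5–β7,
absent in β8; NPXY in C.ow ITGB1, NPXF in C.ow ITGB2) but are not
database-verified residue-for-residue, hence the `synthetic` label. The
β4 tail is excluded because of its extraordinary length (it is also
excluded from the published alignment), so no claim about β4 is encoded.

## Numerical choices and edge cases

* The positivity boundary is **inclusive** (`R >= 2`): the per-figure
  definitions of the reported percentages use `≥`, and the threshold and
  strictness are both exposed (`classify_positive(threshold =, strict =)`).
* The ROI1 mean **includes** pixels that also belong to ROI2 — the
  literal reading of "mean fluorescence for ROI1" — so `R` slightly
  underestimates enrichment when the site lies inside the cell outline.
* The maximum is taken on raw, unsmoothed pixels (whether the original
  was smoothed is unstated; raw is the conservative reading).
* Line scans (`line_scan()`) use bilinear interpolation and normalize
  each channel to its own maximum along the segment; an all-zero channel
  is reported as all-zero rather than divided.
* `R = 1` exactly for a constant POI image, any ROIs; a non-positive
  ROI1 mean or an empty ROI is an error, and per-cell errors in cohort
  runs become logged exclusions rather than failures.
* Enrichment factors below 1 render a depleted corona that the max-based
  statistic cannot see (it reports 1); negative factors are rejected.

## Problem sizes used by the verification suite

The test suite's statistical checks run at sizes chosen to give stable
answers at interactive cost: parameter recovery and segmentation
adequacy use 60-cell cohorts at the default 256 × 256 scale;
discrimination (3-fold enrichment versus control, adjusted p < 0.001)
uses 20 master seeds at the same scale with automated ROIs; the type-I
calibration of the ANOVA/Bonferroni chain uses 1000 replicates of two
60-cell groups drawn from one condition at a reduced 96 × 96 scale with
a fixed attachment angle and ground-truth-mask recruitment — the
procedure under calibration is the statistics chain, the recruitment
distribution is rotation-invariant, and segmentation adequacy is
established separately.

## Limitations

Automated ROIs are validated only on synthetic ground truth; the
simulator's geometric simplicity means that performance on real,
irregular cells is untested. The ratio's noise-dependent upward bias
makes absolute `R` values comparable only between identically acquired
and identically quantified conditions. The synthetic tail sequences for
β5–β8 and *Capsaspora* should be replaced with database sequences before
any use beyond motif-logic demonstration.
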