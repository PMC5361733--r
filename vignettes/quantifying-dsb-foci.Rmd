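---
title: "Quantifying DNA double-strand-break foci in 3D image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA double-strand-break foci in 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbfoci)
library(dplyr)
```

## The measurement problem

Ionizing radiation and replication stress sever both strands of the DNA
duplex. Cells mark each double-strand break (DSB) by phosphorylating
histone H2AX (γH2AX) and recruiting repair mediators such as 53BP1, which
accumulate into micrometre-scale nuclear foci that can be counted under a
fluorescence microscope. The number of foci per nucleus is therefore a
per-cell dosimeter of DNA damage, and its change over time after
irradiation a readout of repair capacity.

Two confounders make naive counting misleading:

* **Cell-cycle phase.** Cells replicating their DNA (S/G2) carry many more
  spontaneous foci than G1 cells, so populations with different cycle
  structure (fibroblasts versus fast-cycling pluripotent cells) are not
  comparable unless counts are stratified by phase. Phase is read out by
  EdU incorporation: a thymidine analogue given before fixation labels
  every nucleus that synthesized DNA, and the total EdU intensity per
  nucleus is bimodal — EdU-negative (G1) versus EdU-positive (S/G2).
* **Subjectivity.** Manual focus scoring does not scale to the hundreds of
  cells per condition needed for stable means; the whole chain from
  nucleus segmentation to spot counting must be automatic and
  parameter-explicit.

`dsbfoci` implements this chain for three-channel 3D stacks (nuclear
stain, DSB-marker, EdU): nucleus instance segmentation, extended-maxima
focus counting, total-intensity EdU gating, and a stratified statistics
layer. Because the kind of raw imaging data the pipeline targets is
rarely public, the package also contains a synthetic-image generator with
known ground truth; every stage is validated by parameter recovery
against that truth.

## The processing model, stage by stage

### Nucleus segmentation

The nuclear channel is smoothed with a Gaussian of SD `sigma_px` (default
1 px laterally; the axial SD is scaled by the `spacing_y/spacing_z` ratio,
which at 124 nm pixels and 3 µm sections is ~0.04 voxels — effectively no
axial smoothing, on purpose). A **two-level Otsu** threshold is then
computed on a 256-bin histogram: the pair of cut points maximizing the
three-class between-class variance. The lower level plays the role of the
hysteresis low threshold and the upper level the seed threshold:
foreground is every voxel above the low level that is 26-connected to a
voxel above the high level. This reading is the only one in which a
two-level Otsu naturally parameterizes hysteresis thresholding: the upper
class (bright nucleoplasm) seeds objects, the middle class (dimmer nuclear
rim) is annexed only where connected to a seed, and background stays out.

Connected components below `min_voxels` (default 2000 voxels ≈ 0.09 pL at
the default spacing — well below any intact nucleus, above debris) are
discarded, as are components touching the volume border, replacing the
whole-cell selection a human would do by cropping. Touching-nuclei
splitting (watershed) is deliberately not implemented: the generator
guarantees separated nuclei and real clumps are caught by the size filter.
Thresholds are recomputed per field, so segmentation is invariant under
affine intensity rescaling.

### Focus detection

Foci are detected in the marker channel by the **extended-maxima
(h-maxima) transform**: grayscale reconstruction by dilation of
`volume − h` under `volume`, followed by regional maxima of the
reconstruction. A surviving component is a connected voxel set on which
the image stands at least `h` above its surrounding reconstruction level —
a pure *prominence* criterion, invariant to additive offsets, which is
what a "spot height threshold" should mean. Defaults are the empirically
standard detector settings for this assay: smoothing SD 1 px, height
threshold `h = 80` camera counts, maximum spot size 800 voxels
(components larger than that are diffuse signal, not a focus), and
26-connectivity. The height criterion is applied before the size filter;
a merged multi-peak component counts as one focus (no declumping).
Components are assigned to the nucleus whose label covers their centroid;
centroids on background are discarded.

One degenerate case deserves a note. The textbook transform marks the
*entire domain* when the reconstruction is globally flat — a blank
channel, or a single peak shallower than `h`, reconstructs to a constant,
and a constant image is vacuously "all regional maxima". We therefore
require a maxima plateau to have at least one strictly *lower* neighbour;
a domain-spanning plateau has none and yields zero components, which is
the behaviour a spot counter needs.

### EdU gating

The EdU readout per cell is the **total** channel intensity over the
nucleus's labelled voxels. Per virtual slide (pooling all its fields), a
classical one-dimensional Otsu threshold is computed on a 256-bin
linear-scale histogram of the totals; cells strictly below the threshold
are called G1 (EdU-negative), cells at or above it S/G2 (EdU-positive).
The tie rule is arbitrary but fixed and documented. Gating is
scale-equivariant: rescaling all totals rescales the threshold and leaves
every assignment unchanged.

### Statistics

Per (line, marker, dose, time, phase) group the package reports the mean
foci per cell, the SEM (sample SD/√n; defined as 0 with a warning for
n = 1), and n — the schema of a published condition summary table, which
ships as a fixture (`table1()`). On top of that:

* `fold_change()` / `percent_increase()` — ratio and percent arithmetic
  with the exact identity `fold = 1 + percent/100`; `format_fold()`
  rounds the way such numbers are conventionally reported (nearest
  integer at ≥ 3, one decimal below).
* `compare_two_groups()` — Student's two-sample t (equal-variance,
  two-sided) by default, Welch behind a flag. The paper trail for this
  assay uses the plain Student form, so that is the default.
* `anova_tukey()` — one-way ANOVA with Tukey HSD (Tukey–Kramer for the
  unequal group sizes that per-cell tables always have), significance at
  α = 0.05.
* `repair_time_course()` — per series (line, marker, phase), the means at
  0, 0.5, 2 and 6 h after irradiation and the percentage of foci
  remaining at 2 and 6 h relative to the 0.5 h peak, when damage
  recognition is maximal. Steeper decline = faster repair. SEMs are
  cell-level; region-level aggregation can be had by summarising with
  `field_id` among the grouping keys.

## The synthetic-image generator

The generator emulates the acquisition the pipeline targets: 30 z-slices
at 3 µm, 1392 × 1040 px fields at 124 nm pixels, 16-bit-style camera
counts. Its generative model is deliberately the simplest structure
consistent with published summaries, because those summaries (means, SEMs,
EdU-negative percentages) are all that exists to calibrate against:

* nuclei are non-overlapping axis-aligned ellipsoids, lateral semi-axes
  4–7 µm, axial semi-axes 1.5–2.5 slices, placed uniformly with a 10 px
  lateral gap and off the field border;
* each cell is G1 with probability `frac_g1`, and its focus count is
  Poisson with the phase-specific rate (`lambda_g1`, `lambda_sg2`);
* foci are uniform in the 0.9-scaled nucleus ellipsoid, rendered as
  in-plane Gaussian spots (SD 1 px, peak 200 counts) on the slice nearest
  their axial position;
* per-cell EdU is a phase-specific *total* intensity (10% CV) spread over
  the nucleus volume as a per-voxel level. Totals, not per-voxel levels,
  are what gating sees; drawing totals directly keeps the two clusters
  ~9 within-cluster SDs apart, as a clean bimodal EdU histogram shows.
  (An earlier per-voxel-level model let the ~4× spread of nucleus volumes
  leak into both clusters, compressing the separation to ~2 SD and making
  linear-scale Otsu split inside the S/G2 cluster.)
* optional additive Gaussian read noise (default 0: the validation
  scenarios are noise-free by design), clipped at zero.

Two resolvability constraints tie the generator to the detector's
geometry, both chosen from first principles rather than tuned:

* two foci within one z-slice of each other keep ≥ 8 px lateral
  separation. After 1 px rendering PSF and 1 px detection smoothing, a
  spot's peak is ~88–100 counts; at 8 px separation the saddle between
  two spots stays low enough that each peak keeps ≥ 80 counts of
  prominence even at worst-case sub-pixel offsets. Without this, the
  h-criterion correctly merges close pairs — real overlapping foci do
  merge under any prominence detector — but then the recovered mean
  systematically undershoots the generative rate and "parameter recovery"
  is no longer a well-posed test of the counter.
* a focus's *voxelized* position must lie inside the 0.93-scaled
  ellipsoid: a continuous position near the axial rim can otherwise round
  onto a z-slice whose nucleus cross-section excludes it, leaving the
  rendered spot on background where the centroid-assignment rule rightly
  drops it.

What the generator does **not** emulate — and what passing recovery tests
therefore do not certify: optical blur across slices (no 3D PSF),
photobleaching, uneven illumination, clustered or merged foci,
mitotic/apoptotic morphology, touching nuclei, intensity-dependent noise.
On real stacks the detector's empirical parameters carry the burden those
effects impose; the synthetic suite validates the algorithmic chain, not
the microscope.

## Numerical choices and edge cases

* Coordinates are 0-based voxel indices in (z, y, x) order; spacing in nm.
* Otsu bins span `[min, max]` of the data; ties in between-class variance
  resolve to the smallest threshold(s). Degenerate histograms (fewer than
  3 / 2 distinct values) raise typed errors rather than guessing.
* Hysteresis requires `t_low ≤ t_high`; labels are assigned in decreasing
  component-size order.
* Reconstruction uses the raster/anti-raster + FIFO hybrid algorithm, so
  whole-field extended maxima run in well under a second per stack.
* The smoothing kernel is truncated at 3 SD and renormalized; mirror
  boundaries keep the mean within 1% on finite fields.
* For a fixed seed, generation, rendering and the whole pipeline are
  bit-reproducible; per-field seeds are derived deterministically from
  the slide seed.

## Validation problem sizes

The recovery experiments run at a reduced field geometry of 12 × 512 ×
512 voxels with full-sized nuclei (≈ 6 nuclei per field), chosen so a
virtual slide of 500–1200 cells — the scale at which a Poisson mean is
pinned to ±3 SEM ≈ ±0.1–0.6 foci — renders and analyses in a few minutes
on one CPU. The full-geometry default (30 × 1040 × 1392, 20–50 nuclei
per field) behaves identically per nucleus; multiple fields per virtual
slide supply slide-level n either way. Statistical-layer checks
(law-of-large-numbers, type-I error of the t test, Tukey versus pairwise
p) run at n = 5000–10000 cells and 400–1000 replicates, where Monte-Carlo
tolerances of a few percent are meaningful.

## Known limitations

* Segmentation assumes separated nuclei; clumps are excluded, not split.
* A merged multi-peak maxima component counts as one focus.
* Three-state gating (separating S from G2 by DNA content) is out of
  scope; the EdU split is binary.
* The per-field versus per-cell choice of Otsu scope for segmentation is
  fixed to per-field; a per-crop variant would require the manual
  cropping this package exists to replace.
* Repair kinetics are summarised (percent remaining relative to the
  0.5 h peak), not model-fitted.
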