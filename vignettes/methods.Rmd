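---
title: "Methods: object-based synapse quantification in punctacoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based synapse quantification in punctacoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctacoloc)
```

## The problem

Structural synapses are routinely quantified in fluorescence microscopy by
immunostaining one presynaptic marker (e.g. Bassoon, VGluT1) and one
postsynaptic marker (e.g. Homer1, PSD95, Gephyrin) in different channels.
Because the two compartments face each other across a synaptic cleft far
below the diffraction limit, a presynaptic punctum that spatially overlaps
a postsynaptic punctum is counted as one synapse. `punctacoloc` implements
this object-based counting pipeline end to end: load and normalize images,
optionally denoise, threshold each channel into a foreground mask, detect
puncta as connected components, count red/green overlaps, and write a
per-image CSV summary. A built-in simulator with exact ground truth closes
the loop by measuring recall and precision of the whole pipeline.

## Pipeline model and assumptions

1. **Canonical representation.** Every analysis unit is a 3-plane 8-bit RGB
   image. Higher bit depths are rescaled by the *nominal* range
   (`v / (2^bits - 1) * 255`, round half up), never by per-image min–max,
   so conversion is data-independent and two runs of the same file always
   agree. Z-stacks are first collapsed by grouped maximum projection:
   consecutive groups of `group_size` optical planes (default 3, matching a
   1 µm projection at a 0.34 µm z-step) are reduced to their per-pixel
   maximum; a 15-plane stack yields 5 projections, each analyzed as its own
   image. Trailing planes that do not fill a group are dropped with a
   warning, because a partial projection would have a different effective
   depth.
2. **Puncta are small, bright and roughly circular.** Detection is
   connected-component analysis (8-connectivity, as in ImageJ particle
   analysis) of a thresholded mask, with an area filter and an optional
   circular region of interest. Objects within one channel are assumed
   non-overlapping; touching puncta are not split.
3. **Colocalization is geometric overlap**, not intensity correlation.
   Two methods are provided and should nearly agree on circular puncta:
   * *Circular approximation*: each punctum is modelled as the circle of
     its equivalent radius \(r = \sqrt{A/\pi}\) at its centroid. A red and
     a green punctum colocalize iff the centre distance satisfies
     \(d < r_1 + r_2\) (strict: tangent circles share zero area). The
     overlap area is the circle–circle lens computed by the sector
     construction (two circular sectors between the intersection points
     minus the two chord triangles). Counting is **per pair**: one record
     per qualifying red×green pair, so a punctum with several partners
     appears several times; the summary also reports a deduplicated count
     (distinct red puncta engaged) side by side.
   * *Pixel overlap*: the logical AND of the red and green masks (and
     optionally blue, for triple colocalization); each connected component
     of the overlap mask is one record. This makes no shape assumption and
     is the default analysis mode.

## Thresholding

Four methods produce the per-channel masks, and every call emits an audit
record (`image, channel, method, value`) collected into `thresholds.csv`:

* **fixed** — foreground is `intensity >= value`. The comparison is
  documented as inclusive because different conventions silently change
  counts.
* **from file** — a CSV of per-image, per-channel values; feeding a
  previous run's `thresholds.csv` back reproduces its `Summary.csv`
  byte-identically. This replaces interactive manual thresholding while
  preserving its reproducibility contract.
* **synquant** — a statistical spot detector in the spirit of the SynQuant
  family, re-implemented here in simplified form from its parameter
  semantics rather than ported. Candidates are connected components from a
  descending intensity sweep over all levels present; each is scored by the
  contrast z-statistic
  \[
  z = \frac{\bar I_{\mathrm{in}} - \bar I_{\mathrm{ring}}}
  {\sigma\sqrt{1/n_{\mathrm{in}} + 1/n_{\mathrm{ring}}}},
  \]
  against a 2-px surrounding ring, and accepted if `z >= z_threshold`
  (default 10) with area in `[min_size, max_size]` (10–100 px), fill factor
  ≥ 0.5 and bounding-box aspect ratio ≤ 4; defaults are the published
  settings for simulated synapse data with `noise_sd = 12`. Overlapping
  candidates are resolved greedily by descending z. Because z depends only
  on intensity differences, the mask is invariant to constant offsets. The
  `z_axis_multiplier` parameter is accepted for configuration parity but
  has no effect in 2D and warns when set.
* **external mask** — accepts masks or probability maps produced by outside
  tools (e.g. a trained pixel classifier); probabilities are binarized at
  0.5. Training and inference of such classifiers are out of scope.

## Preprocessing (off by default)

Optional noise reduction applies background subtraction then Gaussian blur;
optional brightness normalization maps the `(1 - f)` quantile to 255 so the
saturated-pixel fraction is equalized across images (default
`f = 0.0035`, the common enhance-contrast convention). Background
subtraction estimates the background as the grayscale morphological opening
with a flat disc of radius `rolling_ball_radius` (default 50 px, far larger
than any punctum so puncta survive) and subtracts it; a flat image maps to
zero and the output never exceeds the input. Preprocessing changes pixel
statistics, so it is disabled unless requested, and the applied
configuration is echoed in the run log.

## Puncta measurements

Each punctum records its 0-based centroid, area, equivalent radius and
circularity \(4\pi A / P^2\). The perimeter estimator matters for
circularity, so it is fixed and documented: corner-corrected crack length,
\(P = E - (2-\sqrt2)\,C\), where `E` is the number of exposed pixel edges
and `C` counts boundary corners from 2×2 neighbourhood configurations (one
or three foreground pixels, or two diagonal ones counting twice). Each
corner replaces two unit cracks by one \(\sqrt2\) diagonal, so a rasterized
radius-10 disc scores ≈ 0.95 while a 1×10 line scores ≈ 0.33. Values above
1 from discretization are clamped; a single pixel is defined as 1.

ROI membership is decided by the **centroid** (a punctum is counted exactly
once, and the rule is unambiguous at the ROI edge); the nominal area
\(\pi r^2\) of a circular ROI is reported even when it clips the image
border. For the pixel method the ROI is applied to the overlap components,
while per-channel puncta counts in the summary are ROI-filtered as well.

## The simulator and what it does (not) show

`generate_simulated_image()` reproduces the standard validation design:
1000 positions per 1024×1024 two-channel image — 334 red-only, 333
green-only, 333 with a red and a green punctum pasted at the same location
(the simulated synapses) — giving exactly 667 red and 666 green puncta of
ground truth per image. Puncta are radially decaying Gaussian-profile discs
(radius 2–6 px, peak 120–230, ten templates per channel), synthesized
rather than cropped from real micrographs so the package is
self-contained. Anchors are the top-left corners of the stamp bounding
boxes, sampled so same-channel boxes never overlap; at a shared position
the two channels' differing stamp sizes offset the centres by
\(\sqrt2\,|r_1 - r_2|\) px, producing the varying partial overlaps seen in
real data. Stamps are composited by pixelwise maximum with an i.i.d.
Gaussian background of mean `20·m` and sd `12·m` for noise multiplier
`m ∈ {0, 0.25, 0.5, 0.75, 1}`; the benchmark holds 20 images per level
(100 total), all seeds derived from one configuration seed.

Scoring matches detection centres to true synapse centres greedily by
increasing distance within a 5 px tolerance (one-to-one); matched
detections are TP, the rest FP, unmatched truths FN, with
recall = TP/(TP+FN) and precision = TP/(TP+FP). The tolerance and the
greedy rule are package choices — reasonable, documented, and fixed.

What passing these tests shows: the bookkeeping, geometry and detection
chain are correct on images whose puncta are bright, circular, and
non-overlapping within a channel on stationary Gaussian backgrounds. What
they do not show: performance on real tissue with autofluorescence,
uneven illumination, out-of-focus haze, non-circular or touching puncta,
or marker-specific staining artifacts — for those, thresholds must be
validated visually via the `_colocs` overlay images.

On the clean (multiplier 0) benchmark the pipeline with threshold 1 and
pixel overlap reaches recall ≈ 1.0 and precision ≈ 0.93: the false
positives are genuine chance adjacencies of red and green puncta that the
design does not count as synapses, which is also why precision stays below
1 in this kind of validation. At multiplier 1 a threshold of 1 floods the
mask and recall collapses — the expected degradation under excessive
background.

## Numerical choices

* Round-half-up (`floor(x + 0.5)`) everywhere an intensity is quantized;
  base R's round-half-to-even would make 8-bit conversion value-dependent
  in a surprising way.
* TIFFs are read through the normalized [0, 1] path and rescaled by
  `2^bits − 1`, which is exact for 8- and 16-bit data and independent of
  the file's photometric layout.
* 8-connectivity labelling is built as 4-connected labelling plus a
  union-find merge of diagonally touching labels — fully vectorized apart
  from the (small) label-pair loop.
* Degenerate inputs: empty masks give empty (not error) puncta tables;
  constant planes give empty statistical-threshold masks and are returned
  unchanged (with a warning) by brightness normalization; tangency and
  containment limits of the lens area are handled exactly; sub-pixel
  radius puncta cannot occur because `min_size >= 1`.
* Determinism: puncta are sorted by `(y, x)` before ids are assigned;
  CSVs are written identically for identical inputs, which is what makes
  the from-file replay byte-exact.

## Problem sizes in the shipped tests

The test suite validates the generator bookkeeping on the full 100-image
default benchmark and detection fidelity on 20 images each at noise 0 and
1; geometry is checked against the closed-form lens on 10^4 random triples
(1e-6 relative) and Monte-Carlo rejection sampling with 10^7 points per
triple (1e-3 relative); component detection is checked against a
brute-force flood-fill oracle on 100 random 64×64 masks; statistical
thresholding of pure noise uses 180×180 planes over 5 seeds. The whole
suite runs in a few minutes on one core.

## Known limitations

* 2D only: colocalization operates on single optical sections or
  max-projections, never across z.
* No watershed splitting of touching puncta; dense staining inflates areas
  and merges counts.
* The circular method mis-handles strongly non-circular objects — use the
  pixel mode there (it is the default).
* BMP input is not supported (no reader in the supported stack); convert
  to TIFF or PNG. Proprietary microscope formats must be exported to TIFF
  first.
* Intensity-correlation measures (Pearson, Manders) are intentionally out
  of scope; this package counts objects.
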