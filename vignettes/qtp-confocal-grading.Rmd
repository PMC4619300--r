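---
title: "Grading cervical epithelium from confocal images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading cervical epithelium from confocal images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtpcervix)
```

## The problem

Cervical intraepithelial neoplasia (CIN) changes both cell morphology and
tissue architecture: dysplastic epithelium shows larger nuclei, a higher
nuclear-to-cytoplasmic ratio, and reduced cell-to-cell distance. En-face
confocal fluorescence imaging of acriflavine-stained epithelium makes nuclei
appear as bright, roughly circular blobs on a darker cytoplasmic background,
so these changes become measurable in vivo without excision. This package
implements the complete measurement chain — nuclei segmentation, architecture
features, threshold grading, and diagnostic statistics — together with a
synthetic epithelium generator that provides exact ground truth for testing.

## Segmentation model

Nuclei are segmented in four stages:

1. **Edge detection.** A Canny detector: derivative-of-Gaussian gradients
   (scale `sigma_px`, default 1.5 px), non-maximum suppression along the
   quantised gradient direction, and double-threshold hysteresis in which
   weak edge pixels survive only when 8-connected to a strong pixel. The
   strong threshold is the `high_frac` quantile (default 0.9) of the nonzero
   gradient magnitudes and the weak threshold is `low_frac` (default 0.4)
   times that value. Percentile thresholds adapt to each frame's contrast
   without per-image tuning; the original workflow does not state numeric
   thresholds, so these defaults are engineering choices and both are
   exposed in `qtp_config()`.
2. **Hole filling** by morphological reconstruction: background regions not
   connected to the frame border become foreground, so closed nuclear
   contours become solid objects while open arcs are unaffected. An optional
   `bridge_px` dilation before filling (matching erosion afterwards) closes
   broken contours in low-contrast material; it is off by default because
   hysteresis already closes contours at the default contrast and bridging
   can merge tightly packed nuclei.
3. **Cleanup**: `n_rounds` (default 2) of erosion-then-dilation with a
   Euclidean disk structuring element of radius `se_radius_px` (default
   1 px), removing thin, non-nuclear edge responses. At the frame border,
   erosion ignores out-of-grid neighbours and dilation treats them as
   background.
4. **Quality filtering**, replacing manual object review: connected
   components are kept only when their centroid lies in the region of
   interest, their area falls in `[10, 200]` µm², and their solidity (pixel
   count over convex-hull pixel count, the hull count obtained exactly via
   Pick's theorem) is at least 0.7. Touching nuclei are *not* split: the
   source workflow describes no declumping, and grossly merged objects are
   caught by the area ceiling instead.

Coordinates follow one convention everywhere: pixels are `[row, col]`, and
the physical position of a pixel centre is `x = (col − 1) · pixel_size`,
`y = (row − 1) · pixel_size` in µm. The pixel size is a required calibration
input; the default 0.87 µm/px mirrors the stated lateral resolution of the
source instrument and is flagged as approximate.

## Architecture features

Let S be the set of nucleus centroids. The Voronoi tessellation assigns each
point p a cell V(p); the Delaunay graph connects two points exactly when
their cells share an edge. The package computes four features per specimen:

- **Mean nuclear area** (µm²), over all nuclei in the ROI.
- **Cell density** (nuclei per mm² of ROI). The source material is
  inconsistent about the unit (its feature table says per mm², its text per
  µm²); per mm² gives plausible magnitudes (hundreds to thousands) and is
  adopted.
- **ENC ratio**: the mean over interior cells of nuclear area divided by
  Voronoi cell area, the cell acting as a cytoplasm proxy. The source does
  not say whether the specimen value is a mean of per-cell ratios or a ratio
  of means; the per-cell mean matches the per-cell definition and is used.
- **3NDND** (µm): for each interior point with at least three Delaunay
  neighbours, the mean of its three smallest neighbour distances, averaged
  over qualifying points; points with fewer than three neighbours are
  excluded rather than padded.

**Boundary handling.** Cells that were unbounded or clipped by the ROI have
truncated cytoplasm estimates, so they are excluded from ENC and 3NDND but
still counted in density and nuclear area — their cytoplasm estimate is
unreliable, their existence is not. A point is "interior" exactly when
clipping left its cell untouched.

**Numerical choices.** The tessellation is built with `deldir` (with output
rounding disabled — the default 6-digit rounding costs ~1e-8 relative area
error, visible against closed-form checks), cells are clipped to the ROI
polygon with `polyclip`, and a cell wholly inside the ROI keeps its exact
unclipped area. Mask ROIs are traced into rectilinear polygons along pixel
edges, so clipped areas still sum exactly to the ROI area. Degenerate
co-circular point sets (where the Delaunay triangulation is not unique) are
accepted; zero-length Voronoi edges are dropped from the adjacency, and only
properties invariant to the tie-break are asserted in tests. Fewer than
three points, duplicated points, or a collinear set raise a geometry error
naming the condition.

## Grading and statistics

Thresholds published for the two discriminative features are applied as
three-class rules: ENC < 0.08 is normal, 0.08–0.18 low grade, > 0.18 high
grade; 3NDND > 25 µm is normal, 21–25 µm low grade, < 21 µm high grade. The
published bands are open at the cut points (no case falls exactly on one);
this package assigns ENC boundary values to the higher-risk side
(clinically conservative) and keeps the 3NDND low band closed on both ends,
following the published wording "between 21 and 25". Both cut pairs are
configurable.

Sensitivity and specificity are reported as **truncated** integer percents,
`floor(100·ratio)`: all four recomputable colposcopy benchmark values
(73/58, 75/69) match truncation of the underlying count ratios and not
rounding, so truncation is the contract. The ordinal association between
impression and histopathology is a mid-rank Spearman correlation computed on
the expanded pair list; the published coefficient (0.43) reproduces only
when histopathology is first collapsed to the three-level
normal/low/high ladder, so that collapse is the default (4-level coding is
available). Reactive atypia, where present in source data, is mapped to
normal before analysis. Group comparisons use one-way ANOVA with Fisher's
LSD post hoc test: pairwise t statistics from the pooled within-group mean
square, unadjusted for multiplicity — LSD is unadjusted by definition, and
no correction is applied anywhere.

## The synthetic cohort

No raw images or per-specimen features were ever deposited for this
analysis, so the generator defines the package's test bed. Nucleus centres
come from a *jittered hexagonal lattice with hard-core rejection*: lattice
constant `spacing_mean_um`, isotropic Gaussian jitter `spacing_sd_um`
(default 1.5 µm), points accepted in fixed order only when at least
`2·radius_mean_um` from all previous points. A hexagonal backbone — rather
than a Poisson process — reproduces the regular packing of squamous
epithelium that makes Voronoi cells meaningful cytoplasm proxies, and makes
the jitter-free case exactly solvable: the Voronoi cell is a regular hexagon
of area (√3/2)d², the ENC ratio is πr²/((√3/2)d²), and 3NDND equals d.

Grade geometry (spacing/radius 30/3.0, 23/4.0, 15/4.5 µm for
normal/low/high) was chosen once so that these closed forms land inside the
published threshold bands — ENC 0.036, 0.110, 0.326 against cuts 0.08/0.18;
3NDND 30, 23, 15 µm against cuts 25/21 — because the source reports bands,
not raw per-specimen features; its box-plot quantiles are not recoverable
from print. Nuclei render as disks (radius Gaussian, sd 0.3 µm, floored at
0.5 µm) at gray 180 over background 40, blurred with a 0.5 µm Gaussian
point-spread and overlaid with additive Gaussian noise (sd 6 gray levels,
≈4% of contrast), clipped to [0, 255]. The default field of view is 445 µm
(a 512-pixel frame at 0.87 µm/px). All randomness flows from one seed per
specimen; cohort seeds derive deterministically from a base seed, and
identical spec + seed is bit-identical by construction.

What the generator does **not** emulate: depth-dependent attenuation and
dye penetration, multi-layer stratification, out-of-focus light, irregular
nuclear shapes, chromatin texture, inflammation, and imaging artefacts such
as stitching or motion. Passing the synthetic suites therefore demonstrates
that the measurement chain is correct and well-behaved under controlled
morphology — it does not certify clinical performance; the published
real-data accuracies are not reproducible without the original images.

## Problem sizes used in the checks

The regression suites run the full-size default cohort (10 specimens per
grade at 445 µm field) for segmentation recovery and grade separation;
geometry oracles use 20 random point sets of up to 50 points against a
0.25 µm nearest-point raster (refined 4× where the raster's own
quantization exceeds the 1% comparison band); unit tests use 150 µm fields
for speed. The Fisher-LSD calibration uses 500 Monte-Carlo replicates of
three groups of 20 with a 2-sd shift.

## Known limitations

- Tile clipping against strongly non-convex mask ROIs assumes a cell with
  every vertex inside the ROI is wholly inside; a cell spanning a narrow
  notch could be misflagged interior.
- Solidity from convex-hull pixel counts is slightly optimistic for objects
  a few pixels across; such objects are governed by the area filter anyway.
- The threshold classifier is fixed, not fitted: no ROC optimisation is
  attempted, matching the source's fixed-band design.
- Colposcopic impression is not simulated; impression-based statistics run
  only on the packaged printed contingency table.
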