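---
title: "Quantifying microvascular architecture with reaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvascular architecture with reaver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reaver)
```

## The problem and the approach

Fluorescently labeled microvascular networks — for example retinal vessels
labeled with IB4 lectin and imaged by confocal microscopy as
maximum-intensity projections — are routinely quantified by four
architectural metrics: vessel length density (mm of vessel per mm² of
tissue), vessel area fraction, mean vessel diameter (µm), and branchpoint
count. `reaver` implements the REAVER (Rapid Editable Analysis of Vessel
Elements Routine) two-stage pipeline for computing these from a
single-channel 2D image:

1. **Segmentation.** The image is lightly blurred (3×3 averaging — the
   8-pixel neighborhood), a background estimate is formed with a heavy
   averaging filter (default 128 px), and the difference is thresholded
   (default 0.045 on the unit intensity scale). The binary mask is then
   cleaned: an 8-neighborhood filter keeps pixels with ≥ 4 true neighbors,
   8-connected components smaller than 1600 px are removed, borders are
   smoothed with an 11-square local-majority filter, holes under 800 px are
   filled, one thinning iteration compensates the net one-pixel dilation of
   the smoothing steps, and the component-area filter runs once more.

2. **Skeletonization and refinement.** The mask is pre-smoothed (eight
   set-if-4-neighbors passes, four bridge+fill pairs, one 3×3 majority
   filter, holes under 80 px filled) and thinned to a unit-width centerline
   with replicate padding, so vessels crossing the field of view keep
   centerline pixels at the border. The Euclidean distance transform (EDT)
   of the *stage-one* segmentation, sampled at centerline pixels, gives the
   local vessel radius; the centerline is cut at branch pixels into
   segments, segments with mean radius below the thickness threshold
   (default 3 px) are pruned, junctions touched by at least two surviving
   segments are restored, and a spur/clean/thin pass finishes. Branchpoints
   and endpoints are reported away from the outermost row/column, where edge
   effects produce false positives.

Metrics follow directly: area fraction is the true-pixel fraction; length
density is the centerline pixel count converted through the pixel size (no
diagonal correction — that is how the metric is defined); mean diameter is
the average of `2·EDT − 1` over centerline pixels times the pixel size;
branchpoints are counted once per junction cluster.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `averaging_filter_size` | 128 | px | background (low-frequency) estimate |
| `grey_to_binary_threshold` | 0.045 | unit intensity | initial segmentation |
| `min_connected_component_area` | 1600 | px | reject non-vessel blobs |
| `wire_dilation_threshold` | 0 | px | optional mask dilation before skeletonization |
| `vessel_thickness_threshold` | 3 | px (radius) | prune thin centerline segments |
| `light_blur_size` | 3 | px | pre-threshold denoising blur |
| `hole_fill_area_seg` / `hole_fill_area_centerline` | 800 / 80 | px | hole filling |
| `smooth_filter_size` | 11 | px | local-majority border smoothing |

At 20× (128 px ≙ 40 µm, i.e. 0.3125 µm/px) the 3-px thickness threshold is
0.9 µm and the 11-px smoothing filter 3.4 µm; at 60× (128 px ≙ 27 µm) they
are 0.6 µm and 2.3 µm. Intensities are always normalized by the dtype
maximum at load, which is what makes the printed 0.045 threshold meaningful
for both 8- and 16-bit input. The pixel size is user-supplied rather than
parsed from file metadata, whose dialects are unreliable.

**The light blur.** The light "averaging filter with an 8-pixel
neighborhood" is implemented as a 3×3 kernel (the eight neighbors plus the
center), not an 8×8 box. The choice is forced by geometry as much as by
wording: a box filter of width k turns a tube edge into a k-px ramp, and a
low threshold like 0.045 crosses that ramp far down its tail — with an 8×8
light blur every vessel boundary would be pushed out by about 3 px per side,
which the single compensating thinning iteration cannot undo. With a 3×3
kernel the crossing sits about one pixel outside the edge and the thinning
iteration restores the drawn width to within a fraction of a pixel.

**Numerical conventions.** Box filters use exact integral-image means with
edge-replication padding (zero padding would create dark borders that the
background subtraction would segment); even sizes anchor the window origin
at `floor(k/2)`. Thresholding is strict (`>`). Foreground connectivity is 8,
hole connectivity 4. The threshold comparison of the majority smoother
(`> 0.5` on the complement fraction) has a discrete margin of 1/k², so
floating-point summation error cannot flip it.

## The thinning operator

`bwmorph_op(kind = "thin")` is a homotopic thinning. Every deletion is
gated on an exact (8,4)-simplicity test — the pixel's true neighbors must
form one 8-connected group and its background neighbors one 4-connected
group adjacent to it, with off-image cells counting as background (the
image embedded in an infinite background plane, as in MATLAB's `bwmorph`) —
plus endpoint protection. Candidates are applied in four parity waves with
re-checks against the current mask; pixels of equal row/column parity are
never adjacent, so each wave is equivalent to deleting its pixels one at a
time, and every deletion is a simple-pixel deletion. Consequently thinning
preserves the number of 8-connected foreground components and of background
4-components exactly, and the fixed point is idempotent.

A finite number of iterations runs Guo–Hall-style subiteration cycles,
each peeling about one boundary layer per side — which is exactly what the
segmentation stage's single compensating iteration needs. Thinning *to
convergence* is distance-ordered instead: simple pixels are deleted in
increasing order of their distance-transform value, so the surviving
centerline follows the ridge of the distance transform. Plain layer
peeling can shear the skeleton off the ridge in corridors between nearby
junctions; the off-ridge pixels then sample spuriously small radii and the
thickness pruning deletes whole inter-junction pieces. Both schemes delete
only simple non-endpoint pixels, so they share their fixed points.

One caveat is documented rather than hidden: a 2×2 block whose four corners
each anchor a diagonal arm is *irreducible* — deleting any of its pixels
either disconnects an arm or creates a hole, so no topology-preserving
thinner (MATLAB's included) can reach unit width there. Such configurations
arise in dense random masks but not in smoothed vessel segmentations. The
package's guarantee is sharp: any 2×2 block that survives thinning contains
no simple pixel, i.e. unit width is achieved whenever a unit-width homotopic
representative is reachable by pixel deletions.

**Branchpoint clusters.** On an 8-connected unit-width skeleton a digital
junction is usually a small cluster of 2–4 mutually adjacent pixels with
≥ 3 neighbors each (a T-attachment makes the two flanking spine pixels
diagonal neighbors of the branch pixel). Counting raw ≥ 3-neighbor pixels
therefore over-counts junctions up to threefold. `find_branchpoints()`
reports one representative per 8-connected cluster, which makes the count
equal the number of graph junctions on well-separated networks; segment
splitting still removes all ≥ 3-neighbor pixels. For the same reason,
pruning restores junction pixels per cluster (a cluster returns iff at
least two surviving segments touch it) — per-pixel restoration would leave
junction chains broken, disconnecting the network.

## The phantom generator

`generate_phantom()` builds networks of straight tubes with analytic ground
truth: the segmentation truth is the union of stadium footprints (pixels
within diameter/2 of a tube axis), the centerline truth the thinned
rasterization of the axes, and the expected metrics follow from arc
lengths, drawn diameters (arc-length weighted, which is what a
centerline-pooled estimator measures) and the junction count. Rendering
emulates a maximum-intensity-projection confocal field: a dim background
(0.05) with a low-frequency gradient (amplitude 0.1, plane plus sinusoid —
this is what the heavy background filter must remove), a bright plateau
(0.8) on the tube footprint, a small optical blur (Gaussian, σ 0.5 px over
a 2-px support; MIP confocal capillary edges span about a pixel), and
optional additive Gaussian noise. Diameters are drawn as odd pixel values
in 7–15 px (capillaries to small venules at ~1 µm/px), because the
`2·EDT − 1` estimator recovers odd widths exactly on axis-aligned tubes.

The default tree is axis-aligned: a horizontal trunk with exactly
perpendicular branches (lengths 110–200 px, junctions ≥ 24 px apart,
24-px margins, non-parent clearance checks). An `angle_jitter_deg`
parameter adds uniform angular jitter when set. The default is 0 because
tilt probes the *metric definitions*, not the pipeline: pixel-count length
under-counts a θ-tilted digital line by 1 − max(|cos θ|, |sin θ|) (≈ 3.4%
at 15°, 29% at 45°), and the `2·EDT − 1` diameter estimator carries a
−0.4 to −1.4 px bias on tilted tubes (background pixel centers graze the
band boundary, and the digital skeleton zigzags off the ridge). On
axis-aligned phantoms the analytic truth is exact, so a recovery failure
indicates a pipeline defect rather than discretization of the definitions.
Branch lengths are kept long relative to tube caliber — as in real
microvascular fields — because skeletons pay fixed costs of roughly half a
radius of end-retraction per free tip and a few diagonal-shortcut pixels
per junction.

What passing phantom tests does *not* show: recovery of curved or
anisotropically oriented vessels, performance under structured noise
(autofluorescence, bleed-through, out-of-focus haze), crossing vessels from
different z-planes collapsed by the projection, or intensity variation
along a vessel. The phantoms validate the machinery, not the biology.

## Evaluation module

Pixel confusion counts compare a predicted mask against ground truth;
scores are accuracy (TP+TN)/total, sensitivity TP/(TP+FN), specificity
TN/(TN+FP), and additionally precision TP/(TP+FP) (reported as
`precision_ppv`, so both common readings of a "sensitivity" figure are
available). Per-image error statistics are the signed error E = Y − G, the
absolute error |E|, and the Brown–Forsythe precision residual
|E − median(E)| (median of the two central order statistics for even n).
Inferential statistics (paired tests, multiple-comparison corrections,
agreement plots) are deliberately out of scope; the tables returned are
ready for any standard stats package.

## Known limitations

* The `wire_dilation_threshold` parameter is retained for interface
  compatibility; with its default 0 it is a no-op, and when positive it
  dilates the mask by that many 3×3 passes before skeletonization.
* Length density uses raw pixel counts by definition, so oblique vessels
  are under-measured by up to 29%; diameters of tubes far from axis
  alignment are under-measured by up to ~1 px (see above).
* A 3-px thickness threshold prunes whole capillary branches whose mean
  radius is marginally below 3 px; with 7-px tubes the measured mean radius
  (~3.2–3.4 px after digitization) sits close to that threshold.
* The spec-fixed 3×3 majority step of skeleton pre-smoothing erases
  structures a single pixel wide before thinning; a 1-px filament therefore
  never reaches the centerline regardless of the thickness threshold.
* Test-suite problem sizes: phantom recovery runs ten 512×512 trees
  noise-free plus ten with noise; morphology oracles run on ≤ 16×16 masks
  and the thinning contract on 32×32 masks, 100 draws each.
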