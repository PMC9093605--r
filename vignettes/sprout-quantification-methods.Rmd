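---
title: "Quantifying spheroid sprouting: the model behind sproutquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid sprouting: the model behind sproutquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutquant)
```

## The measurement problem

In the spheroid sprouting assay, endothelial cells aggregated into a
spheroid are embedded in a gel and sprout radially toward angiogenic
stimuli. A fluorescence image of one spheroid shows a bright, roughly
circular body and dimmer, curvilinear sprouts; some sprouts detach and
appear as isolated fragments on the focal plane. The quantities of
interest per spheroid are the total and sprouting areas, the number of
sprouts split into *attached* and *migrated*, and the cumulative sprout
length (CSL) — the total extent of the sprout network.

Tools built for the related fibrin bead assay anchor their segmentation
on the microcarrier bead's circular outline; spheroids have no bead, so
this pipeline instead segments the body and sprouts jointly from edge
density and separates the body afterwards by brightness.

## Pipeline and parameters

All tunables live in one `sprout_config()` object; defaults below.

**Segmentation of the total spheroid.** The image (normalized to
[0, 1] by the acquisition bit depth, never the per-image maximum, so
thresholds are comparable within a plate) is median-filtered (kernel
1 px — the identity, kept configurable for noisy acquisitions),
contrast-enhanced by contrast-limited adaptive histogram equalization
(8×8 tiles, clip 0.01 of the histogram bins), and edge-segmented with
3×3 Sobel kernels. The gradient magnitude is binarized at twice its
root-mean-square — the classical automatic Sobel cutoff; at half that
value, equalization-amplified background noise floods the edge mask.
The sparse edge mask is then spread by convolution with a unit-sum
Gaussian (support 100 px, σ = 1 px) into an edge-density image, and
thresholded at

$$t = \mathrm{median}(v_{\neq 0}) + 0.3\,\mathrm{SD}(v_{\neq 0})$$

over its nonzero values (sample SD, strict `>` comparison, so a flat
plateau keeps nothing). Holes are filled — the spheroid body is solid
tissue and the area metric is a region area — and mask components below
50 px are dropped: that is the approximate mask footprint of the
smallest skeleton component the later stages can count (6 px of
centerline at minimal sprout width plus edge fattening), so smaller
specks can only ever be noise. Detached sprout fragments form their own
mask components and must survive this stage; a largest-component-only
mode exists (`keep_largest_component`) for crops that catch pieces of
neighboring spheroids, but it is off by default precisely because it
would erase migrated sprouts.

**σ of the spread.** The spread exists to close gaps at the scale of
the structures (a sprout half-width, one to two pixels at 2 µm/px).
Making σ comparable to the inter-sprout spacing instead (tens of
pixels) fuses neighboring sprouts into single lobes and inflates every
area, which is why the default is deliberately small relative to the
100-px kernel support.

**Spheroid center.** The body is by far the brightest structure, so the
center is the largest connected region of pixels ≥ 90 % of the maximum
of an 11×11-median-smoothed image (the even 10×10 neighborhood has no
central pixel; the nearest odd size is used), dilated by a 5-px disc to
cover the body's dim rim and clipped to the total mask. A constant
image degenerates gracefully: everything is "brightest", the center
equals the total mask and the sprouting area is empty.

**Sprouting area** is the exact set difference total \ center; the
three masks always partition, and this is asserted at run time, not
assumed.

**Skeleton.** The total mask is thinned (Guo–Hall, run to its fixed
point) — the total rather than the sprouting area, because the center
is subtracted *from the skeleton* next, which removes skeletal "sprout
extensions" inside the body; subtracting the center from a skeleton of
the already center-free sprouting area would be a no-op. The subtracted
skeleton is dilated with a diamond (L1 ball) of radius 2, bridging gaps
of up to 4 px left by the subtraction, re-thinned, and pruned of
branches under 10 px (long enough to remove thinning artifacts at the
component-filter scale, short enough to keep real sprouts, which are
tens of pixels at 2 µm/px). Components under 6 px are then discarded;
a component of exactly 6 px is kept, reading the filter threshold as
the retained minimum.

**End behavior of the refinement.** Re-thinning a diamond-dilated curve
mishandles open ends by one or two pixels in a direction-dependent way
(the thinning either traces into the pointed cap or stops short of it),
so dilate-and-rethin alone has no fixed point — ends creep indefinitely.
`refine_skeleton()` therefore pins every open end back to the
pre-dilation skeleton's own end pixels (retracting overgrowth, restoring
dropped end pixels), which makes the operator exactly idempotent — a
property the test suite asserts on synthetic pipeline skeletons, not
just on straight-line fixtures.

**Counting and classification.** A sprout is a connected component of
the final skeleton (8-connectivity, configurable to 4). A component
touching the center mask — within the skeleton's own bridging distance
(`diamond_radius`) plus one diagonal step, since thinning retracts ends
a pixel or two — is *attached*; otherwise it is *migrated*. Attachment
cannot be resolved across focal planes: a "migrated" sprout may be
attached on another z-slice, and intensity projections are not used
because the bright body smears into a halo. CSL is the foreground pixel
count of the final skeleton (not a Euclidean polyline length), times
2.0 µm/px by default.

Because counting is component-based, two sprouts branching from one
trunk count as one. This undercounting is characteristic of the method
and is pinned by a Y-shaped fixture in the tests rather than patched,
so the package's counts remain comparable with the method family it
implements.

## The synthetic ground-truth generator

`generate_spheroid()` renders the phenotype the pipeline expects: a
full-intensity core disk (radius 40 px in a 512×512 frame), `n`
bounded-curvature random-walk centerlines seeded on the core boundary
at angular spacing at least half the even spacing, drawn at intensity
0.5 and dilated to 3 px width; optional detached fragments (20–40 px)
at least 30 px clear of the core; and additive Gaussian noise
(σ = 0.03) clipped to [0, 1]. Ground-truth lengths are the exact pixel
counts of the rasterized centerlines, so pipeline CSL is compared
like-for-like. Distinct centerlines keep a minimum clearance of 8 px
outside the core rim (walks violating it are redrawn): sprouts that
genuinely merge have no well-defined separate ground truth, and the
assay's sprouts are near-radial and rarely cross. Identical specs and
seeds render bit-identical images.

What the generator does *not* emulate: the microscope's point-spread
function, uneven illumination, gel autofluorescence texture,
out-of-focus halos, and touching neighbor spheroids. Passing the
synthetic recovery studies therefore demonstrates the pipeline's
internal correctness and its contrast-based segmentation contract, not
performance on any particular microscope's output; on real data the
free parameters most likely to need adjustment are `sobel_sensitivity`,
`center_bright_fraction` and `min_mask_area_px`.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run, per seed: a 100-raster
(32×32) comparison of the adaptive threshold against a brute-force
median + sample-SD oracle; a 20-image recovery study at the generator
defaults above, scoring exact attached-count recovery and CSL within
±15 % of ground truth; a migrated-detection study adding 1–3 detached
fragments to seven of those fixtures; the Y-fixture undercount; and a
byte-identity check of two batch runs over the same directory. These
sizes keep a full run in the low minutes on a single core while still
crossing every module boundary end to end.

Numerical notes: convolution is FFT-based with zero padding, and
magnitudes below 1e-10 are snapped to zero so the nonzero-value
statistics see the same support a direct convolution would produce;
the CSL bias is mildly negative (median ≈ −10 %) because the center
subtraction removes each sprout's first few pixels and thinning
retracts tips slightly — consistent, seed-stable, and well inside the
±15 % acceptance band.

## Known limitations

- Branch-sharing sprouts are counted once (by design, see above).
- Attachment is a single-plane statement.
- Sprout width, individual sprout lengths, and branch-point statistics
  are out of scope; the skeleton is summarized only as components and
  total length.
- Touching spheroids in one frame are not separated; crop first
  (`cmd_crop()` replaces interactive cropping with declarative
  rectangles for reproducibility).
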