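---
title: "Overlay augmentation for slide-preview tissue detection: methods and design"
author: "overlayAug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlay augmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlayAug)
```

## The problem

Whole-slide scanners photograph every glass slide at low resolution (a few
megapixels) before scanning, and a tissue-detection model segments the
specimen on that preview to plan the scan area and focus points. Slides in
routine practice carry non-tissue content — felt-pen markings drawn by
pathologists, air bubbles trapped in the covering glue, dirt speckles, and
brand marks — and these artifacts both mislead the detector and capture the
autofocus. Annotated previews showing artifacts are rare, so detectors
trained on mostly clean slides fail exactly where robustness matters.

Overlay augmentation addresses the data scarcity directly: artifact
instances are extracted once from labeled slides, transformed with seeded
random operators, and composited onto clean annotated previews. Every
augmented image inherits its source's tissue mask unchanged, so a large,
artifact-rich training set is produced without any new manual labeling.

## The compositing model

Preview images are `M x N x 3` arrays of 8-bit intensities with 0-based
`(x = column, y = row)` coordinates. In brightfield imaging an artifact
absorbs light, so compositing subtracts the artifact's *negative* from the
preview, clamped at black:

    I_out(x, y, c) = max(0, I_in(x, y, c) + I_over(x~, y~, c) - 255)

Overlays are stored in *canonical white-background form*: every pixel
outside the artifact mask is 255 on all channels, which makes the blend an
identity there — the masked-negative subtraction needs no conditional. Two
consequences used throughout the tests: the output never exceeds either
input (higher intensities always win), and pixels outside the artifact
footprint are bit-identical to the input.

Placement handles each axis independently. An overlay narrower than the
preview gets a uniform integer offset `x0` in `[0, N - w]`; a wider overlay
sits at `x0 = 0` and a uniform crop start in `[0, w - N]` selects the
visible window (and symmetrically in y). Every size combination therefore
has a valid placement. Uniform draws are a choice: the method's description
of the offsets says only "random"/"arbitrary".

## The seven transforms

Geometric transforms act on patch and mask together; content transforms act
on the *strength* `S = 255 - patch` inside the mask and never touch a pixel
outside it.

| transform | parameter, default sampling range | notes |
|---|---|---|
| scaling | factor in \[0.75, 1.25\] | dims `floor(d * f + 0.5)`, min 1; patch bilinear, mask nearest then re-binarized |
| rotation | integer angle in \[0, 359\] | canvas expands to the rotated box; multiples of 90 are exact index permutations |
| mirroring | axis in \{none, horizontal, vertical, both\} | |
| hue | integer in \[0, 180\] half-degrees | masked pixels to HSV, hue replaced, S and V kept to 8-bit rounding |
| scratch | count in \{1..10\}, factor in \[0, 0.2\] | one-pixel lines between two distinct random edges; factor map blurred 3x3; strength multiplied on line-mask intersections |
| Perlin fade | weight in \[0, 1\] | strength times `1 - weight * noise`; frequency 4, normalized, optional threshold |
| intensity | factor `sqrt(u)`, u in \[0.3, 0.7\] | strength multiplied by the factor |

Content transforms (hue, scratch, Perlin, intensity) model properties of
translucent ink and are applied to felt-pen overlays only by default;
`contentCategories` in `augmentationConfig()` widens that (e.g. to bubbles)
when wanted.

Decisions taken where the procedure is genuinely open:

* **Order.** The transforms are described as independent, with no order
  given. A fixed order — scale, rotate, mirror, hue, scratch, Perlin,
  intensity — is required for a parameter draw to reproduce its overlay
  bit-exactly; geometric-before-content keeps the content operators acting
  on the final pixel grid.
* **Strength space.** Whether intensity scaling multiplies the patch or its
  negative is ambiguous in prose; the package multiplies the negative
  (strength). Physically, scratches and fading let light through, so these
  operators can only *lighten* the marking — a property the tests assert
  pointwise. Scaling the patch itself would darken it instead.
* **Scratch details.** The per-line factor is constant along a line (the
  alternative, per-pixel, is noisier than any real scratch). The factor map
  is zero away from lines, the 3x3 blur is a mean (box) filter, and the
  attenuation applies on the unblurred line pixels intersected with the
  mask — so a factor of 0 erases the ink on the line core exactly, and no
  pixel outside the mask ever changes.
* **Rotation fill and angle 0.** Exposed corners after rotation fall
  outside the rotated mask, so the fill value is irrelevant after
  re-canonicalization; angle 0 and mirror axis `none` are legal draws
  (identity is a valid augmentation).
* **Hue 180.** Half-degree hue values live in `[0, 180)`; 180 is accepted
  and treated modulo 180.

Randomness is explicit: a `TransformParams` object carries every sampled
value plus integer sub-seeds for the scratch geometry and the Perlin
gradient field, so the chain has no hidden randomness and any augmentation
can be replayed from its provenance record (`replayRecord()`).

## Artifact extraction and the bank

Labeled artifact images use the same convention as annotated previews: a
binary mask, white ROI on black. `extractArtifacts()` splits the mask into
8-connected components (felt-pen strokes are thin diagonals; 4-connectivity
would fragment them), drops components under `minArea = 9` pixels (labeling
specks), and crops each to its bounding box plus a 2-pixel margin so later
3x3 blurs never touch a crop border. Whole-mask extraction
(`splitComponents = FALSE`) is available since a labeled image could also be
read as one compound artifact. Banks round-trip through a plain directory
layout (`<category>/<id>.png` + `.mask.png` + `manifest.json`).

## Masks, metrics, conventions

The tissue mask is *never* modified by augmentation: artifacts are
background for the segmentation label, and the detector is trained to find
tissue despite them. Masks binarize at the 127 midpoint (guarding against
antialiased hand labels); 0/1-valued masks normalize to 0/255.

Validation metrics are pixel counts between predicted and ground-truth
masks: sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1
`2TP/(2TP+FP+FN)`, and IoU `TP/(TP+FP+FN)` for training monitoring. A zero
denominator yields 0 by default (the worst-case reading; empty masks are
never evaluated in practice), with `empty = "one"` available for the
both-masks-empty convention. Per-category aggregation reports per-image
means with the population standard deviation (divide by n); sample standard
deviation and pooled-pixel metrics are flags. F1 and IoU satisfy
`F1 = 2 IoU / (1 + IoU)` for all counts, which the tests exploit as an
internal consistency check.

## The synthetic fixture generator

`generateCleanPreview()` emulates what the method assumes about scanner
previews, at configurable scale (default 512 x 1024, height x width —
slides are landscape): a near-white field with smooth Perlin texture, an
optional darker label area at the left edge, and 1-3 tissue blobs built as
Perlin-perturbed ellipses filled with a stain-like base color
(eosin-pink/hematoxylin-purple defaults) plus smooth jitter. The mask is
the exact union of painted blob supports. `generateSyntheticArtifact()`
produces the four categories: saturated translucent strokes (felt pen), a
bright disk with a darker thin ring (bubble), scattered dark speckles
(dirt), and dark glyph-like rectangles (brand mark).

What the fixtures do *not* model: real tissue morphology and texture, stain
variability, illumination falloff, compression noise, or the visual
complexity of real artifacts. Passing tests on fixtures therefore establish
the *algorithmic* contracts — blend arithmetic, mask discipline, placement
law, determinism — not detection performance on clinical data, which
requires a real archive and model training (both outside this package's
scope, as is the U-Net itself: the package emits image/mask pairs any
segmentation trainer can consume).

## Pipeline and reproducibility

`prepareDataset()` resizes annotated previews to a fixed working resolution
(default 512 x 1024; images bilinear, masks nearest-then-binarized) and
splits ids 80:20 into training and validation after a seeded shuffle
(`floor(n * ratio)` train), with an optional held-out test fraction removed
first. `runAugmentation()` co-emits originals with every augmented copy
(augmentation extends the training set), writes footprint masks and
JSON-lines provenance, and seeds each sample hierarchically: master seed
plus sample-id hash gives every sample its own stream, so serial reruns —
and any future parallel ones — are byte-identical. Two runs with the same
seed and configuration produce identical output trees; the test suite
checks this by checksum.

Problem sizes in the shipped tests were chosen to exercise every code path
quickly: random 64 x 64 previews against a per-pixel loop oracle for the
blend, 10,000 draws for placement and parameter-range laws, and a 20-sample
fixture dataset at full 512 x 1024 resolution for the end-to-end
determinism check.

## Known limitations

* The compositing model is subtractive and thus strictly darkening;
  reflective artifacts (glints) are out of scope.
* Overlapping overlays blend sequentially, equivalent to clamped summed
  strengths; no physical model of stacked translucent media is attempted.
* The Perlin `octaves` parameter is a single lattice frequency (matching
  the noise library the method builds on), not a multi-octave fractal sum.
* Hue replacement round-trips through 8-bit RGB; saturation and value are
  preserved only to one intensity level, and repeated application is stable
  to the same tolerance rather than bit-identical.
* `EBImage` supplies interpolation for resize and non-axis rotations;
  interpolated pixel values are therefore library-defined (the contracts
  tested are dimensional and mask-consistency ones, plus exactness at
  multiples of 90 degrees).

```{r example, eval = FALSE}
## minimal end-to-end run
pv <- generateCleanPreview(fixtureSpec(dims = c(128L, 256L), seed = 42L))
bank <- artifactBank(list(
    generateSyntheticArtifact("felt_pen", c(48L, 48L), seed = 7L),
    generateSyntheticArtifact("bubble", c(40L, 40L), seed = 8L)))
res <- augmentSample(pv, bank, augmentationConfig(), seed = 99L)
stopifnot(identical(tissueMask(res$sample), tissueMask(pv)))
segMetrics(res$footprint, tissueMask(pv))$iou  # artifact/tissue overlap
```
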