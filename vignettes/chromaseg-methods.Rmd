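---
title: "Methods: histogram-seeded segmentation and luminance-matched colorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histogram-seeded segmentation and luminance-matched colorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaseg)
```

## The problem

T2-weighted brain MR slices show three dominant tissue classes — gray
matter (GM), white matter (WM) and cerebrospinal fluid (CSF) — as three
modes of the gray-level histogram, sitting above a large near-zero
background. Iterative clustering methods (K-means, fuzzy C-means, EM)
segment such images by repeatedly re-estimating cluster centroids, which
costs iterations and depends on random initialization. chromaseg instead
selects centroids *once*, directly from the histogram, using prior
anatomical knowledge of where each tissue's intensities live on a T2
image, and then classifies every voxel in a single pass. A second,
independent tool colorizes any 8-bit gray medical image by borrowing
chromaticity from a color-spectrum palette while preserving each pixel's
own luminance.

## Automatic centroid selection

For each plane $z$ of the volume the pipeline is:

1. **Histogram** $h_z(g)$, exact counts over $g = 0..255$
   (`compute_histogram()`).
2. **Peaks**: strict local maxima $h(g-1) < h(g) > h(g+1)$; a plateau of
   equal counts flanked by smaller counts yields one peak at its lower
   median; $g = 0$ and $g = 255$ are never peaks, so the background bin
   cannot pose as a tissue mode (`find_peaks()`).
3. **Pruning**: peaks below 5% of the highest peak count are discarded as
   noise spikes (`prune_peaks()`, fraction configurable).
4. **Merging**: scanning in ascending gray order, any peak closer than 10
   gray levels to the last survivor is merged into it, keeping the
   higher-count peak (ties keep the lower gray level) and rescanning from
   the survivor (`merge_peaks()`). The output is pairwise separated by at
   least the threshold, which makes both pruning and merging idempotent.
5. **Selection**: within each anatomical window — GM 45–85, WM 86–140,
   CSF 141–255 on T2 — the surviving peak with the highest count becomes
   that region's centroid (`select_centroids()`).

The minimum separation of 10 gray levels must exceed noise-level histogram
jitter yet stay far below the ~45-level spacing of the anatomical windows;
the 5% pruning fraction is the conventional minor-peak cutoff. Both are
arguments, not constants. Degenerate planes fall back gracefully: a window
containing counts but no surviving peak uses the raw histogram argmax
there; a window with no counts at all uses the window midpoint and warns.
These fallbacks keep batch runs alive on slices where a tissue is truly
absent (e.g. extreme apical slices).

## Single-phase classification

With centroids $C(z, r)$ fixed, each voxel $V(x, y, z)$ receives the label
$\arg\min_r |V(x,y,z) - C(z,r)|$ (`assign_hard()`); ties break to the
lowest region index, and voxels darker than the GM lower bound (45 by
default) form an optional background class 0. The pass never updates the
centroids — that is the point of the method. 3D volumes are handled
per-plane with per-plane centroids (a `global` option pools the plane
histograms instead, for volumes whose slices should share centroids).

Soft segmentation returns graded memberships
$u_r \propto (|V - C_r| + \varepsilon)^{-2}$, normalized over regions,
with $\varepsilon = 10^{-6}$. The functional form (inverse-square
distance, equivalent to a fuzzy-C-means membership with fuzzifier 2 at
fixed centroids) is this package's choice; its argmax provably matches the
hard labels away from exact ties, and an exact centroid hit yields a
membership of essentially 1. `extract_region()` produces per-tissue images
either by masking (hard) or by intensity-weighting with the membership
(soft), so more opaque pixels are the more confidently classified ones.

## Evaluation: the volume Jaccard coefficient

Segmentations are compared region-wise through
$J_c = |V_1 - V_2| / (V_1 + V_2)$ on voxel counts, reported to 8 decimals
(`jaccard_volume()`, `compare_methods()`). This is a volume-difference
ratio, not a spatial-overlap index: two segmentations of equal size but
disjoint support would still score 0. It is, however, exactly the
coefficient that accompanies published per-region volume tables for this
method family, and the package reproduces every such printed coefficient
from its printed volume pair to all printed decimals (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

## Luminance-matched colorization

The colorizer works in CIELAB. For a gray pixel of value $g$:

1. Its luminance on the NTSC YIQ scale is $L = 0.299R + 0.587G + 0.114B =
   g$ for the triple $(g,g,g)$.
2. The palette entry with luma nearest $L$ is selected (Euclidean distance
   on the 0–255 luma axis; ties to the lower luma). A match within the
   criterion $C_1 = 3.4$ counts as successful; beyond it the configurable
   fallback applies (nearest entry by default, or an error).
3. The output pixel is the sRGB rendering of
   $(L^*_{gray}, a^*_{entry}, b^*_{entry})$: the pixel keeps its own
   CIELAB lightness and adopts only the entry's chromaticity.

Because the output is a pure function of $g$ given the palette, the
implementation precomputes a 256-entry lookup table; tests assert it
equals the scalar per-pixel definition exactly. The default $C_1 = 3.4$ is
roughly half the band spacing that divides a 200-entry luma-spanning
palette into the ~38 perceivable bands needed to tell apart the basic
brain soft tissues; with an 8-bit luma axis, 255/(2 × 38) ≈ 3.4.

### Color-space conversions

`rgb_to_lab()`/`lab_to_rgb()` implement the standard chain — sRGB
inverse-gamma linearization, the IEC 61966-2-1 primaries matrix under D65,
then CIELAB. The D65 reference white is taken as the image of (1,1,1)
through the same matrix, so the gray axis maps to $a^* = b^* = 0$ *exactly*
and gray round-trips are lossless. Out-of-gamut CIELAB inputs are clipped
in linear RGB before gamma encoding. Round-trip error is at most 1 per
channel over the 8-bit cube.

### The built-in spectrum palette and luminance fidelity

No reference spectrum image ships with the package; `generate_spectrum()`
builds one. Three requirements interact:

* entry lumas should ascend across the 8-bit range so every gray level has
  a nearby match;
* the ends should look like the visible spectrum (violet at 400 nm, red at
  700 nm);
* colorization should *preserve* luminance, measured on the YIQ scale.

The last point is the delicate one. The colorizer preserves CIELAB $L^*$
by construction, but YIQ luma is a gamma-space weighted sum whose weights
(0.299/0.587/0.114) differ from the linear-light luminance weights; to
first order, adding chroma at fixed $L^*$ shifts YIQ luma by about 0.23
gray levels per unit of $a^*$ (the $b^*$ direction is nearly neutral). A
fully saturated spectrum would therefore break luminance preservation by
tens of gray levels. `generate_spectrum()` resolves this by *luminance
grading*: column $i$ of $n$ targets luma $255\,i/(n{+}1)$, takes its hue
angle in CIELAB from the standard piecewise wavelength→RGB approximation,
and carries the largest chroma whose reconstructed color still lands
within half a gray level of the luma target (found by a descending chroma
scan). The interior grid — rather than one touching 0 and 255 exactly —
keeps the darkest and brightest columns chromatic (violet, red) instead of
collapsing to pure black and white. Measured over the full 0–255 ramp with
the default 200-color palette, the median absolute luma error is ≈ 0.66
and the 99th percentile ≈ 1.9 (recomputed by the acceptance script), and
the ramp produces 256 distinct output colors — far above the 38-band
floor.

## The phantom generator

`generate_phantom()` supplies ground-truthed test data: nested ellipses
emulating an axial T2 slice — an outer GM ring (brain ellipse with
semi-axes 0.92/0.88 of the half-plane, WM at 0.78 scale inside it), a
ventricular CSF body (0.36/0.50) with two peripheral CSF pockets (radius
0.15), on a near-zero background. Class modes default to GM 65, WM 110,
CSF 180 and background 5 — near the centers of the anatomical windows so
tests exercise the published bounds without straddling them — with
additive Gaussian noise (default σ = 5), rounded and clipped; everything
is a deterministic function of the seed. At 128×128 the classes hold
roughly 4100/3400/2900 pixels, sized so that the binomial jitter of
histogram bins leaves each class's peak within ±3 of its mode with high
probability at σ = 5.

What the phantom does *not* emulate: partial-volume mixture voxels, bias
fields, Rician noise, anatomical shape variability, or skull/scalp
structures. Passing the recovery tests therefore shows the pipeline is
correct *given* its modal-histogram assumption — three separated unimodal
tissue distributions inside known windows — not that the assumption holds
on every clinical image (low-contrast or heavily biased acquisitions can
violate it).

## Problem sizes and numerical choices

The test suite and acceptance script use 128×128 single-plane phantoms (10
seeds), 64×64 random planes for the brute-force equivalence checks, a 6³
RGB lattice for round-trip audits, and the full 256-level ramp for
colorization — sizes at which every property is exercised in seconds while
the statistical checks retain comfortable margins. Tie-breaks are fixed
everywhere (lowest region index; lower gray level; lower luma), histogram
counts are exact integers, and all randomness flows through explicit
seeds, so every result in the package is bit-reproducible.

## Known limitations

* The anatomical windows are T2-specific defaults; T1/PD/FLAIR images need
  their own `region_ranges()`.
* DICOM series are not read directly; convert to NIfTI or PNG/TIFF stacks.
* The volume Jaccard coefficient measures volumetric agreement only, not
  spatial overlap.
* Per-plane centroid selection assumes each plane shows all three tissues;
  the fallbacks (raw argmax, midpoint-with-warning) keep degenerate planes
  processable but flag them for review.
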