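# chromaseg

Histogram-seeded tissue segmentation and luminance-matched colorization of
gray brain MR images, in R.

T2-weighted brain MR slices show gray matter (GM), white matter (WM) and
cerebrospinal fluid (CSF) as three modes of the gray-level histogram.
chromaseg segments such images **without iterative clustering**: cluster
centroids are selected automatically, once, from each plane's histogram
peaks inside anatomically prescribed intensity windows (GM 45–85,
WM 86–140, CSF 141–255 on T2), and every voxel is then classified to its
nearest centroid in a single pass — hard labels or graded soft
memberships. The package also provides a **luminance-matched CIELAB
colorization** for any 8-bit gray medical image, a volume-based Jaccard
coefficient for comparing segmentations, and a seeded brain phantom
generator so every stage is testable without external data.

It is aimed at medical-image-analysis practitioners who want a fast,
deterministic, fully reproducible baseline segmentation and a
luminance-faithful color rendering of gray radiological images.

## The methods in brief

**Centroid selection.** Per plane *z*: exact histogram *h_z(g)*; strict
local maxima (plateaus contribute their midpoint); peaks below 5% of the
highest peak are pruned; peaks closer than 10 gray levels are merged
keeping the higher; the highest surviving peak inside each anatomical
window becomes that region's centroid. Degenerate windows fall back to the
raw histogram argmax, then to the window midpoint (with a warning).

**Classification.** Hard: label = argmin_r |V(x,y,z) − C(z,r)|, ties to
the lowest region index; voxels below the GM lower bound form an optional
background class. Soft: memberships u_r ∝ (|V − C_r| + ε)⁻², normalized.
Centroids are never updated — the segmentation is single-phase.

**Colorization.** Each gray pixel *g* keeps its own CIELAB lightness L\*
and adopts the chromaticity (a\*, b\*) of the palette entry whose YIQ luma
(0.299R + 0.587G + 0.114B) is nearest *g*; a match within criterion
C₁ = 3.4 counts as successful. The built-in 400–700 nm spectrum palette is
luminance-graded so this transfer preserves luma to about one gray level.

**Evaluation.** Volume Jaccard coefficient Jc = |V₁ − V₂| / (V₁ + V₂)
between per-region voxel counts, reported to 8 decimals.

## Worked example

```r
library(chromaseg)

# a seeded T2-like phantom with ground-truth labels
ph  <- generate_phantom(shape = c(1, 128, 128), noise_sigma = 5, seed = 42)
fit <- segment_volume(ph$volume)
tidy(fit)
#> # A tibble: 3 × 6
#>   plane region centroid source voxels fraction
#>   <int> <chr>     <int> <chr>   <int>    <dbl>
#> 1     1 GM           65 peak     4067    0.248
#> 2     1 WM          108 peak     3525    0.215
#> 3     1 CSF         181 peak     2824    0.172
```

The selected centroids (65, 108, 181) sit on the phantom's class modes
(65, 110, 180); `source = "peak"` says each came from a genuine histogram
peak rather than a fallback. Comparing recovered volumes against the
ground truth:

```r
compare_methods(
  dplyr::filter(region_volumes(fit$labels), region != "background"),
  dplyr::filter(region_volumes(ph$labels),  region != "background"))
#> # A tibble: 3 × 4
#>   region    v1    v2 coefficient
#>   <chr>  <int> <int>       <dbl>
#> 1 GM      4067  4068    0.000123
#> 2 WM      3525  3524    0.000142
#> 3 CSF     2824  2824    0
```

Coefficients near zero mean the recovered per-region volumes match the
truth almost exactly. The same coefficient compares two methods' published
volumes:

```r
jaccard_volume(7921, 7466)
#> Jc(7,921, 7,466) = 0.02957042
```

Colorize a slice (or any gray image) with the built-in spectrum palette:

```r
pal <- build_palette(generate_spectrum(200), 200)
img <- colorize_plane(ph$volume, pal)   # luminance-preserving RGB
write_color(img, "slice_color.png")
```

`autoplot(fit)` renders the segmentation with the conventional colors
(GM purple, WM dark pink, CSF yellow); `autoplot(fit, type = "histogram")`
shows the plane's histogram with the selected centroids. A thin CLI
(`system.file("cli", "chromaseg", package = "chromaseg")`) exposes
`segment`, `centroids`, `colorize`, `phantom` and `jaccard` subcommands.

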