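---
title: "Methods: calibrated adipocyte morphometry with adiposize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated adipocyte morphometry with adiposize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package measures

Histology of white adipose tissue poses two routine quantification
problems. First, adipocyte morphometry: in an H&E-stained section,
adipocytes appear as pale polygons bounded by thin membranes, and the
distribution of their cross-sectional areas distinguishes hypertrophy
(larger cells) from hyperplasia (more cells). Second, stained-area
fractions: in immunofluorescent or chromogenically stained sections, the
fraction of the image occupied by a colour class (for example macrophage
staining) is the readout of interest.

adiposize implements both workflows as a scriptable library and CLI:
contour-based cell counting and sizing with reversible curation, and
colour-range / channel-based area quantification, plus the statistics
used to compare two analyses of the same section.

## The counting model

Counting proceeds on a binary image in which cell interiors are
foreground and membranes are background:

1. **Grayscale.** RGB is collapsed with the standard luma weights
   0.299 R + 0.587 G + 0.114 B.
2. **Haze removal** (optional, `dehaze_strength` in [0, 1]). A veiling
   brightness from slide preparation is removed with a
   dark-channel-prior style correction: the atmospheric light `A` is the
   mean colour of the brightest 0.1 % of the per-pixel channel-minimum
   map, the transmission is `t = 1 − strength · darkA` floored at 0.1,
   and the radiance `(I − A)/t + A` is clipped back to [0, 255].
   Strength 0 is the exact identity, and a uniform image stays uniform.
   We deliberately specify only this observable contract: the correction
   is global, and whether a locally adaptive variant would do better on
   real slides is out of scope.
3. **Denoising** (optional, `denoise_radius`). A square median filter of
   side `2r + 1` with replicate padding. It removes dust specks whose
   diameter is at most the radius while membranes wider than the
   window's minority limit survive unchanged.
4. **Thresholding.** Either a fixed cutoff (pixels strictly above the
   threshold are foreground) or Otsu's criterion: the integer threshold
   maximizing between-class variance of the intensity histogram, with
   plateau ties resolved to the plateau midpoint so a two-level image is
   split between its levels. An `invert` flag serves stains whose cell
   interiors are darker than their surroundings.
5. **Border thickening** (`border_thickness`). Erosion of the foreground
   by a disc, equivalently dilation of the membrane lines. Thicker
   borders seal membrane breaks so neighbouring cells stop merging, at
   the documented cost of shrinking each cell's measured area. The image
   frame is *not* treated as a membrane: out-of-frame pixels replicate
   the edge, so frame-touching cells keep touching the frame and the
   border-cell filter still sees them. (Erosion with background padding
   would silently detach every frame cell.)
6. **Contour tracing.** One external contour per 8-connected foreground
   component (background is 4-connected, so a diagonal membrane break
   does not create two cells). Components are found by flood fill;
   each outer boundary is walked with Moore-neighbourhood border
   following from the component's raster-first pixel, terminated by
   Jacob's criterion (stop on re-entering the start pixel when the next
   step would repeat the second chain pixel — a plain "returned to
   start" test terminates one pixel too early or late on spurs).
   Interior holes neither produce contours nor count toward area.
7. **Chain compression.** Boundary chains store only the endpoints of
   maximal constant-direction runs, so an axis-aligned rectangle keeps 4
   vertices. The compression is exactly invertible by stepping the unit
   direction between consecutive vertices; we do not merge runs that are
   collinear in real coordinates but change step pattern, because that
   would break exact reconstruction of the rasterized chain.
8. **Measurement.** A cell's pixel area is its component's foreground
   pixel count (boundary included, holes excluded), converted to µm²
   with the squared calibration factor.

### Calibration

The microns-per-pixel factor (MPP) is either read from file metadata or
derived from a measured scale bar: `mpp = length_µm / length_px`, area
factor `mpp²`. Metadata is searched in this order: TIFF X/Y-resolution
tags together with their unit (inch = 25 400 µm, cm = 10 000 µm), then a
case-insensitive `<number> micron(s) per pixel` / `µm/px` phrase in the
TIFF image description. X and Y resolutions disagreeing by more than 1 %
are rejected: anisotropic pixels are unsupported rather than silently
averaged. Displayed values are rounded to 4 decimals; internal values
keep full precision. All coordinates are 0-based `(row, col)` with row
increasing downward.

### Curation

Three reversible mechanisms flip per-cell inclusion flags and never
touch geometry, so any sequence can be undone without re-detection:

- **Size limits**: the closed interval `[min, max]` in µm² (closed on
  both ends — the least surprising reading of "between a and b" for
  boundary cells). Size limits require a calibration; for uncalibrated
  images pass `--mpp 1` explicitly to filter in pixel units.
- **Border cells**: cells whose component touches the image frame are
  incompletely imaged and can be excluded and restored with one switch.
- **Point toggling**: a click point is tested for membership in a
  component's foreground pixel set (not point-in-polygon of the
  compressed chain, which is ambiguous on raster edges). Clicking an
  included cell excludes it (`manual`); clicking it again restores it.
  Clicking a cell excluded by an automatic rule overrides the rule and
  brings it back — manual curation wins last. A background click is a
  recorded no-op.

Filters are *flags, not standing rules*: switching border exclusion off
restores border cells even if a size filter applied meanwhile would have
caught them. Re-apply the size filter if both should hold.

### Manual border correction

Real sections have faint membranes no automatic threshold recovers. The
mask can be exported as a lossless black/white image, edited in any
paint program (drawing black strokes reconnects membranes), and
re-imported; re-binarization at 128 makes any dark stroke a border. The
import refuses shape mismatches, and lossy JPEG export triggers a
warning.

## Colour separation

A colour range is a box in RGB space — three independent inclusive
intervals, matching three slider pairs; HSV selection and stain
deconvolution are out of scope. The area fraction is
`100 · |mask| / (H·W)`, plus µm² when calibrated; a range and its
complement always sum to exactly 100 %. Fluorescent channels are split
by thresholding each selected channel (default threshold 0 — any
nonzero intensity counts, since the display model is a flat uniform
colour, which forces binarization but names no cutoff; it is
user-settable). Renderings paint selected channels at full intensity
and can be saved and re-loaded as new session images. Named presets
such as `reddish_brown` are tool defaults for a starting point, not
measured constants.

## Histograms and method comparison

Size histograms use half-open bins `[e_i, e_{i+1})` with an open-ended
final bin, so real-valued calibrated areas can never fall between bins
whose printed labels assume integers; cells below the first edge go to
a separate underflow row, and counts/areas always reconcile exactly
with the population totals.

Two analyses of the same section are compared by the Pearson
correlation between their per-bin count vectors and between their
per-bin area vectors, with two-sided p-values from
`t = r·sqrt((n−2)/(1−r²))` on `n − 2` degrees of freedom — the same
p-value a spreadsheet linear regression reports. Percent differences
`100·|b − a|/a` use the *first* table as reference, so r is symmetric
under swapping but the percent columns are not. Totals rows are kept as
read from file even when they disagree with the bin sums (one shipped
benchmark table prints a total count one higher than its bins; the
comparison uses both as published rather than silently reconciling).

## The synthetic-image generator

Because no real slides ship with the package, every pipeline stage is
tested against generated mosaics with exact ground truth:

- **Disc grids**: bright discs on dark background; pixel counts are the
  exact rasterized disc sizes. A negative margin clips outer discs at
  the frame to exercise border-cell logic.
- **Voronoi mosaics** emulate an H&E adipose field: 50 cells by default
  in 192×192 px, sites on a jittered grid (so no degenerate slivers),
  membranes 3 px wide at intensity 40 ± 10, interiors at 230 ± 10.
  The intensity scale mimics a well-exposed H&E field (bright lipid
  interiors, dark eosin membranes) with mild jitter; the defaults were
  fixed once, before any test was run, and are not tuned. Membrane
  pixels belong to no cell in ground truth; on sealed mosaics detection
  recovers the interior pixel sets *exactly*, cell for cell.
- **Artifacts**: haze is a convex blend with white; dust specks are
  ≤ 2 px discs stamped with contrast to their locale (dark on bright
  interiors — making holes; bright on dark background — making spurious
  objects a median filter removes; the generic "dark speck" reading
  would be invisible to object counts); the scratch is one long thin
  bright streak whose registry stores a click point.
- **Fluorescent overlays**: disjoint single-channel discs with recorded
  per-channel pixel counts.
- **Broken membranes**: `gap_fraction` deletes round membrane patches
  (radius = membrane width, centres kept ≥ 3 radii apart) until the
  target fraction of membrane pixels is gone.

One integer seed drives all randomness; identical parameters give
bit-identical images.

### What a green test does and does not establish

The generator produces clean two-mode intensity histograms, convex-ish
cells and perfectly closed membranes (unless broken on purpose). Green
tests establish the geometric and bookkeeping correctness of the
pipeline — not performance on real slides, which have staining
gradients, touching nuclei, out-of-focus regions and genuinely
ambiguous membranes. The broken-membrane experiment makes this honest:
with 30 % of membrane pixels deleted, the automatic count collapses to
1–2 merged objects; sweeping the border-thickness slider (3–6 px) with
the standard small-object filter returns within one cell of the truth,
but *exact* recovery on every image needs the manual-correction round
trip, which is precisely the workflow the tool's GUI ancestors built
around a paint program. Erosion that seals every membrane break also
begins to split thin cells — there is no free lunch in the thickness
parameter, which is why it is exposed as a slider rather than fixed.

## Numerical choices and edge cases

- Otsu on a constant image returns 127 (arbitrary, documented).
- `compare_methods` needs ≥ 3 bins (else the t-test is undefined) and
  reports `NA` for zero-variance vectors rather than ±1.
- `percent_difference(0, b)` is undefined and reported as `NA`.
- Cell ids are assigned 1..N in raster-scan order of each component's
  first pixel — deterministic across runs and equal to the ground-truth
  ordering of the generators.
- Image intensities are integers 0–255 throughout; TIFF support is
  deliberately minimal (uncompressed 8-bit baseline, both endiannesses
  read, little-endian written) because its only job here is lossless
  storage plus resolution metadata. PNG and JPEG decoding delegate to
  the png/jpeg packages; no whole-slide pyramidal formats.
- CSV (RFC 4180, dot decimal, UTF-8) is the canonical export; xlsx is a
  minimal single-sheet convenience mirror.

## Known limitations

No watershed splitting of merged cells (manual correction is the
supported route); no machine-learning segmentation; no HSV or optical
density colour models; no anisotropic pixels; no multi-page TIFF. The
automatic-calibration path reads standard resolution tags and micron
phrases only — exotic vendor metadata blocks are not parsed.
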