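---
title: "Tile-based whole-slide image processing with slidetiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based whole-slide image processing with slidetiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidetiler)
```

## The problem

A whole-slide image is a brightfield scan of a complete tissue section,
commonly 10^8–10^9 pixels at full resolution. Algorithms for microscopy
images — thresholding, stain separation, object counting — are written for
single fields of view that fit in memory; a decoded slide does not. The
slide's container format already holds the solution: a pyramidal tiled
TIFF stores several resolution *series*, each cut into small storage tiles
that decode independently. `slidetiler` turns that storage property into a
processing model: a per-tile analysis function is iterated over a tile
grid covering one series, and everything else — extraction, persistence,
naming, error isolation, cross-tile state — is the engine's job. No other
workflow is imposed; the analysis itself stays an ordinary R function of
one in-memory image.

## The tile grid

For a series of width $W$ and height $H$, tile side $T$ and overlap $V$
(the same in both directions, $0 \le V < T$), origins along each axis
advance by the stride $s = T - V$ and stop at the first tile reaching the
edge; that tile is clipped to the boundary. Clipping, rather than shifting
the last tile inward, is deliberate: a shifted tile would silently overlap
its neighbour by more than $V$, and at $V = 0$ would double-count pixels
in any area aggregation. With clipping, the $V = 0$ grid is a *partition*:
every pixel belongs to exactly one tile. This is what makes slide-level
stain areas an exact integer identity with whole-image classification, at
every tile size — per-pixel classification is local, so summing disjoint
tiles equals classifying the whole. The package's tests assert this
identity literally, including at tile sizes that divide neither dimension.

Overlap exists for the other use case: objects (mitoses, nuclei) that
straddle a tile boundary and would otherwise be seen whole by no tile.
Quantifications that sum areas should run at $V = 0$; the slide-level
H/DAB processor warns when it is asked to aggregate with $V > 0$.

Tiles are processed in row-major order (y outer, x inner) and slides in
lexicographic order, so results tables are reproducible byte for byte.
Each tile is written to `<output>/tiles/` under the name
`<slide>.<ext>__<series>_<x>_<y>.tif` before its processor runs, and
deleted afterwards unless the run keeps tiles. Coordinates in the name are
in the pixel grid of the selected series — the only convention under which
the name suffices to re-extract the tile. Parsing anchors on the rightmost
`__<digits>_<digits>_<digits>.tif` suffix, so underscores in slide names
cannot break the round trip.

## Reading pyramids

`open_slide()` lists every image directory of a TIFF in file order,
flattening SubIFD-attached reduced levels into the same 1-based series
list; series 1 is the highest resolution in the usual layout. Files may
contain non-pyramid series (thumbnails, labels); the package lists them
as-is and does not guess, since the container gives no reliable marker —
selecting them is legal and their interpretation is the caller's.
`read_region()` decodes only the storage tiles or strips intersecting the
requested rectangle, so memory scales with the region, not the series.
Coordinates are 0-based, half-open, origin top-left, x = column — matching
TIFF storage order. Supported on-disk forms: classic TIFF 6.0, 8-bit RGB,
chunky layout, tiled or stripped, uncompressed, Deflate/zlib, or LZW
(decode only), with the horizontal predictor honoured. BigTIFF and
JPEG-in-TIFF are rejected with a clear error, as is anything else the
parser cannot interpret — in a batch run such files are recorded as
failures and the batch continues, since unsupervised overnight runs must
not die on one bad input.

## Cross-tile state

Each tile invocation is independent; state that must survive between
them — running totals, per-slide accumulators, arrays — lives in a results
store the engine passes to every invocation and saves at the end of each
slide. The store holds named append-only tables (one CSV per table, RFC
4180, header in first-seen column order, numbers at 17 significant digits
so doubles round-trip exactly) and a key/value variable store persisted as
JSON. Keeping this mechanism deliberately simple — tables plus variables,
no richer state model — matches how per-tile analyses actually accumulate
whole-slide results, and keeps every intermediate inspectable as plain
text.

## H/DAB positivity

The built-in analyses quantify hematoxylin (blue, nuclear counterstain)
versus DAB (brown, peroxidase product). Brightfield absorbance is additive
in optical-density space: per channel $OD = -\log_{10}(\max(I,1)/255)$, so
white is exactly 0 and saturated black is capped at $-\log_{10}(1/255)
\approx 2.41$. A pixel's OD vector is modeled as $M c$, with the columns
of $M$ the unit absorbance vectors of hematoxylin, DAB, and a residual
channel completed as their normalized cross product; solving the 3×3
system gives per-stain concentrations. The default vectors are the
standard published H-DAB calibration, H = (0.650, 0.704, 0.286) and
DAB = (0.268, 0.570, 0.776) in R, G, B optical density; both are
user-overridable (function argument or the CLI's YAML config) for slides
with a different stain calibration.

Classification applies OD thresholds `tau_h = tau_d = 0.15`: DAB-positive
if the DAB concentration reaches `tau_d`; otherwise hematoxylin if its
concentration reaches `tau_h`; otherwise background. DAB takes precedence
because a DAB-positive nucleus is positive regardless of counterstain —
required for positivity, $100 \cdot \mathrm{DAB}/(\mathrm{H} +
\mathrm{DAB})$, to behave as a fraction of nuclei-like area. A blank
denominator yields 0 by convention, keeping slide aggregation defined on
empty tiles. The thresholds are validated only against the synthetic
generator (where pure-stain pixels sit at concentration ≈ 1, an order of
magnitude above threshold) and are explicitly not a clinical calibration:
no nuclei segmentation, no stromal or in-situ discrimination, no validated
scoring. The positivity denominator is stained area (H + DAB), the
nuclear-fraction convention; both raw counts are reported in every row so
any other denominator can be recomputed after the fact.

## The synthetic generator

`generate_slide()` writes tiled pyramidal TIFFs containing hard-edged
discs on a white background, painted at the exact 8-bit transmittance
$\mathrm{round}(255 \cdot 10^{-\mathrm{od} \cdot v})$ of their stain
vector $v$ (default amplitude 1.0 OD). Discs are placed by rejection
sampling, fully inside bounds and pairwise non-overlapping, under a fixed
seed; the same spec yields a byte-identical file, and the generator
restores the caller's RNG state. Because edges are hard and colors exact,
the per-stain pixel counts the generator reports are exact integers, and
ground-truth recovery is an equality test, not a tolerance test. Equal
disc radii make expected positivity a pure count ratio (7 blue + 3 brown
discs → exactly 30%).

Pyramid levels halve dimensions (`ceiling(dims / 2^(L-1))`) by 2×2 block
mean followed by 8-bit rounding (R's `round`, documented so reduced-level
reads are reproducible; trailing odd rows/columns average the pixels that
exist). Level 1 is produced storage-tile by storage-tile, so single-level
generation is memory-bounded at any permitted size; multi-level generation
holds one full level for downsampling and is therefore capped at 64 Mpx.

What the fixtures do *not* emulate: scanner noise and texture, stain
co-localization and gradients, anti-aliased object boundaries, JPEG
artifacts, stitching seams. Tests passing on them demonstrate the
geometry, accounting and plumbing are exact — not that the default
thresholds are adequate for real tissue, which is an explicit non-goal.

## Numerical and design notes

* **Quantization.** Painting a concentration, synthesizing 8-bit RGB and
  deconvolving recovers the concentration up to rounding: a half-count at
  intensity $I$ perturbs one channel's OD by $\log_{10}(I/(I-0.5))$,
  amplified by at most $\lVert M^{-1} \rVert_\infty \approx 2.8$. The
  tests assert this exact propagated bound per pixel rather than a single
  global constant; at the generator's working point the error is ~10^-3,
  two orders of magnitude below the classification thresholds.
* **Two deconvolution routes.** The user-facing `deconvolve()` solves the
  system via `solve()`; the test suite checks it against an explicitly
  coded adjugate inverse, and the built-in processors' channel-plane
  accumulation is asserted to give identical counts.
* **Degenerate inputs.** Zero-byte and truncated files, BigTIFF,
  non-template tile names, overlap ≥ tile size, singular stain bases,
  unknown processors, and missing store keys each raise a classed error;
  the batch engine converts per-slide and per-tile errors into recorded
  failures and continues.
* **Memory discipline.** The engine's working set is one tile. After each
  large tile (and periodically for small ones) it triggers a collection so
  the allocator's high-water mark tracks the live working set instead of
  accumulated garbage — a few milliseconds per tile against ~100 ms of
  decode and analysis, and what keeps day-long unsupervised batches flat
  in memory. The test suite processes a 16384×8192 slide at tile size 512
  and asserts the allocation high-water mark stays under a quarter of the
  decoded slide size (it measures ~10%).
* **Sequential by design.** Cross-tile persistence through one shared
  store is order-sensitive, and the documented row order is part of the
  output contract; any future parallelism must preserve it.
* **Problem sizes.** The shipped tests and the acceptance script use
  slides from 128² up to 16384×8192 pixels, tile sizes 64–2048, and
  500–10000 randomized cases per property — sizes at which the full suite
  runs in a few minutes on one core while still crossing the
  larger-than-working-set threshold that motivates the package.

## Limitations

Only tiled and plain TIFF are read natively; proprietary scanner formats
(SVS, NDPI, SCN, Mirax, BIF) are out of scope for the core, though SVS
files that are plain tiled TIFF inside often open as-is. One focal plane,
one time point, 8-bit RGB only. The H/DAB macros are demonstrations of the
engine, not a validated assay. CSV/JSON persistence is a pragmatic state
model, not a database; concurrent writers are unsupported.
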