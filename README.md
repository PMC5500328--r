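# slidetiler

Tile-based batch processing of whole-slide images in R.

A whole-slide image (WSI) is a gigapixel scan of a complete glass slide.
Generic image-analysis code assumes the image fits in memory; a WSI does
not. Its TIFF container, however, stores the image as a pyramid of
resolution *series*, each split into small storage tiles that can be
decoded independently. `slidetiler` exploits that: it iterates a
user-supplied per-tile analysis over every tile of a chosen series — with
configurable tile size and overlap — so an algorithm written and tested on
a single microscopic field runs unchanged over a full slide, with memory
bounded by one tile. It is aimed at researchers prototyping digital
pathology analyses (biomarker quantification, tissue fractions, rare-event
screening) who need unsupervised batch runs over folders of slides, not a
clinical-grade scoring system.

## What it does

* **Pyramid access** — [`open_slide()`] enumerates the resolution series of
  a tiled or plain TIFF (main-IFD chains and SubIFD pyramids, uncompressed
  / Deflate / LZW); [`read_region()`] decodes an arbitrary rectangle of a
  series touching only the storage segments it intersects.
* **Tiling** — [`compute_grid()`] covers a `W x H` plane with tiles of side
  `T` overlapping by `V` pixels (stride `T - V`, identical in X and Y);
  edge tiles are clipped, never shifted, so at `V = 0` the tiles partition
  the plane and area aggregation never double-counts. Every extracted tile
  is persisted under the template
  `"<slide name>.<ext>__<series>_<x>_<y>.tif"`, so any tile can be
  identified and re-extracted later.
* **The engine** — [`run_folder()`] walks a folder of slides, writes each
  tile, invokes `processor(tile, context, store)` on it, and deletes the
  tile afterwards unless asked to keep it. Per-tile errors are collected,
  not fatal. Cross-tile state flows through a persistent results store
  (named append-only CSV tables plus a key/value variable store).
* **H/DAB reference analyses** — built-in processors quantify
  hematoxylin/DAB immunohistochemistry by color deconvolution: per pixel,
  optical density `OD = -log10(I/255)` is solved as `OD = M c` where the
  columns of `M` are stain absorbance vectors (Ruifrok–Johnston H-DAB by
  default), and positivity is `100 * DAB area / (H area + DAB area)`.
  `hdab_tile` writes one row per tile, `hdab_slide` one row per slide, and
  [`max_positivity_tile()`] retrieves the hottest tile of a kept run.
* **Synthetic slides** — [`generate_slide()`] writes pyramidal tiled TIFFs
  with hard-edged discs painted at exact stain transmittances, so every
  result above is testable against integer ground truth without any
  external dataset.

## Worked example

```r
library(slidetiler)

# a synthetic slide: 7 hematoxylin discs, 3 DAB discs, equal radius
dir.create("slides")
spec <- synthetic_slide_spec(1024, 768, n_blue = 7, n_brown = 3,
                             object_radius = 30, seed = 42)
generate_slide(spec, "slides/demo.tif")
#> Synthetic slide 1024x768: 19747 blue px, 8463 brown px, positivity 30%

# whole-slide positivity via the tiled engine
cfg <- run_config("slides", "out", processor = "hdab_slide",
                  tile_size = 512, quiet = TRUE)
run_folder(cfg)
#> Run summary: 1 slide(s), 4 tile(s) processed, 0 retained, 0 failure(s)

get_table(load_store("out/results"), "slides")
#>      slide blue_area brown_area positivity_pct
#> 1 demo.tif     19747       8463             30
```

The slide-level areas equal the generator's painted-pixel counts exactly,
and 3 of 10 equal-radius discs give exactly 30% positivity: per-pixel
classification is local, and a zero-overlap grid partitions the slide, so
tiled aggregation is an integer identity — at any tile size.

The same run from a shell:

```sh
inst/cli/slidetiler synth --width 1024 --height 768 --blue 7 --brown 3 \
    --radius 30 --seed 42 --out slides/demo.tif
inst/cli/slidetiler run --input slides --output out --processor hdab_slide \
    --tile-size 512
inst/cli/slidetiler run --input slides --output out2 --processor hdab_tile \
    --tile-size 512 --keep-tiles
inst/cli/slidetiler hdab-max --results out2/results
#> demo.tif__1_512_512.tif
```

A custom analysis is one R file defining
`process_tile(tile, context, store)`; pass its path as `--processor`.

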