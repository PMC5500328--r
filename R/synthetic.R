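# Synthetic whole-slide fixtures: pyramidal tiled TIFFs with a white
# background and hard-edged stained discs painted at exact 8-bit stain
# transmittances, so stain-area ground truth is an integer, not an
# estimate. Every other module is testable against these files without any
# external dataset.

#' Describe a synthetic slide
#'
#' @param width,height Level-1 dimensions in pixels (`width * height` up to
#'   ~256 Mpx; pyramids with more than one level are capped at 64 Mpx
#'   because downsampling holds one full level in memory).
#' @param n_blue,n_brown Number of hematoxylin-colored / DAB-colored discs.
#' @param object_radius Disc radius in pixels.
#' @param stain_od Optical-density amplitude of painted discs; each disc is
#'   painted at the exact 8-bit transmittance `round(255 * 10^(-stain_od *
#'   v))` of its stain vector `v`.
#' @param seed Integer seed for disc placement; the same spec yields a
#'   byte-identical file.
#' @param internal_tile Storage tile side of the written TIFF, in pixels.
#' @param n_levels Pyramid depth; level L has dimensions
#'   `ceiling(dims / 2^(L-1))`, computed by 2x2 block mean then 8-bit
#'   rounding.
#' @param compression `"deflate"` or `"none"`.
#' @param subifd Write reduced levels as SubIFDs instead of chained main
#'   directories.
#' @return An object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(width, height, n_blue = 0L, n_brown = 0L,
                                 object_radius = 20L, stain_od = 1.0,
                                 seed = 1L, internal_tile = 256L,
                                 n_levels = 1L, compression = "deflate",
                                 subifd = FALSE) {
  if (width < 1 || height < 1)
    st_parameter_error("slide dimensions must be positive")
  if (as.numeric(width) * as.numeric(height) > 256e6)
    st_parameter_error("synthetic slides are limited to 256 Mpx")
  if (n_levels > 1 && as.numeric(width) * as.numeric(height) > 64e6)
    st_parameter_error("multi-level synthetic slides are limited to 64 Mpx")
  if (n_blue < 0 || n_brown < 0 || object_radius < 1)
    st_parameter_error("object counts must be >= 0 and radius >= 1")
  if (stain_od <= 0) st_parameter_error("stain_od must be positive")
  if (internal_tile < 16) st_parameter_error("internal_tile must be >= 16")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blue = as.integer(n_blue), n_brown = as.integer(n_brown),
                 object_radius = as.integer(object_radius),
                 stain_od = stain_od, seed = as.integer(seed),
                 internal_tile = as.integer(internal_tile),
                 n_levels = as.integer(n_levels),
                 compression = compression, subifd = isTRUE(subifd)),
            class = "synthetic_slide_spec")
}

#' Exact 8-bit transmittance color of a stain
#'
#' The RGB color a pure stain of optical-density amplitude `od` produces
#' under the Beer–Lambert model, `round(255 * 10^(-od * v))` — the exact
#' color the synthetic generator paints.
#'
#' @param stain_vector Length-3 absorbance vector (a column of
#'   [hdab_basis()]).
#' @param od Optical-density amplitude.
#' @return Integer RGB triple in 0..255.
#' @export
stain_rgb <- function(stain_vector, od = 1.0) {
  pmax(0L, pmin(255L, as.integer(round(255 * 10^(-od * stain_vector)))))
}

# rejection-sample pairwise non-overlapping disc centers fully inside the
# slide; deterministic under the spec seed
.place_objects <- function(spec) {
  n <- spec$n_blue + spec$n_brown
  if (n == 0L)
    return(data.frame(cx = integer(0), cy = integer(0), r = integer(0),
                      stain = character(0), stringsAsFactors = FALSE))
  r <- spec$object_radius
  if (spec$width < 2 * r + 1 || spec$height < 2 * r + 1)
    st_placement_error("slide too small for radius-%d objects", r)
  cx <- integer(n); cy <- integer(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * n
  while (placed < n) {
    if (attempts >= max_attempts)
      st_placement_error(
        "could not place %d non-overlapping radius-%d discs on a %dx%d slide after %d attempts; use fewer or smaller objects",
        n, r, spec$width, spec$height, max_attempts)
    attempts <- attempts + 1L
    x <- sample.int(spec$width - 2L * r, 1L) + r - 1L
    y <- sample.int(spec$height - 2L * r, 1L) + r - 1L
    # centers farther apart than 2r share no pixel
    if (placed > 0L &&
        any((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2 <= (2 * r)^2))
      next
    placed <- placed + 1L
    cx[placed] <- x; cy[placed] <- y
  }
  data.frame(cx = cx, cy = cy, r = r,
             stain = rep(c("H", "DAB"), c(spec$n_blue, spec$n_brown)),
             stringsAsFactors = FALSE)
}

# Paint the region [x0, x0+w) x [y0, y0+h) of the virtual slide: white
# background, discs at exact stain colors, hard edges. Returns the pixel
# array and the per-stain painted-pixel counts inside the region.
.paint_region <- function(objects, colors, x0, y0, w, h) {
  img <- array(255L, dim = c(h, w, 3L))
  counts <- c(H = 0, DAB = 0)
  for (k in seq_len(nrow(objects))) {
    ob <- objects[k, ]
    xs <- max(x0, ob$cx - ob$r):min(x0 + w - 1L, ob$cx + ob$r)
    ys <- max(y0, ob$cy - ob$r):min(y0 + h - 1L, ob$cy + ob$r)
    if (xs[1] > xs[length(xs)] || ys[1] > ys[length(ys)]) next
    if (ob$cx + ob$r < x0 || ob$cx - ob$r > x0 + w - 1L ||
        ob$cy + ob$r < y0 || ob$cy - ob$r > y0 + h - 1L) next
    mask <- outer((ys - ob$cy)^2, (xs - ob$cx)^2, "+") <= ob$r^2
    if (!any(mask)) next
    col <- colors[[ob$stain]]
    for (ch in 1:3) {
      plane <- img[ys - y0 + 1L, xs - x0 + 1L, ch]
      plane[mask] <- col[ch]
      img[ys - y0 + 1L, xs - x0 + 1L, ch] <- plane
    }
    counts[ob$stain] <- counts[ob$stain] + sum(mask)
  }
  list(img = img, counts = counts)
}

# 2x2 block mean with 8-bit rounding; odd trailing row/column blocks
# average the pixels that exist. Output dims are ceiling(dims / 2).
downsample_2x <- function(img) {
  d <- dim(img)
  h2 <- ceiling(d[1] / 2); w2 <- ceiling(d[2] / 2)
  # replicate-pad to even: the mean over a replicated pair equals the mean
  # of the single available row/column
  if (d[1] %% 2 == 1) img <- img[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (d[2] %% 2 == 1) img <- img[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  a <- (img[seq(1, 2 * h2, 2), , , drop = FALSE] +
        img[seq(2, 2 * h2, 2), , , drop = FALSE])
  a <- (a[, seq(1, 2 * w2, 2), , drop = FALSE] +
        a[, seq(2, 2 * w2, 2), , drop = FALSE])
  out <- round(a / 4)
  storage.mode(out) <- "integer"
  out
}

#' Generate a synthetic whole-slide TIFF with known ground truth
#'
#' Writes a tiled (optionally pyramidal) TIFF per the spec and a JSON
#' ground-truth sidecar at `<out_path>.json`. Level 1 is produced storage
#' tile by storage tile, so generation memory is bounded by one tile for
#' single-level slides of any permitted size. Painted colors are exact and
#' un-anti-aliased, so the reported per-stain pixel counts are exact
#' integers recoverable by classification.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param out_path Output TIFF path.
#' @return Invisibly, an object of class `slide_ground_truth`: `blue_px`,
#'   `brown_px`, `positivity_pct` (`100 * brown / (blue + brown)`, 0 when
#'   blank), `objects` (centers, radii, stains), `width`, `height`,
#'   `path`.
#' @examples
#' \dontrun{
#' spec <- synthetic_slide_spec(1024, 768, n_blue = 7, n_brown = 3, seed = 42)
#' gt <- generate_slide(spec, "slide.tif")
#' gt$positivity_pct  # 30 for equal-radius discs
#' }
#' @export
generate_slide <- function(spec, out_path) {
  if (!inherits(spec, "synthetic_slide_spec"))
    st_parameter_error("'spec' must come from synthetic_slide_spec()")
  # localize the RNG so generation neither depends on nor disturbs the
  # caller's random state
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  basis <- hdab_basis()
  colors <- list(H = stain_rgb(basis[, "H"], spec$stain_od),
                 DAB = stain_rgb(basis[, "DAB"], spec$stain_od))
  objects <- .place_objects(spec)

  ts <- spec$internal_tile
  comp_code <- .comp_code(spec$compression)
  n_cols <- ceiling(spec$width / ts)
  n_rows <- ceiling(spec$height / ts)
  counts <- c(H = 0, DAB = 0)
  segments <- vector("list", n_cols * n_rows)
  full <- if (spec$n_levels > 1L)
    array(255L, dim = c(spec$height, spec$width, 3L)) else NULL
  si <- 0L
  for (ty in seq_len(n_rows) - 1L) {
    for (tx in seq_len(n_cols) - 1L) {
      w <- min(ts, spec$width - tx * ts)
      h <- min(ts, spec$height - ty * ts)
      painted <- .paint_region(objects, colors, tx * ts, ty * ts, w, h)
      counts <- counts + painted$counts
      tile <- painted$img
      if (!is.null(full))
        full[(ty * ts + 1):(ty * ts + h), (tx * ts + 1):(tx * ts + w), ] <- tile
      if (w < ts || h < ts) {
        pad <- array(255L, dim = c(ts, ts, 3L))
        pad[seq_len(h), seq_len(w), ] <- tile
        tile <- pad
      }
      si <- si + 1L
      segments[[si]] <- .encode_segment(.pixels_to_raw(tile), spec$compression)
    }
  }
  levels <- list(list(width = spec$width, height = spec$height,
                      tile_w = ts, tile_h = ts,
                      compression_code = comp_code, segments = segments))
  if (spec$n_levels > 1L) {
    lv_img <- full
    for (l in seq_len(spec$n_levels - 1L)) {
      lv_img <- downsample_2x(lv_img)
      levels[[l + 1L]] <- list(
        width = dim(lv_img)[2], height = dim(lv_img)[1],
        tile_w = ts, tile_h = ts, compression_code = comp_code,
        segments = array_to_segments(lv_img, tile_size = ts,
                                     compression = spec$compression))
    }
  }
  tiff_write_levels(out_path, levels, subifd = spec$subifd)

  blue_px <- unname(counts["H"]); brown_px <- unname(counts["DAB"])
  gt <- structure(list(
    blue_px = blue_px, brown_px = brown_px,
    positivity_pct = if (blue_px + brown_px > 0)
      100 * brown_px / (blue_px + brown_px) else 0,
    objects = objects, width = spec$width, height = spec$height,
    n_levels = spec$n_levels, stain_od = spec$stain_od,
    seed = spec$seed, path = out_path),
    class = "slide_ground_truth")
  jsonlite::write_json(
    list(blue_px = blue_px, brown_px = brown_px,
         positivity_pct = gt$positivity_pct,
         width = spec$width, height = spec$height, seed = spec$seed,
         stain_od = spec$stain_od,
         objects = objects),
    paste0(out_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(gt)
}

#' @export
print.slide_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic slide %dx%d: %.0f blue px, %.0f brown px, positivity %.4g%%\n",
              x$width, x$height, x$blue_px, x$brown_px, x$positivity_pct))
  invisible(x)
}
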