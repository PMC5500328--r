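#' Open a whole-slide TIFF and enumerate its resolution series
#'
#' Parses the file structure of a pyramidal tiled TIFF (or a plain
#' single-resolution TIFF) and lists every image series in file order,
#' without reading any pixel data. Series are numbered from 1, matching the
#' convention of slide scanners where series 1 is usually the highest
#' resolution. SubIFD-attached pyramid levels are flattened into the same
#' 1-based list, each directly after its parent directory. Non-pyramid
#' series a file may contain (thumbnails, label images) are listed as-is;
#' selecting them is legal and their interpretation is left to the caller.
#'
#' @param path Path to a tiled or plain TIFF file, RGB 8-bit.
#' @return An object of class `slide_pyramid`: list with `path`,
#'   `pixel_type` and `series`, a data frame with one row per series
#'   (`index`, `width_px`, `height_px`, `downsample` relative to series 1,
#'   `internal_tile_w`, `internal_tile_h` — 0 when the series is stripped).
#' @examples
#' \dontrun{
#' slide <- open_slide("slide.tif")
#' slide$series
#' tile <- read_region(slide, 1, 0, 0, 512, 512)
#' }
#' @export
open_slide <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    st_parameter_error("'path' must be a single file path")
  if (!file.exists(path) || dir.exists(path))
    st_not_found("slide file not found: '%s'", path)
  meta <- tryCatch(
    tiff_meta(path),
    st_unsupported_format = function(e) stop(e),
    error = function(e)
      st_unsupported_format("cannot open '%s' as TIFF: %s", path, conditionMessage(e))
  )
  n <- length(meta$ifds)
  w <- vapply(meta$ifds, `[[`, 0, "width")
  h <- vapply(meta$ifds, `[[`, 0, "height")
  series <- data.frame(
    index = seq_len(n),
    width_px = w,
    height_px = h,
    downsample = (w[1] / w + h[1] / h) / 2,
    internal_tile_w = vapply(meta$ifds, function(m) if (m$tiled) m$tile_w else 0, 0),
    internal_tile_h = vapply(meta$ifds, function(m) if (m$tiled) m$tile_h else 0, 0)
  )
  structure(list(path = path, pixel_type = "RGB 8-bit",
                 series = series, meta = meta),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat("Whole-slide image:", x$path, "\n")
  cat(" ", nrow(x$series), "series,", x$pixel_type, "\n")
  print(x$series, row.names = FALSE)
  invisible(x)
}

#' Read a rectangular region from one series of a slide
#'
#' Decodes exactly the requested pixels, touching only the storage tiles or
#' strips of the file that intersect the request; memory use is proportional
#' to the region, not the series. Coordinates are 0-based, half-open, with
#' the origin at the top-left corner, `x` the column and `y` the row, in the
#' pixel grid of the requested series.
#'
#' @param slide A `slide_pyramid` from [open_slide()].
#' @param series 1-based series index.
#' @param x,y Top-left corner of the region, in pixels.
#' @param w,h Region width and height, in pixels (at least 1). The region
#'   must lie fully inside the series bounds; callers tile the slide via
#'   [compute_grid()], which only produces in-bounds rectangles.
#' @return Integer array `h x w x 3`, values 0..255.
#' @export
read_region <- function(slide, series, x, y, w, h) {
  if (!inherits(slide, "slide_pyramid"))
    st_parameter_error("'slide' must be a slide_pyramid from open_slide()")
  if (length(series) != 1L || is.na(series) || series < 1 ||
      series > nrow(slide$series) || series != floor(series))
    st_series_error("series %s out of range (file has %d series)",
                    format(series), nrow(slide$series))
  for (v in list(x = x, y = y, w = w, h = h))
    if (length(v) != 1L || is.na(v) || v != floor(v))
      st_parameter_error("region coordinates must be single integers")
  sw <- slide$series$width_px[series]
  sh <- slide$series$height_px[series]
  if (w < 1 || h < 1 || x < 0 || y < 0 || x + w > sw || y + h > sh)
    st_bounds_error(
      "region [%d,%d)x[%d,%d) exceeds series %d bounds %dx%d",
      x, x + w, y, y + h, series, sw, sh)
  tiff_read_region(slide$meta, series, x, y, w, h)
}
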