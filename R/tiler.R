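#' Compute the tile grid for an image plane
#'
#' Tiles a `width x height` plane with square tiles of side `tile_size`
#' that overlap by `overlap` pixels in both directions. Origins along each
#' axis advance by the stride `tile_size - overlap`; generation stops at the
#' first tile that reaches the edge, and that final tile is clipped to the
#' image bound (never shifted inward, so the tiles partition the plane
#' exactly when `overlap = 0` and no pixel is ever counted twice by an
#' aggregating analysis). Tiles are ordered row-major: y outer, x inner.
#'
#' @param width,height Plane dimensions in pixels.
#' @param tile_size Tile side in pixels.
#' @param overlap Pixels shared between adjacent tiles, identical for the X
#'   and Y directions; must be smaller than `tile_size`.
#' @return An object of class `tile_grid`: list with `tile_size`, `overlap`,
#'   `width`, `height`, `n_cols`, `n_rows` and `tiles`, a data frame in grid
#'   order with columns `x_origin`, `y_origin`, `width`, `height` (0-based
#'   origins; extents clipped at the edges).
#' @examples
#' g <- compute_grid(5000, 3000, tile_size = 2048, overlap = 0)
#' g$n_cols * g$n_rows  # 6 tiles
#' @export
compute_grid <- function(width, height, tile_size, overlap = 0) {
  for (v in list(width, height, tile_size, overlap))
    if (length(v) != 1L || is.na(v) || v != floor(v))
      st_parameter_error("grid parameters must be single integers")
  if (width < 1 || height < 1)
    st_parameter_error("image dimensions must be positive (got %dx%d)", width, height)
  if (tile_size < 1)
    st_parameter_error("tile_size must be at least 1")
  if (overlap < 0 || overlap >= tile_size)
    st_parameter_error("overlap must satisfy 0 <= overlap < tile_size (got overlap=%d, tile_size=%d)",
                       overlap, tile_size)
  stride <- tile_size - overlap
  axis_origins <- function(len) {
    if (tile_size >= len) return(0)
    (0:ceiling((len - tile_size) / stride)) * stride
  }
  xs <- axis_origins(width)
  ys <- axis_origins(height)
  tiles <- data.frame(
    x_origin = rep(xs, times = length(ys)),
    y_origin = rep(ys, each = length(xs))
  )
  tiles$width <- pmin(tile_size, width - tiles$x_origin)
  tiles$height <- pmin(tile_size, height - tiles$y_origin)
  structure(list(tile_size = tile_size, overlap = overlap,
                 width = width, height = height,
                 n_cols = length(xs), n_rows = length(ys),
                 tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("Tile grid: %d x %d tiles (%d total) over %dx%d px, tile %d px, overlap %d px\n",
              x$n_cols, x$n_rows, nrow(x$tiles), x$width, x$height,
              x$tile_size, x$overlap))
  invisible(x)
}

#' Build a tile file name encoding its slide position
#'
#' Extracted tiles are persisted under a name that makes them identifiable
#' after the run:
#' `<slide filename with extension>__<series>_<x origin>_<y origin>.tif`
#' (double underscore after the slide name, single underscores between the
#' three decimal integers, no padding). Origins are in the pixel grid of the
#' selected series, so the name is sufficient to re-extract the tile.
#'
#' @param slide_filename Original slide file name, extension included.
#' @param series 1-based series index.
#' @param x_origin,y_origin Tile origin in pixels (0-based).
#' @return The tile file name (no directory component).
#' @examples
#' tile_name("CMU-1.svs", 1, 2048, 4096)  # "CMU-1.svs__1_2048_4096.tif"
#' @export
tile_name <- function(slide_filename, series, x_origin, y_origin) {
  if (!is.character(slide_filename) || length(slide_filename) != 1L ||
      !nzchar(slide_filename))
    st_parameter_error("'slide_filename' must be a non-empty string")
  if (any(c(series, x_origin, y_origin) < 0) || series < 1)
    st_parameter_error("series must be >= 1 and origins >= 0")
  sprintf("%s__%d_%d_%d.tif", slide_filename,
          as.integer(series), as.integer(x_origin), as.integer(y_origin))
}

#' Parse a tile file name back into its components
#'
#' Exact inverse of [tile_name()]. Parsing anchors on the rightmost
#' `__<digits>_<digits>_<digits>.tif` suffix, so underscores (single or
#' double) inside the original slide file name never break the round trip.
#'
#' @param name A file name produced by [tile_name()] (directory part, if
#'   any, is ignored).
#' @return List with `slide_filename`, `series`, `x_origin`, `y_origin`.
#' @export
parse_tile_name <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    st_parse_error("tile name must be a single string")
  base <- basename(name)
  m <- regexec("^(.*)__([0-9]+)_([0-9]+)_([0-9]+)\\.tif$", base)[[1]]
  if (m[1] == -1 || attr(m, "match.length")[2] == 0)
    st_parse_error("'%s' does not match the tile name template", base)
  parts <- regmatches(base, list(regexec("^(.*)__([0-9]+)_([0-9]+)_([0-9]+)\\.tif$", base)[[1]]))[[1]]
  list(slide_filename = parts[2],
       series = as.integer(parts[3]),
       x_origin = as.integer(parts[4]),
       y_origin = as.integer(parts[5]))
}
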