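# Minimal TIFF 6.0 writer: 8-bit RGB, tiled or stripped, single image or
# multi-level pyramid (main-IFD chain or SubIFD dialect), uncompressed or
# Deflate. Files are always little-endian classic TIFF.
#
# Two layers: tiff_write_levels() takes pre-encoded segments (used by the
# synthetic slide generator, which streams storage tiles without holding a
# full level in memory) and write_image_tiff() takes pixel arrays.

.comp_code <- function(compression) {
  switch(compression,
         none = 1L, deflate = 8L,
         st_parameter_error("unknown compression '%s' (use 'none' or 'deflate')",
                            compression))
}

uint_to_raw <- function(x, size) {
  x <- as.numeric(x)
  out <- raw(length(x) * size)
  for (i in seq_len(size)) {
    out[seq(i, by = size, length.out = length(x))] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# (h, w, 3) integer array -> interleaved row-major bytes
.pixels_to_raw <- function(img) {
  as.raw(as.vector(aperm(img, c(3L, 2L, 1L))))
}

.encode_segment <- function(bytes, compression) {
  if (compression == "deflate") memCompress(bytes, type = "gzip") else bytes
}

# Cut an image array into full-size padded storage tiles (pad value 255 =
# white background) or strips, already compressed.
array_to_segments <- function(img, tile_size = NULL, rows_per_strip = NULL,
                              compression = "deflate") {
  h <- dim(img)[1]; w <- dim(img)[2]
  segs <- list()
  if (!is.null(tile_size)) {
    tw <- tile_size[1]; th <- if (length(tile_size) > 1) tile_size[2] else tile_size[1]
    for (ty in seq_len(ceiling(h / th)) - 1L) {
      for (tx in seq_len(ceiling(w / tw)) - 1L) {
        rows <- (ty * th + 1):min(h, (ty + 1) * th)
        cols <- (tx * tw + 1):min(w, (tx + 1) * tw)
        full <- array(255L, dim = c(th, tw, 3L))
        full[seq_along(rows), seq_along(cols), ] <- img[rows, cols, , drop = FALSE]
        segs[[length(segs) + 1L]] <- .encode_segment(.pixels_to_raw(full), compression)
      }
    }
  } else {
    if (is.null(rows_per_strip))
      rows_per_strip <- max(1L, min(h, floor(65536 / (w * 3))))
    for (s in seq_len(ceiling(h / rows_per_strip)) - 1L) {
      rows <- (s * rows_per_strip + 1):min(h, (s + 1) * rows_per_strip)
      segs[[length(segs) + 1L]] <-
        .encode_segment(.pixels_to_raw(img[rows, , , drop = FALSE]), compression)
    }
    attr(segs, "rows_per_strip") <- rows_per_strip
  }
  segs
}

.level_entries <- function(lv, seg_offsets, sub_offsets = NULL) {
  ent <- list()
  add <- function(tag, type, values) ent[[length(ent) + 1L]] <<-
    list(tag = tag, type = type, values = as.numeric(values))
  add(254L, 4L, lv$subfile_type)
  add(256L, 4L, lv$width)
  add(257L, 4L, lv$height)
  add(258L, 3L, c(8, 8, 8))
  add(259L, 3L, lv$compression_code)
  add(262L, 3L, 2)           # RGB
  add(274L, 3L, 1)           # top-left orientation
  add(277L, 3L, 3)
  add(284L, 3L, 1)           # chunky
  if (!is.null(sub_offsets) && length(sub_offsets)) add(330L, 4L, sub_offsets)
  if (!is.null(lv$tile_w)) {
    add(322L, 4L, lv$tile_w)
    add(323L, 4L, lv$tile_h)
    add(324L, 4L, seg_offsets)
    add(325L, 4L, lv$seg_sizes)
  } else {
    add(273L, 4L, seg_offsets)
    add(278L, 4L, lv$rows_per_strip)
    add(279L, 4L, lv$seg_sizes)
  }
  ent[order(vapply(ent, `[[`, 0, "tag"))]
}

.entries_ext_size <- function(entries) {
  sum(vapply(entries, function(e) {
    total <- .tiff_type_size[e$type] * length(e$values)
    if (total > 4) total else 0L
  }, 0))
}

.serialize_ifd <- function(entries, ifd_offset, next_offset) {
  n <- length(entries)
  ext_base <- ifd_offset + 2 + 12 * n + 4
  ext <- raw(0)
  body <- uint_to_raw(n, 2L)
  for (e in entries) {
    size <- .tiff_type_size[e$type]
    total <- size * length(e$values)
    vraw <- uint_to_raw(e$values, size)
    body <- c(body, uint_to_raw(e$tag, 2L), uint_to_raw(e$type, 2L),
              uint_to_raw(length(e$values), 4L))
    if (total <= 4) {
      body <- c(body, vraw, raw(4L - total))
    } else {
      body <- c(body, uint_to_raw(ext_base + length(ext), 4L))
      ext <- c(ext, vraw)
    }
  }
  c(body, uint_to_raw(next_offset, 4L), ext)
}

# levels: list of lists with fields width, height, segments (list of raw),
# compression_code, and either tile_w/tile_h or rows_per_strip.
# subfile_type is set automatically (0 for level 1, 1 for reduced levels).
tiff_write_levels <- function(path, levels, subifd = FALSE) {
  nlev <- length(levels)
  for (i in seq_len(nlev)) {
    levels[[i]]$subfile_type <- if (i == 1L) 0L else 1L
    levels[[i]]$seg_sizes <- vapply(levels[[i]]$segments, length, 0L)
  }
  # layout: header | all segment data | IFD blocks (entries + external values)
  pos <- 8
  for (i in seq_len(nlev)) {
    levels[[i]]$seg_offsets <- pos + cumsum(c(0, levels[[i]]$seg_sizes))[seq_along(levels[[i]]$seg_sizes)]
    pos <- pos + sum(levels[[i]]$seg_sizes)
  }
  # IFD sizes are computable before offsets are known: entry count and
  # external sizes do not depend on the offset values themselves
  ifd_offsets <- numeric(nlev)
  for (i in seq_len(nlev)) {
    sub_stub <- if (subifd && i == 1L && nlev > 1L) numeric(nlev - 1L) else NULL
    ent <- .level_entries(levels[[i]], levels[[i]]$seg_offsets, sub_stub)
    ifd_offsets[i] <- pos
    pos <- pos + 2 + 12 * length(ent) + 4 + .entries_ext_size(ent)
  }
  if (pos >= 2^32)
    st_parameter_error("image too large for classic TIFF (file would exceed 4 GiB)")

  blob <- vector("list", 2L + nlev)
  blob[[1L]] <- c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), uint_to_raw(ifd_offsets[1], 4L))
  blob[[2L]] <- do.call(c, unlist(lapply(levels, `[[`, "segments"), recursive = FALSE))
  for (i in seq_len(nlev)) {
    sub_off <- if (subifd && i == 1L && nlev > 1L) ifd_offsets[-1L] else NULL
    next_off <- if (subifd) 0 else if (i < nlev) ifd_offsets[i + 1L] else 0
    ent <- .level_entries(levels[[i]], levels[[i]]$seg_offsets, sub_off)
    blob[[2L + i]] <- .serialize_ifd(ent, ifd_offsets[i], next_off)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in blob) writeBin(b, con)
  invisible(path)
}

#' Write an 8-bit RGB image (or image pyramid) as TIFF
#'
#' Writes classic little-endian TIFF 6.0. A single array gives a
#' single-directory file; a list of arrays gives a multi-resolution file,
#' stored either as a chain of main image directories (the common pyramidal
#' TIFF dialect) or with reduced levels attached as SubIFDs.
#'
#' @param img An integer array `h x w x 3` with values 0..255, or a list of
#'   such arrays ordered from highest resolution down.
#' @param path Output file path.
#' @param internal_tile Storage tile side in pixels; `NULL` writes a
#'   stripped file.
#' @param compression `"deflate"` (zlib) or `"none"`.
#' @param subifd If `TRUE` and `img` is a multi-level list, attach reduced
#'   levels as SubIFDs of the first directory instead of chaining them.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(img, path, internal_tile = NULL,
                             compression = "deflate", subifd = FALSE) {
  code <- .comp_code(compression)
  if (!is.list(img)) img <- list(img)
  levels <- lapply(img, function(a) {
    a <- .as_rgb8(a)
    lv <- list(width = dim(a)[2], height = dim(a)[1], compression_code = code)
    if (!is.null(internal_tile)) {
      lv$tile_w <- internal_tile; lv$tile_h <- internal_tile
      lv$segments <- array_to_segments(a, tile_size = internal_tile,
                                       compression = compression)
    } else {
      segs <- array_to_segments(a, compression = compression)
      lv$rows_per_strip <- attr(segs, "rows_per_strip")
      lv$segments <- segs
    }
    lv
  })
  tiff_write_levels(path, levels, subifd = subifd)
}

.as_rgb8 <- function(a) {
  if (!is.array(a) || length(dim(a)) != 3L || dim(a)[3] != 3L)
    st_parameter_error("expected an h x w x 3 RGB array")
  storage.mode(a) <- "integer"
  if (anyNA(a) || min(a) < 0L || max(a) > 255L)
    st_parameter_error("RGB values must be integers in 0..255")
  a
}
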