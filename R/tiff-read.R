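# Minimal TIFF 6.0 reader for whole-slide use: enumerates image directories
# (classic main-IFD chains and SubIFD-attached pyramid levels) and decodes
# arbitrary rectangular regions of a directory, touching only the storage
# tiles / strips that intersect the request. Memory is bounded by the region
# plus one storage segment, never the full image.
#
# Supported: 8-bit RGB, chunky planar layout, tiled or stripped,
# compression none (1), LZW (5), Deflate/zlib (8 and 32946), horizontal
# predictor. BigTIFF and JPEG-in-TIFF are rejected with an
# unsupported-format error.

# TIFF field type byte widths, indexed by type code 1..13
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L, 4L)

.TAG <- list(
  subfile_type = 254L, width = 256L, height = 257L, bits = 258L,
  compression = 259L, photometric = 262L, strip_offsets = 273L,
  spp = 277L, rows_per_strip = 278L, strip_counts = 279L,
  planar = 284L, predictor = 317L, tile_w = 322L, tile_h = 323L,
  tile_offsets = 324L, tile_counts = 325L, subifds = 330L
)

# little/big-endian unsigned integers from raw; returns doubles so 32-bit
# offsets above 2^31 survive
raw_to_uint <- function(r, size, endian) {
  m <- matrix(as.integer(r), nrow = size)
  if (endian == "big") m <- m[rev(seq_len(size)), , drop = FALSE]
  as.numeric(drop(256^(seq_len(size) - 1) %*% m))
}

.read_tag_values <- function(con, endian, type, count, value_raw) {
  if (type < 1L || type > 13L) return(NULL)
  size <- .tiff_type_size[type]
  total <- size * count
  if (total <= 4) {
    data <- value_raw[seq_len(total)]
  } else {
    off <- raw_to_uint(value_raw, 4L, endian)
    seek(con, off)
    data <- readBin(con, "raw", total)
    if (length(data) < total) st_unsupported_format("truncated TIFF tag data")
  }
  if (type %in% c(3L, 8L)) raw_to_uint(data, 2L, endian)
  else if (type %in% c(4L, 9L, 13L)) raw_to_uint(data, 4L, endian)
  else if (type %in% c(1L, 6L, 7L)) as.numeric(as.integer(data))
  else NULL  # rationals/floats/ascii: not needed for any tag we consume
}

.parse_ifd <- function(con, endian, offset, file_size) {
  if (offset <= 0 || offset + 2 > file_size)
    st_unsupported_format("TIFF directory offset out of file bounds")
  seek(con, offset)
  n <- raw_to_uint(readBin(con, "raw", 2L), 2L, endian)
  if (n < 1 || offset + 2 + 12 * n + 4 > file_size)
    st_unsupported_format("truncated TIFF directory")
  block <- readBin(con, "raw", 12L * n + 4L)
  entries <- list()
  for (i in seq_len(n)) {
    e <- block[(12L * (i - 1L) + 1L):(12L * i)]
    tag <- raw_to_uint(e[1:2], 2L, endian)
    type <- raw_to_uint(e[3:4], 2L, endian)
    count <- raw_to_uint(e[5:8], 4L, endian)
    pos_after <- seek(con, NA)
    vals <- .read_tag_values(con, endian, as.integer(type), count, e[9:12])
    seek(con, pos_after)
    if (!is.null(vals)) entries[[as.character(tag)]] <- vals
  }
  next_off <- raw_to_uint(block[(12L * n + 1L):(12L * n + 4L)], 4L, endian)
  list(entries = entries, next_offset = next_off)
}

.normalize_ifd <- function(entries, path) {
  g <- function(tag, default = NULL) {
    v <- entries[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  width <- g(.TAG$width); height <- g(.TAG$height)
  if (is.null(width) || is.null(height))
    st_unsupported_format("TIFF directory without image dimensions in '%s'", path)
  tiled <- !is.null(g(.TAG$tile_offsets))
  meta <- list(
    width = width, height = height,
    bits = g(.TAG$bits, 1), spp = g(.TAG$spp, 1),
    compression = g(.TAG$compression, 1),
    photometric = g(.TAG$photometric, 1),
    planar = g(.TAG$planar, 1), predictor = g(.TAG$predictor, 1),
    subfile_type = g(.TAG$subfile_type, 0),
    tiled = tiled,
    subifds = g(.TAG$subifds, numeric(0))
  )
  if (tiled) {
    meta$tile_w <- g(.TAG$tile_w); meta$tile_h <- g(.TAG$tile_h)
    meta$offsets <- g(.TAG$tile_offsets); meta$counts <- g(.TAG$tile_counts)
  } else {
    meta$rows_per_strip <- min(g(.TAG$rows_per_strip, height), height)
    meta$offsets <- g(.TAG$strip_offsets); meta$counts <- g(.TAG$strip_counts)
  }
  if (is.null(meta$offsets) || is.null(meta$counts))
    st_unsupported_format("TIFF directory without pixel data locations in '%s'", path)
  meta
}

# Parse file structure only; no pixel data is read.
tiff_meta <- function(path) {
  file_size <- file.info(path)$size
  if (is.na(file_size) || file_size < 8)
    st_unsupported_format("'%s' is not a readable TIFF file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 8L)
  endian <- if (identical(hdr[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(hdr[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else st_unsupported_format("'%s' is not a TIFF file (bad byte-order mark)", path)
  magic <- raw_to_uint(hdr[3:4], 2L, endian)
  if (magic == 43)
    st_unsupported_format("'%s' is a BigTIFF file, which is not supported", path)
  if (magic != 42)
    st_unsupported_format("'%s' is not a TIFF file (bad magic number)", path)

  ifds <- list()
  off <- raw_to_uint(hdr[5:8], 4L, endian)
  seen <- character(0)
  while (off != 0) {
    key <- as.character(off)
    if (key %in% seen || length(seen) >= 1000L)
      st_unsupported_format("cyclic TIFF directory chain in '%s'", path)
    seen <- c(seen, key)
    parsed <- .parse_ifd(con, endian, off, file_size)
    main <- .normalize_ifd(parsed$entries, path)
    ifds[[length(ifds) + 1L]] <- main
    # SubIFD pyramid dialect: levels hang off the parent directory
    for (soff in main$subifds) {
      sub <- .parse_ifd(con, endian, soff, file_size)
      ifds[[length(ifds) + 1L]] <- .normalize_ifd(sub$entries, path)
    }
    off <- parsed$next_offset
  }
  if (!length(ifds))
    st_unsupported_format("no image directories found in '%s'", path)
  list(path = path, endian = endian, ifds = ifds)
}

# TIFF-variant LZW (MSB-first codes, clear 256, EOI 257, early code-width
# change). Decode-only; used for compatibility with LZW slides.
lzw_decode <- function(input, max_out) {
  bits <- as.integer(rawToBits(input))
  dim(bits) <- c(8L, length(input))
  bits <- as.vector(bits[8:1, , drop = FALSE])
  nbits <- length(bits)
  dict <- vector("list", 4096L)
  for (i in 0:255) dict[[i + 1L]] <- i
  out <- integer(max_out)
  opos <- 0L
  pos <- 1L
  width <- 9L
  next_code <- 258L
  prev <- NULL
  repeat {
    if (pos + width - 1L > nbits) break
    code <- sum(bits[pos:(pos + width - 1L)] * 2^((width - 1L):0))
    pos <- pos + width
    if (code == 256) { width <- 9L; next_code <- 258L; prev <- NULL; next }
    if (code == 257) break
    if (code < next_code && !is.null(dict[[code + 1L]])) {
      entry <- dict[[code + 1L]]
    } else if (!is.null(prev)) {
      entry <- c(prev, prev[1L])
    } else st_unsupported_format("corrupt LZW stream")
    n <- length(entry)
    if (opos + n > max_out) { entry <- entry[seq_len(max_out - opos)]; n <- length(entry) }
    out[(opos + 1L):(opos + n)] <- entry
    opos <- opos + n
    if (opos >= max_out) break
    if (!is.null(prev) && next_code < 4096L) {
      dict[[next_code + 1L]] <- c(prev, entry[1L])
      next_code <- next_code + 1L
      if (next_code == 2^width - 1L && width < 12L) width <- width + 1L
    }
    prev <- entry
  }
  as.raw(out[seq_len(opos)])
}

.decode_segment <- function(con, meta, idx, seg_w, seg_h) {
  expected <- seg_w * seg_h * 3L
  seek(con, meta$offsets[idx])
  rawdat <- readBin(con, "raw", meta$counts[idx])
  if (length(rawdat) < meta$counts[idx])
    st_unsupported_format("truncated pixel data in TIFF segment %d", idx)
  comp <- meta$compression
  data <- if (comp == 1) rawdat
          else if (comp %in% c(8, 32946)) memDecompress(rawdat, type = "gzip")
          else if (comp == 5) lzw_decode(rawdat, expected)
          else st_unsupported_format("unsupported TIFF compression code %d", comp)
  if (length(data) < expected)
    st_unsupported_format("short pixel data in TIFF segment %d", idx)
  if (length(data) > expected) data <- data[seq_len(expected)]
  a <- as.integer(data)
  dim(a) <- c(3L, seg_w, seg_h)
  if (meta$predictor == 2) {
    for (i in 2:seg_w) a[, i, ] <- (a[, i, ] + a[, i - 1L, ]) %% 256L
  }
  aperm(a, c(3L, 2L, 1L))  # -> (rows, cols, channel)
}

.check_rgb8 <- function(meta) {
  if (!all(meta$bits == 8) || meta$spp < 3)
    st_unsupported_format("only 8-bit RGB images are supported (bits=%s, samples=%d)",
                          paste(meta$bits, collapse = ","), meta$spp)
  if (meta$spp != 3)
    st_unsupported_format("images with %d samples per pixel are not supported", meta$spp)
  if (meta$planar != 1)
    st_unsupported_format("planar (non-interleaved) TIFF layout is not supported")
  invisible(TRUE)
}

# Decode the rectangle [x, x+w) x [y, y+h) of one directory. 0-based,
# half-open, x = column, y = row, in the pixel grid of that directory.
tiff_read_region <- function(meta_file, series, x, y, w, h) {
  meta <- meta_file$ifds[[series]]
  .check_rgb8(meta)
  con <- file(meta_file$path, "rb")
  on.exit(close(con))
  if (meta$tiled) {
    tw <- meta$tile_w; th <- meta$tile_h
    across <- ceiling(meta$width / tw)
    tx_range <- (x %/% tw):((x + w - 1) %/% tw)
    ty_range <- (y %/% th):((y + h - 1) %/% th)
    # aligned single-tile request: return the decoded tile directly rather
    # than copying it into a fresh buffer (the common case when the
    # extraction tile size is a multiple of the storage tile size)
    if (length(tx_range) == 1L && length(ty_range) == 1L &&
        x == tx_range * tw && y == ty_range * th && w == tw && h == th) {
      return(.decode_segment(con, meta, ty_range * across + tx_range + 1, tw, th))
    }
  }
  out <- array(0L, dim = c(h, w, 3L))
  if (meta$tiled) {
    for (ty in ty_range) {
      for (tx in tx_range) {
        idx <- ty * across + tx + 1
        tile <- .decode_segment(con, meta, idx, tw, th)
        gx0 <- max(x, tx * tw); gx1 <- min(x + w, (tx + 1) * tw) - 1
        gy0 <- max(y, ty * th); gy1 <- min(y + h, (ty + 1) * th) - 1
        out[(gy0:gy1) - y + 1, (gx0:gx1) - x + 1, ] <-
          tile[(gy0:gy1) - ty * th + 1, (gx0:gx1) - tx * tw + 1, ]
      }
    }
  } else {
    rps <- meta$rows_per_strip
    for (s in (y %/% rps):((y + h - 1) %/% rps)) {
      rows <- min(meta$height, (s + 1) * rps) - s * rps
      strip <- .decode_segment(con, meta, s + 1, meta$width, rows)
      gy0 <- max(y, s * rps); gy1 <- min(y + h, s * rps + rows) - 1
      out[(gy0:gy1) - y + 1, , ] <-
        strip[(gy0:gy1) - s * rps + 1, (x + 1):(x + w), ]
    }
  }
  out
}
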