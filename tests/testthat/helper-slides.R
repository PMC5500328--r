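# Shared fixture builders. All fixtures are generated in code at test
# time; nothing binary is stored in the repository.

rand_rgb <- function(w, h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(sample.int(256L, w * h * 3L, replace = TRUE) - 1L, dim = c(h, w, 3L))
}

# whole-image oracle through the independent libtiff-based reader;
# readTIFF normalizes to 0..1 doubles
read_tiff_oracle <- function(path, ifd = 1) {
  ref <- tiff::readTIFF(path, all = TRUE)[[ifd]]
  ref <- round(ref * 255)
  storage.mode(ref) <- "integer"
  ref
}

# generate a synthetic slide into dir and return path + ground truth
gen_slide <- function(dir, name = "slide.tif", width = 512, height = 384,
                      n_blue = 0, n_brown = 0, radius = 20, seed = 1,
                      internal_tile = 128, n_levels = 1, ...) {
  path <- file.path(dir, name)
  spec <- synthetic_slide_spec(width, height, n_blue = n_blue,
                               n_brown = n_brown, object_radius = radius,
                               seed = seed, internal_tile = internal_tile,
                               n_levels = n_levels, ...)
  gt <- generate_slide(spec, path)
  list(path = path, gt = gt)
}

# processor that records every context it sees
recording_processor <- function(log) {
  force(log)
  function(tile, context, store) {
    log$contexts[[length(log$contexts) + 1L]] <- context
    log$dims[[length(log$dims) + 1L]] <- dim(tile)
    invisible(NULL)
  }
}

# brute-force per-pixel tile cover counts — the coverage oracle
cover_counts <- function(width, height, grid) {
  cov <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_len(nrow(grid$tiles))) {
    tl <- grid$tiles[i, ]
    rows <- (tl$y_origin + 1):(tl$y_origin + tl$height)
    cols <- (tl$x_origin + 1):(tl$x_origin + tl$width)
    cov[rows, cols] <- cov[rows, cols] + 1L
  }
  cov
}

# independent 3x3 inverse via the explicit adjugate formula, kept separate
# from the solve()-based implementation path
adjugate_solve <- function(m, b) {
  a <- m
  det <- a[1,1]*(a[2,2]*a[3,3]-a[2,3]*a[3,2]) -
         a[1,2]*(a[2,1]*a[3,3]-a[2,3]*a[3,1]) +
         a[1,3]*(a[2,1]*a[3,2]-a[2,2]*a[3,1])
  inv <- matrix(c(
     a[2,2]*a[3,3]-a[2,3]*a[3,2], -(a[1,2]*a[3,3]-a[1,3]*a[3,2]),  a[1,2]*a[2,3]-a[1,3]*a[2,2],
    -(a[2,1]*a[3,3]-a[2,3]*a[3,1]), a[1,1]*a[3,3]-a[1,3]*a[3,1], -(a[1,1]*a[2,3]-a[1,3]*a[2,1]),
     a[2,1]*a[3,2]-a[2,2]*a[3,1], -(a[1,1]*a[3,2]-a[1,2]*a[3,1]),  a[1,1]*a[2,2]-a[1,2]*a[2,1]),
    nrow = 3, byrow = TRUE) / det
  inv %*% b
}
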