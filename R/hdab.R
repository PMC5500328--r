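# Reference per-tile analyses: hematoxylin/DAB positivity by color
# deconvolution. Brightfield absorbance is additive in optical-density
# space, so an RGB pixel is modeled as od = M %*% c with M the 3x3 matrix
# of per-stain unit absorbance vectors and c the stain "concentrations";
# inverting M separates the stains. Positivity is the DAB-positive area as
# a percentage of the stained (hematoxylin + DAB) area — a simple
# biomarker-expression proxy, not a clinical-grade score.

#' Default H/DAB stain basis
#'
#' Unit absorbance (optical-density) vectors for hematoxylin and DAB in
#' R, G, B order — the standard published H-DAB calibration — with the
#' residual channel completed as their normalized cross product. Users with
#' their own stain calibration can pass custom vectors.
#'
#' @param h,d Length-3 nonnegative absorbance vectors for hematoxylin and
#'   DAB; normalized internally.
#' @return 3x3 matrix whose columns (`H`, `DAB`, `Res`) have unit norm.
#' @export
hdab_basis <- function(h = c(0.650, 0.704, 0.286),
                       d = c(0.268, 0.570, 0.776)) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) st_parameter_error("stain vector must be non-zero")
    v / n
  }
  h <- unit(h); d <- unit(d)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(r^2)) < 1e-9)
    st_parameter_error("stain vectors are collinear; basis would be singular")
  m <- cbind(H = h, DAB = d, Res = unit(r))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Convert an 8-bit RGB image to optical density
#'
#' Per channel, `OD = -log10(max(I, 1) / 255)`: white (255) maps to exactly
#' 0 absorbance and the clamp at 1 bounds the OD of saturated black pixels
#' at `-log10(1/255)`.
#'
#' @param img Integer array `h x w x 3`, values 0..255.
#' @return Double array `h x w x 3` of nonnegative optical densities.
#' @export
rgb_to_od <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    st_parameter_error("expected an h x w x 3 RGB array")
  # algebraically -log10(pmax(I,1)/255); clamping while still integer
  # avoids one full-size double temporary on large tiles
  log10(255) - log10(pmax(img, 1L))
}

#' Separate stains by color deconvolution
#'
#' Solves `M c = od` per pixel, where the columns of `M` are the stain
#' absorbance vectors of the basis.
#'
#' @param od Optical-density array from [rgb_to_od()].
#' @param basis 3x3 stain matrix from [hdab_basis()].
#' @return List of three `h x w` concentration maps `h`, `d`, `res`.
#' @export
deconvolve <- function(od, basis) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    st_parameter_error("expected an h x w x 3 optical-density array")
  rc <- rcond(basis)
  if (!is.finite(rc) || rc < 1e-12)
    st_stop("st_basis_error", "stain basis is singular or near-singular")
  d <- dim(od)
  odm <- aperm(od, c(3L, 1L, 2L))     # 3 x N, pixels column-wise
  dim(odm) <- c(3L, d[1] * d[2])
  conc <- solve(basis, odm)
  shape <- function(row) matrix(conc[row, ], nrow = d[1], ncol = d[2])
  list(h = shape(1L), d = shape(2L), res = shape(3L))
}

#' Classify pixels as hematoxylin-only or DAB-positive
#'
#' A pixel is brown (DAB-positive) when its DAB concentration reaches
#' `tau_d`; otherwise it is blue when its hematoxylin concentration reaches
#' `tau_h`. DAB takes precedence, so a DAB-positive nucleus counts as
#' positive regardless of counterstain and the two masks are disjoint.
#' Background pixels (neither threshold reached) belong to no mask.
#'
#' @param conc_h,conc_d Concentration maps from [deconvolve()].
#' @param tau_h,tau_d Positive OD thresholds. The defaults (0.15) are
#'   validated against the synthetic slide generator only; they are not a
#'   clinical calibration.
#' @return List of two disjoint logical masks `blue`, `brown`.
#' @export
classify_hdab <- function(conc_h, conc_d, tau_h = 0.15, tau_d = 0.15) {
  if (!isTRUE(tau_h > 0) || !isTRUE(tau_d > 0))
    st_parameter_error("thresholds must be positive")
  brown <- conc_d >= tau_d
  blue <- conc_h >= tau_h & !brown
  list(blue = blue, brown = brown)
}

#' Positivity from blue/brown pixel areas
#'
#' @param blue_area,brown_area Nonnegative pixel counts.
#' @return List of class `positivity_result` with `blue_area`,
#'   `brown_area` and `positivity_pct` = `100 * brown / (blue + brown)` on
#'   the 0–100 scale; by convention 0 when no pixel is stained (blank
#'   tile), which keeps slide-level aggregation well defined.
#' @export
positivity <- function(blue_area, brown_area) {
  if (blue_area < 0 || brown_area < 0)
    st_parameter_error("areas must be nonnegative")
  total <- blue_area + brown_area
  pct <- if (total > 0) 100 * brown_area / total else 0
  structure(list(blue_area = blue_area, brown_area = brown_area,
                 positivity_pct = pct),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf("H/DAB positivity: blue %d px, brown %d px, %.4g%% positive\n",
              as.integer(x$blue_area), as.integer(x$brown_area),
              x$positivity_pct))
  invisible(x)
}

# Shared per-tile measurement used by both built-in processors. Same
# linear algebra as deconvolve()/classify_hdab() (asserted equal in the
# tests) but accumulates the two stain rows channel-plane-wise, so a large
# tile never materializes the 3-channel OD array or the residual map.
.hdab_measure <- function(tile, basis, tau_h, tau_d) {
  rc <- rcond(basis)
  if (!is.finite(rc) || rc < 1e-12)
    st_stop("st_basis_error", "stain basis is singular or near-singular")
  inv <- solve(basis)
  conc_h <- 0; conc_d <- 0
  for (ch in 1:3) {
    od <- log10(255) - log10(pmax(tile[, , ch], 1L))
    conc_h <- conc_h + inv[1L, ch] * od
    conc_d <- conc_d + inv[2L, ch] * od
  }
  masks <- classify_hdab(conc_h, conc_d, tau_h, tau_d)
  list(blue = sum(masks$blue), brown = sum(masks$brown))
}

#' Built-in H/DAB processors
#'
#' `hdab_tile_processor` appends one row per tile to the `"tiles"` table
#' (slide, series, x, y, blue and brown pixel area, positivity
#' percentage). `hdab_slide_processor` accumulates blue/brown running
#' totals in the variable store and, on a slide's last tile, appends one
#' row per slide to the `"slides"` table. Both are available to
#' [load_processor()] and the CLI under the names `"hdab_tile"` and
#' `"hdab_slide"`.
#'
#' With a non-zero tile overlap, overlapped pixels are counted once per
#' covering tile, so slide-level areas are inflated;
#' `hdab_slide_processor` warns once per slide in that case. Quantification
#' runs should use overlap 0 (overlap exists to keep boundary objects
#' whole, not for area fractions).
#'
#' @param basis Stain matrix from [hdab_basis()].
#' @param tau_h,tau_d Classification thresholds, see [classify_hdab()].
#' @return A processor `function(tile, context, store)`.
#' @export
hdab_tile_processor <- function(basis = hdab_basis(), tau_h = 0.15, tau_d = 0.15) {
  force(basis); force(tau_h); force(tau_d)
  function(tile, context, store) {
    m <- .hdab_measure(tile, basis, tau_h, tau_d)
    p <- positivity(m$blue, m$brown)
    append_row(store, "tiles", list(
      slide = context$slide_filename, series = context$series,
      x = context$x_origin, y = context$y_origin,
      blue_area = m$blue, brown_area = m$brown,
      positivity_pct = p$positivity_pct))
    invisible(NULL)
  }
}

#' @rdname hdab_tile_processor
#' @export
hdab_slide_processor <- function(basis = hdab_basis(), tau_h = 0.15, tau_d = 0.15) {
  force(basis); force(tau_h); force(tau_d)
  function(tile, context, store) {
    if (isTRUE(context$overlap > 0) && context$tile_index == 1L)
      warning(sprintf(
        "slide '%s': overlap %d > 0 double-counts overlapped pixels in slide-level areas; use overlap 0 for quantification",
        context$slide_filename, context$overlap), call. = FALSE)
    m <- .hdab_measure(tile, basis, tau_h, tau_d)
    kb <- paste0(".hdab_blue__", context$slide_filename)
    kd <- paste0(".hdab_brown__", context$slide_filename)
    blue <- (if (has_var(store, kb)) get_var(store, kb) else 0) + m$blue
    brown <- (if (has_var(store, kd)) get_var(store, kd) else 0) + m$brown
    set_var(store, kb, blue)
    set_var(store, kd, brown)
    if (context$tile_index == context$n_tiles) {
      p <- positivity(blue, brown)
      append_row(store, "slides", list(
        slide = context$slide_filename,
        blue_area = blue, brown_area = brown,
        positivity_pct = p$positivity_pct))
    }
    invisible(NULL)
  }
}

#' Find the tile with maximum H/DAB positivity
#'
#' Looks up the `"tiles"` table written by the `hdab_tile` processor and
#' returns the template file name of the row with the highest positivity
#' percentage (ties resolve to the first-appended row). When the run kept
#' its tiles, that file still exists under `<output>/tiles/` and can be
#' re-opened for follow-up processing.
#'
#' @param store A [results_store()] holding a non-empty `"tiles"` table.
#' @return The tile file name, with the winning row attached as attribute
#'   `"row"`.
#' @export
max_positivity_tile <- function(store) {
  .check_store(store)
  if (!"tiles" %in% table_names(store))
    st_no_data("the results store has no 'tiles' table; run the hdab_tile processor first")
  df <- get_table(store, "tiles")
  if (!nrow(df)) st_no_data("the 'tiles' table is empty")
  i <- which.max(df$positivity_pct)  # which.max returns the first maximum
  nm <- tile_name(df$slide[i], df$series[i], df$x[i], df$y[i])
  structure(nm, row = df[i, , drop = FALSE])
}
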