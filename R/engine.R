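# The batch workflow: iterate the tile grid of each slide, persist every
# tile as TIFF under its template name, hand it to the per-tile processor
# together with its context and the shared results store, honor the
# keep/delete preference, and keep going when a tile fails — unsupervised
# overnight batches must not die mid-run.

#' Build and validate a run configuration
#'
#' Mirrors the parameter set of an interactive batch dialog: where the
#' slides come from, where results go, which processor runs on each tile,
#' which resolution series is tiled, the tile geometry, and whether
#' extracted tiles are kept after processing.
#'
#' @param input Folder of slides, or a single slide file.
#' @param output Output folder; tiles go to `<output>/tiles/`, the results
#'   store to `<output>/results/`.
#' @param processor Built-in processor name or path to a processor script,
#'   resolved by [load_processor()]. Default `"void"` (pure tile export).
#' @param series 1-based resolution series to process (1 = highest
#'   resolution in the usual pyramid layout).
#' @param tile_size Tile side in pixels.
#' @param overlap Overlap between adjacent tiles in pixels, identical for X
#'   and Y; `0 <= overlap < tile_size`.
#' @param keep_tiles Keep extracted tile files after processing (`FALSE`
#'   deletes each tile once its processor invocation returns).
#' @param tile_compression Compression for persisted tiles, `"none"`
#'   (default; readable everywhere) or `"deflate"`.
#' @param quiet Suppress per-tile progress messages on standard error.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, output, processor = "void", series = 1L,
                       tile_size = 2048L, overlap = 0L, keep_tiles = FALSE,
                       tile_compression = "none", quiet = FALSE) {
  for (v in list(series = series, tile_size = tile_size, overlap = overlap))
    if (length(v) != 1L || is.na(v) || v != floor(v))
      st_config_error("series, tile_size and overlap must be single integers")
  if (series < 1) st_config_error("series must be >= 1")
  if (tile_size < 1) st_config_error("tile_size must be >= 1")
  if (overlap < 0 || overlap >= tile_size)
    st_config_error("overlap must satisfy 0 <= overlap < tile_size (got %d, tile_size %d)",
                    overlap, tile_size)
  .comp_code(tile_compression)
  structure(list(input = input, output = output, processor = processor,
                 series = as.integer(series), tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), keep_tiles = isTRUE(keep_tiles),
                 tile_compression = tile_compression, quiet = isTRUE(quiet)),
            class = "run_config")
}

#' Resolve a processor reference to a processor function
#'
#' A processor is `function(tile, context, store)`: it receives the tile
#' pixel array (integer `h x w x 3`), a tile context (list with
#' `slide_filename`, `series`, `x_origin`, `y_origin`, `tile_width`,
#' `tile_height`, `tile_path`, `tile_index`, `n_tiles`, `tile_size`,
#' `overlap`), and the shared [results_store()]. Its return value is
#' ignored; it must not retain the pixel array beyond the call.
#'
#' Built-ins: `"void"` (do nothing; with `keep_tiles = TRUE` this is the
#' pure tile-export mode), `"manifest"` (append one row per tile to a
#' `"tiles"` table), `"hdab_tile"` and `"hdab_slide"` (see
#' [hdab_tile_processor()]). Any other reference must be the path of an R
#' script that defines a function `process_tile(tile, context, store)`;
#' the script is sourced into its own environment.
#'
#' @param processor_ref Built-in name or script path.
#' @param options Named list of options for built-ins that take them
#'   (`basis`, `tau_h`, `tau_d` for the H/DAB processors).
#' @return A processor function.
#' @export
load_processor <- function(processor_ref, options = list()) {
  if (is.function(processor_ref)) return(processor_ref)
  if (!is.character(processor_ref) || length(processor_ref) != 1L)
    st_load_error("processor reference must be a built-in name or a script path")
  hdab_args <- function() {
    a <- list()
    if (!is.null(options$basis)) a$basis <- options$basis
    if (!is.null(options$tau_h)) a$tau_h <- options$tau_h
    if (!is.null(options$tau_d)) a$tau_d <- options$tau_d
    a
  }
  switch(processor_ref,
    void = function(tile, context, store) invisible(NULL),
    manifest = function(tile, context, store) {
      append_row(store, "tiles", list(
        slide = context$slide_filename, series = context$series,
        x = context$x_origin, y = context$y_origin,
        width = context$tile_width, height = context$tile_height,
        tile_path = context$tile_path))
      invisible(NULL)
    },
    hdab_tile = do.call(hdab_tile_processor, hdab_args()),
    hdab_slide = do.call(hdab_slide_processor, hdab_args()),
    {
      if (!file.exists(processor_ref))
        st_load_error("unknown processor '%s': not a built-in (void, manifest, hdab_tile, hdab_slide) and no such file",
                      processor_ref)
      env <- new.env(parent = globalenv())
      ok <- tryCatch({ sys.source(processor_ref, envir = env); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok))
        st_load_error("error sourcing processor script '%s': %s",
                      processor_ref, conditionMessage(ok))
      fn <- env$process_tile
      if (!is.function(fn) || length(formals(fn)) < 3L)
        st_load_error("processor script '%s' must define process_tile(tile, context, store)",
                      processor_ref)
      fn
    })
}

.prepare_output <- function(config) {
  tiles_dir <- file.path(config$output, "tiles")
  if (!dir.exists(tiles_dir) &&
      !dir.create(tiles_dir, recursive = TRUE, showWarnings = FALSE))
    st_config_error("cannot create output folder '%s'", tiles_dir)
  probe <- file.path(tiles_dir, ".write-probe")
  if (!file.create(probe, showWarnings = FALSE))
    st_config_error("output folder '%s' is not writable", tiles_dir)
  unlink(probe)
  tiles_dir
}

.log <- function(config, fmt, ...) {
  if (!config$quiet) message(sprintf(fmt, ...))
}

#' Process every tile of one slide
#'
#' Iterates the tile grid of the configured series in row-major order. For
#' each tile: the region is read from the slide (memory bounded by the
#' tile), written as TIFF under its template name into `<output>/tiles/`,
#' and the processor is invoked as `processor(tile, context, store)`. The
#' tile file is deleted after the invocation unless `keep_tiles` is set. A
#' processor error on one tile is recorded and the run continues with the
#' next tile. The store is saved at the end of the slide.
#'
#' @param slide A [open_slide()] handle.
#' @param config A [run_config()]; `config$series` must exist in the slide.
#' @param processor A processor function, or `NULL` to resolve
#'   `config$processor` via [load_processor()].
#' @param store Shared [results_store()]; defaults to a store rooted at
#'   `<output>/results/`.
#' @return An object of class `run_summary` with counts
#'   `slides_processed`, `tiles_processed`, `tiles_retained` and a
#'   `failures` data frame (slide, tile, message).
#' @export
run_slide <- function(slide, config, processor = NULL, store = NULL) {
  if (!inherits(slide, "slide_pyramid"))
    st_parameter_error("'slide' must be a slide_pyramid from open_slide()")
  if (!inherits(config, "run_config"))
    st_parameter_error("'config' must come from run_config()")
  if (config$series > nrow(slide$series))
    st_series_error("series %d out of range: '%s' has %d series",
                    config$series, slide$path, nrow(slide$series))
  if (is.null(processor)) processor <- load_processor(config$processor)
  tiles_dir <- .prepare_output(config)
  if (is.null(store)) store <- results_store(file.path(config$output, "results"))

  sname <- basename(slide$path)
  grid <- compute_grid(slide$series$width_px[config$series],
                       slide$series$height_px[config$series],
                       config$tile_size, config$overlap)
  n <- nrow(grid$tiles)
  failures <- list()
  retained <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n)) {
    tl <- grid$tiles[i, ]
    px <- read_region(slide, config$series, tl$x_origin, tl$y_origin,
                      tl$width, tl$height)
    tpath <- file.path(tiles_dir,
                       tile_name(sname, config$series, tl$x_origin, tl$y_origin))
    write_image_tiff(px, tpath, compression = config$tile_compression)
    big_tile <- tl$width * tl$height >= 65536
    if (big_tile) gc(verbose = FALSE, full = TRUE)
    context <- list(
      slide_filename = sname, series = config$series,
      x_origin = tl$x_origin, y_origin = tl$y_origin,
      tile_width = tl$width, tile_height = tl$height,
      tile_path = tpath, tile_index = i, n_tiles = n,
      tile_size = config$tile_size, overlap = config$overlap)
    res <- tryCatch({ processor(px, context, store); TRUE },
                    error = function(e) e)
    if (!isTRUE(res))
      failures[[length(failures) + 1L]] <- data.frame(
        slide = sname, tile = basename(tpath),
        message = conditionMessage(res), stringsAsFactors = FALSE)
    if (config$keep_tiles) retained <- retained + 1L else unlink(tpath)
    rm(px)
    # long unsupervised loops: keep the allocator high-water mark at the
    # per-tile working set rather than accumulated garbage; collection is
    # a few ms against ~100 ms of decode+analysis for a large tile
    if (big_tile || i %% 64L == 0L) gc(verbose = FALSE, full = TRUE)
    .log(config, "[%s] tile %d/%d (%.1fs elapsed)", sname, i, n,
         proc.time()[["elapsed"]] - t0)
  }
  save_store(store)
  .run_summary(slides_processed = 1L, tiles_processed = n,
               tiles_retained = retained, failures = failures)
}

#' Process every slide in a folder
#'
#' Slide files (`*.tif`, `*.tiff`; lexicographic order for deterministic
#' results tables) are each processed by [run_slide()] against one shared
#' results store. A slide that fails to open is recorded as a failure and
#' the batch continues.
#'
#' @param config A [run_config()]; `config$input` may be a folder or a
#'   single slide file.
#' @param processor Optional processor function overriding
#'   `config$processor`.
#' @return A `run_summary` aggregated over all slides.
#' @export
run_folder <- function(config, processor = NULL) {
  if (!inherits(config, "run_config"))
    st_parameter_error("'config' must come from run_config()")
  if (is.null(processor)) processor <- load_processor(config$processor)
  .prepare_output(config)
  files <- if (dir.exists(config$input)) {
    sort(list.files(config$input, pattern = "\\.tiff?$", ignore.case = TRUE,
                    full.names = TRUE))
  } else if (file.exists(config$input)) {
    config$input
  } else {
    st_config_error("input path not found: '%s'", config$input)
  }
  store <- results_store(file.path(config$output, "results"))
  total <- .run_summary(0L, 0L, 0L, list())
  for (f in files) {
    slide <- tryCatch(open_slide(f), error = function(e) e)
    if (inherits(slide, "error")) {
      .log(config, "[%s] failed to open: %s", basename(f), conditionMessage(slide))
      total$failures <- rbind(total$failures, data.frame(
        slide = basename(f), tile = NA_character_,
        message = conditionMessage(slide), stringsAsFactors = FALSE))
      next
    }
    s <- run_slide(slide, config, processor, store)
    total$slides_processed <- total$slides_processed + s$slides_processed
    total$tiles_processed <- total$tiles_processed + s$tiles_processed
    total$tiles_retained <- total$tiles_retained + s$tiles_retained
    total$failures <- rbind(total$failures, s$failures)
  }
  save_store(store)
  total
}

.run_summary <- function(slides_processed, tiles_processed, tiles_retained,
                         failures) {
  fdf <- if (length(failures)) do.call(rbind, failures)
         else data.frame(slide = character(0), tile = character(0),
                         message = character(0), stringsAsFactors = FALSE)
  structure(list(slides_processed = slides_processed,
                 tiles_processed = tiles_processed,
                 tiles_retained = tiles_retained,
                 failures = fdf),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Run summary: %d slide(s), %d tile(s) processed, %d retained, %d failure(s)\n",
              x$slides_processed, x$tiles_processed, x$tiles_retained,
              nrow(x$failures)))
  if (nrow(x$failures)) print(x$failures, row.names = FALSE)
  invisible(x)
}
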