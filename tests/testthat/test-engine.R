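# The tile-iteration workflow: grid-order processor invocation, tile
# persistence and the keep/delete contract, failure isolation, folder
# batches, and processor loading.

local_run_setup <- function(width = 1024, height = 768, n_slides = 1,
                            n_blue = 0, n_brown = 0, ...) {
  indir <- withr::local_tempdir(.local_envir = parent.frame())
  outdir <- withr::local_tempdir(.local_envir = parent.frame())
  slides <- lapply(seq_len(n_slides), function(i)
    gen_slide(indir, sprintf("s%d.tif", i), width = width, height = height,
              n_blue = n_blue, n_brown = n_brown, seed = i, ...))
  list(indir = indir, outdir = outdir, slides = slides)
}

test_that("the processor runs once per grid tile, in row-major order, with a faithful context", {
  rs <- local_run_setup()
  log <- new.env(); log$contexts <- list(); log$dims <- list()
  cfg <- run_config(rs$indir, rs$outdir, tile_size = 512, quiet = TRUE)
  slide <- open_slide(rs$slides[[1]]$path)
  st <- results_store(file.path(rs$outdir, "results"))
  summary <- run_slide(slide, cfg, recording_processor(log), st)

  expect_equal(summary$tiles_processed, 4L)
  org <- t(vapply(log$contexts, function(cx) c(cx$x_origin, cx$y_origin),
                  c(0, 0)))
  expect_equal(org, rbind(c(0, 0), c(512, 0), c(0, 512), c(512, 512)))
  cx <- log$contexts[[2]]
  expect_equal(cx$slide_filename, "s1.tif")
  expect_equal(cx$tile_index, 2L)
  expect_equal(cx$n_tiles, 4L)
  expect_equal(log$dims[[4]], c(256L, 512L, 3L))  # clipped edge tile h x w
  # context round-trips through the name template
  p <- parse_tile_name(basename(cx$tile_path))
  expect_equal(p, list(slide_filename = "s1.tif", series = 1L,
                       x_origin = 512L, y_origin = 0L))
})

test_that("keep_tiles retains template-named files; delete leaves none", {
  rs <- local_run_setup()
  cfg <- run_config(rs$indir, rs$outdir, processor = "void", tile_size = 512,
                    keep_tiles = TRUE, quiet = TRUE)
  s <- run_folder(cfg)
  tiles_dir <- file.path(rs$outdir, "tiles")
  kept <- list.files(tiles_dir)
  expect_equal(s$tiles_retained, 4L)
  expect_setequal(kept, vapply(list(c(0, 0), c(512, 0), c(0, 512), c(512, 512)),
                               function(o) tile_name("s1.tif", 1, o[1], o[2]), ""))
  # void processor + keep is the pure export mode: files are valid slides
  t1 <- open_slide(file.path(tiles_dir, tile_name("s1.tif", 1, 0, 0)))
  expect_equal(c(t1$series$width_px, t1$series$height_px), c(512, 512))

  unlink(tiles_dir, recursive = TRUE)
  cfg2 <- run_config(rs$indir, rs$outdir, processor = "void", tile_size = 512,
                     keep_tiles = FALSE, quiet = TRUE)
  s2 <- run_folder(cfg2)
  expect_equal(s2$tiles_retained, 0L)
  expect_length(list.files(file.path(rs$outdir, "tiles")), 0)
})

test_that("a processor error on one tile is isolated; the run continues", {
  rs <- local_run_setup()
  flaky <- function(tile, context, store) {
    if (context$tile_index == 2L) stop("boom on tile 2")
    append_row(store, "ok", list(i = context$tile_index))
  }
  cfg <- run_config(rs$indir, rs$outdir, tile_size = 512, quiet = TRUE)
  s <- run_folder(cfg, flaky)
  expect_equal(s$tiles_processed, 4L)
  expect_equal(nrow(s$failures), 1L)
  expect_match(s$failures$message, "boom on tile 2")
  st <- load_store(file.path(rs$outdir, "results"))
  expect_equal(get_table(st, "ok")$i, c(1, 3, 4))
})

test_that("folder runs aggregate slides deterministically and isolate corrupt files", {
  rs <- local_run_setup(n_slides = 2, width = 512, height = 384)
  writeLines("garbage, not a slide", file.path(rs$indir, "broken.tif"))
  cfg <- run_config(rs$indir, rs$outdir, processor = "manifest",
                    tile_size = 256, quiet = TRUE)
  s <- run_folder(cfg)
  expect_equal(s$slides_processed, 2L)
  expect_equal(s$tiles_processed, 2L * 4L)
  expect_equal(nrow(s$failures), 1L)
  expect_equal(s$failures$slide, "broken.tif")
  manifest <- get_table(load_store(file.path(rs$outdir, "results")), "tiles")
  expect_equal(nrow(manifest), 8L)
  expect_equal(unique(manifest$slide), c("s1.tif", "s2.tif"))  # lexicographic

  # identical reruns produce byte-identical results tables
  csv1 <- readLines(file.path(rs$outdir, "results", "tiles.csv"))
  out2 <- withr::local_tempdir()
  run_folder(run_config(rs$indir, out2, processor = "manifest",
                        tile_size = 256, quiet = TRUE))
  csv2 <- readLines(file.path(out2, "results", "tiles.csv"))
  expect_identical(gsub(out2, rs$outdir, csv2, fixed = TRUE), csv1)
})

test_that("an empty input folder is a zero-work success", {
  indir <- withr::local_tempdir(); outdir <- withr::local_tempdir()
  s <- run_folder(run_config(indir, outdir, quiet = TRUE))
  expect_equal(s$slides_processed, 0L)
  expect_equal(s$tiles_processed, 0L)
  expect_equal(nrow(s$failures), 0L)
})

test_that("load_processor resolves built-ins, script files, and rejects the rest", {
  expect_true(is.function(load_processor("void")))
  expect_true(is.function(load_processor("hdab_tile")))
  expect_error(load_processor("no_such_processor"), class = "st_load_error")

  script <- withr::local_tempfile(fileext = ".R")
  writeLines(c(
    "process_tile <- function(tile, context, store)",
    "  append_row(store, 'custom', list(x = context$x_origin, n = sum(tile > 0)))"
  ), script)
  proc <- load_processor(script)
  st <- results_store()
  proc(array(1L, c(2, 2, 3)), list(x_origin = 7), st)
  expect_equal(get_table(st, "custom")$x, 7)

  bad <- withr::local_tempfile(fileext = ".R")
  writeLines("irrelevant <- 1", bad)
  expect_error(load_processor(bad), class = "st_load_error")
})

test_that("invalid configurations fail before any tile is read", {
  expect_error(run_config("in", "out", overlap = 512, tile_size = 512),
               class = "st_config_error")
  expect_error(run_config("in", "out", tile_size = 0),
               class = "st_config_error")
  expect_error(run_config("in", "out", series = 0),
               class = "st_config_error")
  rs <- local_run_setup(width = 128, height = 96)
  cfg <- run_config(rs$indir, rs$outdir, series = 5, tile_size = 64,
                    quiet = TRUE)
  expect_error(run_slide(open_slide(rs$slides[[1]]$path), cfg),
               class = "st_series_error")
  expect_error(run_folder(run_config("/no/such/input", rs$outdir, quiet = TRUE)),
               class = "st_config_error")
})
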