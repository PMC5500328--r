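# Color-deconvolution positivity: OD transform, stain separation against
# an independent linear-algebra oracle, classification, aggregation, and
# the maximum-positivity-tile lookup.

px_img <- function(rgb, n = 1) {
  array(rep(as.integer(rgb), each = n), dim = c(n, 1, 3))
}

test_that("optical density transform: white, gray, clamp at black", {
  expect_equal(as.numeric(rgb_to_od(px_img(c(255, 255, 255)))), c(0, 0, 0))
  expect_equal(as.numeric(rgb_to_od(px_img(c(26, 26, 26)))),
               rep(-log10(26 / 255), 3))
  expect_equal(as.numeric(rgb_to_od(px_img(c(0, 0, 0)))),
               rep(-log10(1 / 255), 3))
  expect_true(all(rgb_to_od(rand_rgb(10, 10, seed = 51)) >= 0))
  expect_error(rgb_to_od(matrix(1, 3, 3)), class = "st_parameter_error")
})

test_that("stain basis columns are unit vectors and well conditioned", {
  m <- hdab_basis()
  expect_equal(sqrt(colSums(m^2)), c(H = 1, DAB = 1, Res = 1),
               tolerance = 1e-9)
  expect_true(rcond(m) > 1e-3)
  expect_error(hdab_basis(h = c(1, 0, 0), d = c(2, 0, 0)),
               class = "st_parameter_error")
})

test_that("deconvolution matches an independent adjugate-inverse oracle", {
  m <- hdab_basis()
  # zero OD -> zero concentrations; pure basis vectors -> unit concentrations
  z <- deconvolve(array(0, c(1, 1, 3)), m)
  expect_equal(c(z$h[1], z$d[1], z$res[1]), c(0, 0, 0))
  for (k in 1:3) {
    od <- array(m[, k], c(1, 1, 3))
    conc <- deconvolve(od, m)
    expect_equal(c(conc$h[1], conc$d[1], conc$res[1]),
                 as.numeric(k == 1:3), tolerance = 1e-9)
  }
  set.seed(52)
  odv <- matrix(runif(3 * 500, 0, 2.5), nrow = 3)
  od <- array(aperm(array(odv, c(3, 500, 1)), c(2, 3, 1)), c(500, 1, 3))
  conc <- deconvolve(od, m)
  oracle <- adjugate_solve(m, odv)
  expect_lt(max(abs(rbind(conc$h[, 1], conc$d[, 1], conc$res[, 1]) - oracle)),
            1e-9)
  # reconstruction residual
  recon <- m %*% rbind(conc$h[, 1], conc$d[, 1], conc$res[, 1])
  expect_lt(max(abs(recon - odv)), 1e-6)
  expect_error(deconvolve(od, matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3)),
               class = "st_basis_error")
})

test_that("synthesis then deconvolution recovers concentrations within quantization", {
  m <- hdab_basis()
  set.seed(53)
  conc_true <- matrix(runif(3 * 200, 0, 0.8), nrow = 3)
  intens <- 255 * 10^(-m %*% conc_true)
  rgb <- round(intens)
  img <- array(aperm(array(as.integer(rgb), c(3, 200, 1)), c(2, 3, 1)),
               c(200, 1, 3))
  conc <- deconvolve(rgb_to_od(img), m)
  est <- rbind(conc$h[, 1], conc$d[, 1], conc$res[, 1])
  # rounding intensity by <= 0.5 perturbs a channel's OD by at most
  # log10(I / (I - 0.5)); the inverse basis amplifies it by at most its
  # infinity norm — the exact propagation of the 8-bit quantization
  od_err_bound <- apply(log10(pmax(intens, 1) / pmax(intens - 0.5, 0.5)), 2, max)
  amp <- max(rowSums(abs(solve(m))))
  expect_true(all(abs(est - conc_true) <=
                    rep(amp * od_err_bound, each = 3) + 1e-9))
  # the generator's pure-stain colors land within the same bound of unit
  # concentration, far clear of the classification thresholds
  for (k in c("H", "DAB")) {
    col <- stain_rgb(m[, k], 1.0)
    cc <- deconvolve(rgb_to_od(px_img(col)), m)
    errs <- abs(c(cc$h[1], cc$d[1], cc$res[1]) - as.numeric(k == c("H", "DAB", "Res")))
    bound <- amp * max(log10(pmax(col, 1) / pmax(col - 0.5, 0.5)))
    expect_true(all(errs <= bound + 1e-9))
    expect_lt(max(errs), 0.05)
  }
})

test_that("classification: background, pure stains, mixed counts, precedence", {
  m <- hdab_basis()
  white <- array(255L, c(10, 10, 3))
  conc <- deconvolve(rgb_to_od(white), m)
  masks <- classify_hdab(conc$h, conc$d)
  expect_equal(sum(masks$blue) + sum(masks$brown), 0L)
  expect_equal(positivity(sum(masks$blue), sum(masks$brown))$positivity_pct, 0)

  dab <- px_img(stain_rgb(m[, "DAB"], 1.0), n = 50)
  conc <- deconvolve(rgb_to_od(dab), m)
  masks <- classify_hdab(conc$h, conc$d)
  expect_equal(sum(masks$brown), 50L)
  expect_equal(sum(masks$blue), 0L)

  img <- array(255L, c(10, 10, 3))
  hcol <- stain_rgb(m[, "H"], 1.0); dcol <- stain_rgb(m[, "DAB"], 1.0)
  for (ch in 1:3) img[1:4, , ch] <- hcol[ch]     # 40 hematoxylin px
  for (ch in 1:3) img[5:10, , ch] <- dcol[ch]    # 60 DAB px
  conc <- deconvolve(rgb_to_od(img), m)
  masks <- classify_hdab(conc$h, conc$d)
  expect_equal(sum(masks$blue), 40L)
  expect_equal(sum(masks$brown), 60L)
  expect_false(any(masks$blue & masks$brown))    # disjoint by precedence

  # a doubly stained pixel counts as DAB-positive
  both <- round(255 * 10^(-(m[, "H"] * 0.8 + m[, "DAB"] * 0.8)))
  conc <- deconvolve(rgb_to_od(px_img(both)), m)
  masks <- classify_hdab(conc$h, conc$d)
  expect_true(masks$brown[1] && !masks$blue[1])
})

test_that("positivity arithmetic and blank convention", {
  expect_equal(positivity(0, 0)$positivity_pct, 0)
  expect_equal(positivity(0, 500)$positivity_pct, 100)
  p <- positivity(70, 30)
  expect_equal(p$positivity_pct, 100 * 30 / (70 + 30))
  expect_equal(p$positivity_pct, 30)
  expect_error(positivity(-1, 0), class = "st_parameter_error")
})

test_that("hdab_tile writes one row per tile; hdab_slide one per slide; totals agree", {
  indir <- withr::local_tempdir(); outdir <- withr::local_tempdir()
  sl <- gen_slide(indir, width = 512, height = 384, n_blue = 5, n_brown = 4,
                  radius = 22, seed = 6, internal_tile = 128)
  cfg <- run_config(indir, outdir, processor = "hdab_tile", tile_size = 256,
                    quiet = TRUE)
  run_folder(cfg)
  st <- load_store(file.path(outdir, "results"))
  tiles <- get_table(st, "tiles")
  expect_equal(nrow(tiles), 4L)
  expect_equal(sum(tiles$blue_area), sl$gt$blue_px)
  expect_equal(sum(tiles$brown_area), sl$gt$brown_px)

  out2 <- withr::local_tempdir()
  run_folder(run_config(indir, out2, processor = "hdab_slide",
                        tile_size = 256, quiet = TRUE))
  slides <- get_table(load_store(file.path(out2, "results")), "slides")
  expect_equal(nrow(slides), 1L)
  expect_equal(slides$blue_area, sl$gt$blue_px)
  expect_equal(slides$brown_area, sl$gt$brown_px)
  expect_identical(slides$positivity_pct, sl$gt$positivity_pct)
})

test_that("hdab_slide warns once when overlap is non-zero", {
  indir <- withr::local_tempdir(); outdir <- withr::local_tempdir()
  gen_slide(indir, width = 256, height = 256, n_blue = 2, n_brown = 1,
            radius = 20, seed = 3, internal_tile = 128)
  cfg <- run_config(indir, outdir, processor = "hdab_slide", tile_size = 128,
                    overlap = 32, quiet = TRUE)
  expect_warning(run_folder(cfg), "double-counts")
})

test_that("max_positivity_tile returns the winner, first on ties, and errors on no data", {
  st <- results_store()
  expect_error(max_positivity_tile(st), class = "st_no_data")
  append_row(st, "tiles", list(slide = "a.tif", series = 1, x = 0, y = 0,
                               blue_area = 10, brown_area = 10,
                               positivity_pct = 50))
  expect_equal(as.character(max_positivity_tile(st)), "a.tif__1_0_0.tif")
  append_row(st, "tiles", list(slide = "a.tif", series = 1, x = 512, y = 0,
                               blue_area = 10, brown_area = 10,
                               positivity_pct = 50))
  expect_equal(as.character(max_positivity_tile(st)), "a.tif__1_0_0.tif")
  append_row(st, "tiles", list(slide = "a.tif", series = 1, x = 0, y = 512,
                               blue_area = 1, brown_area = 99,
                               positivity_pct = 99))
  expect_equal(as.character(max_positivity_tile(st)), "a.tif__1_0_512.tif")
})

test_that("the brown-rich tile of a synthetic slide wins max positivity", {
  # discs placed deterministically: all brown mass in one quadrant
  indir <- withr::local_tempdir(); outdir <- withr::local_tempdir()
  img <- array(255L, c(512, 512, 3))
  m <- hdab_basis()
  hcol <- stain_rgb(m[, "H"]); dcol <- stain_rgb(m[, "DAB"])
  for (ch in 1:3) {
    img[50:80, 50:80, ch] <- hcol[ch]        # blue in tile (0,0)
    img[300:340, 300:360, ch] <- dcol[ch]    # brown in tile (256,256)
  }
  write_image_tiff(img, file.path(indir, "q.tif"), internal_tile = 128)
  run_folder(run_config(indir, outdir, processor = "hdab_tile",
                        tile_size = 256, keep_tiles = TRUE, quiet = TRUE))
  st <- load_store(file.path(outdir, "results"))
  best <- max_positivity_tile(st)
  expect_equal(as.character(best), "q.tif__1_256_256.tif")
  expect_true(file.exists(file.path(outdir, "tiles", best)))
})

test_that("tiled aggregation equals whole-image classification for every tile size", {
  indir <- withr::local_tempdir()
  sl <- gen_slide(indir, width = 500, height = 380, n_blue = 6, n_brown = 3,
                  radius = 24, seed = 8, internal_tile = 128)
  s <- open_slide(sl$path)
  m <- hdab_basis()
  conc <- deconvolve(rgb_to_od(read_region(s, 1, 0, 0, 500, 380)), m)
  masks <- classify_hdab(conc$h, conc$d)
  whole <- c(sum(masks$blue), sum(masks$brown))
  for (T in c(100, 128, 256)) {   # non-divisor sizes included
    outdir <- withr::local_tempdir()
    run_folder(run_config(indir, outdir, processor = "hdab_slide",
                          tile_size = T, quiet = TRUE))
    row <- get_table(load_store(file.path(outdir, "results")), "slides")
    expect_identical(c(row$blue_area, row$brown_area), as.numeric(whole))
  }
})
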