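test_that("PNG/TIFF round-trips preserve integer pixel values and defaults", {
  px16 <- matrix(sample(0:65535, 32 * 32, replace = TRUE), 32, 32)
  px8 <- px16 %% 256
  f <- tempfile(fileext = ".tif")
  writeImage(Image2D(px16), f)
  back <- loadImage(f)
  expect_s4_class(back, "Image2D")
  expect_identical(dim(back), c(32L, 32L))
  expect_equal(spacing(back), c(1, 1))
  expect_equal(pixels(back), px16, ignore_attr = TRUE)
  f <- tempfile(fileext = ".png")
  writeImage(Image2D(px8), f)
  expect_equal(pixels(loadImage(f)), px8, ignore_attr = TRUE)
  expect_error(writeImage(Image2D(px16), tempfile(fileext = ".png")),
               "0..255")
  f <- tempfile(fileext = ".csv")
  writeImage(Image2D(px16), f)
  expect_equal(pixels(loadImage(f)), px16, ignore_attr = TRUE)
})

test_that("DICOM slices load with metadata spacing; bad inputs error", {
  px <- matrix(sample(0:4000, 16 * 12, replace = TRUE), 16, 12)
  f <- tempfile(fileext = ".dcm")
  writeBin(make_dicom_bytes(px, spacing = c(1.17, 1.17)), f)
  img <- loadImage(f)
  expect_equal(spacing(img), c(1.17, 1.17))
  expect_equal(dim(img), c(16L, 12L))
  expect_equal(pixels(img), px, ignore_attr = TRUE)
  expect_error(loadImage(tempfile(fileext = ".png")), "not found")
  # color PNG rejected
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fc <- tempfile(fileext = ".png")
  png::writePNG(arr, fc)
  expect_error(loadImage(fc), "color")
})

test_that("resampleToGrid preserves field of view and is idempotent", {
  img <- makePhantom(phantomSpec(shape = c(96, 96), seed = 2))
  img@spacing <- c(1.27, 1.27)
  # identity resample
  same <- resampleToGrid(img, c(1.27, 1.27), c(96, 96))
  expect_identical(pixels(same), pixels(img))
  # 2x nearest upsampling of a checkerboard duplicates blocks
  chk <- Image2D(rbind(c(0, 10), c(10, 0)) %x% matrix(1, 4, 4))
  up <- resampleToGrid(chk, c(0.5, 0.5), c(16, 16), "nearest")
  expect_identical(dim(up), c(16L, 16L))
  expect_equal(pixels(up), pixels(chk)[rep(1:8, each = 2), rep(1:8, each = 2)],
               ignore_attr = TRUE)
  # CBCT -> CT grid magnifies content by the spacing ratio: a disk of
  # radius r px at 1.27 mm must measure ~ r * 1.27/1.17 px at 1.17 mm
  rr <- matrix(seq_len(96) - 48.5, 96, 96)
  cc <- t(rr)
  disk <- Image2D(1000 * (rr^2 + cc^2 <= 30^2), spacing = c(1.27, 1.27))
  up <- resampleToGrid(disk, c(1.17, 1.17), c(128, 128))
  area_in <- sum(pixels(disk) > 500)
  area_out <- sum(pixels(up) > 500)
  expect_equal(area_out / area_in, (1.27 / 1.17)^2, tolerance = 0.02)
  expect_error(resampleToGrid(disk, c(0, 1)), "positive")
})

test_that("phantom generation is seeded, piecewise constant, noise-calibrated", {
  s <- phantomSpec(shape = c(64, 64), n_regions = 4, seed = 9)
  expect_identical(pixels(makePhantom(s)), pixels(makePhantom(s)))
  # without blur, n_regions = 2 gives exactly two gray values
  s2 <- phantomSpec(shape = c(64, 64), n_regions = 2, blur_sigma = 0, seed = 3)
  expect_identical(length(unique(as.numeric(pixels(makePhantom(s2))))), 2L)
  # additive-noise calibration on a large frame
  clean <- makePhantom(phantomSpec(shape = c(512, 512), seed = 5))
  noisy <- makePhantom(phantomSpec(shape = c(512, 512), seed = 5,
                                   noise_sigma = 5))
  expect_equal(sd(pixels(noisy) - pixels(clean)), 5, tolerance = 0.2)
  # contrast offset is a pure shift
  off <- makePhantom(phantomSpec(shape = c(64, 64), seed = 9, n_regions = 4,
                                 contrast_offset = 40))
  expect_equal(pixels(off),
               pixels(makePhantom(phantomSpec(shape = c(64, 64), seed = 9,
                                              n_regions = 4))) + 40)
})

test_that("CBCT-like derivation lands on the coarser grid with noise", {
  ct <- makePhantom(phantomSpec(shape = c(128, 128), spacing = c(1.17, 1.17),
                                seed = 4))
  cb <- makeCbctLike(ct, noise_sigma = 10, contrast_offset = 25, seed = 2)
  expect_equal(spacing(cb), c(1.27, 1.27))
  expect_identical(dim(cb), c(118L, 118L))
  cb2 <- makeCbctLike(ct, noise_sigma = 10, contrast_offset = 25, seed = 2)
  expect_identical(pixels(cb), pixels(cb2))
})
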