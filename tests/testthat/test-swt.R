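test_that("constant images have zero detail and the expected low-pass gain", {
  for (b in c("periodic", "symmetric")) {
    pyr <- swtDecompose(matrix(3, 32, 32), levels = 2, filters = "db2",
                        boundary = b)
    for (j in 1:2) for (o in c("LH", "HL", "HH"))
      expect_lt(max(abs(detailBand(pyr, j, o))), 1e-12)
    # separable low-pass gain is sum(h0)^2 = 2 per level
    expect_equal(approxBand(pyr, 2), matrix(3 * 4, 32, 32),
                 tolerance = 1e-12)
  }
})

test_that("reconstruction inverts decomposition for all families and depths", {
  x <- rand_image(64, seed = 7)
  for (w in c("haar", "db2", "db4", "db8")) for (b in c("periodic", "symmetric"))
    for (J in 1:4) {
      L <- length(waveletFilters(w)@h0)
      if ((L - 1) * 2^(J - 1) + 1 > 64) next  # deeper than the image allows
      pyr <- swtDecompose(x, J, w, b)
      rec <- pixels(swtReconstruct(pyr))
      expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8,
                label = sprintf("PR error (%s, %s, J=%d)", w, b, J))
    }
})

test_that("decomposition commutes with circular shifts under periodic boundary", {
  set.seed(21)
  for (case in 1:5) {
    x <- rand_image(48, seed = 100 + case)
    s <- sample(1:20, 1)
    p0 <- swtDecompose(x, 3, "db2", "periodic")
    p1 <- swtDecompose(circ_shift(x, s), 3, "db2", "periodic")
    for (j in 1:3) {
      expect_lt(max(abs(approxBand(p1, j) - circ_shift(approxBand(p0, j), s))),
                1e-9)
      expect_lt(max(abs(detailBand(p1, j, "HH") -
                        circ_shift(detailBand(p0, j, "HH"), s))), 1e-9)
    }
  }
})

test_that("the inverse transform is linear in the coefficients", {
  a <- swtDecompose(rand_image(32, seed = 1), 2, "db3", "symmetric")
  b <- swtDecompose(rand_image(32, seed = 2), 2, "db3", "symmetric")
  lhs <- pixels(swtReconstruct(a)) + pixels(swtReconstruct(b))
  rhs <- pixels(swtReconstruct(a + b))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  # all-zero pyramid reconstructs to zero
  expect_lt(max(abs(pixels(swtReconstruct(a - a)))), 1e-12)
})

test_that("gradient image = input minus approximation-only reconstruction", {
  x <- rand_image(64, seed = 12)
  for (b in c("periodic", "symmetric")) {
    g <- pixels(synthesizeGradientImage(x, 3, "db2", b))
    pz <- swtDecompose(x, 3, "db2", b)
    # zero the details instead: reconstruct approximation content only
    pz@detailLH <- lapply(pz@detailLH, function(m) m * 0)
    pz@detailHL <- lapply(pz@detailHL, function(m) m * 0)
    pz@detailHH <- lapply(pz@detailHH, function(m) m * 0)
    approx_only <- pixels(swtReconstruct(pz))
    expect_lt(max(abs(g - (x - approx_only))), 1e-8)
  }
})

test_that("gradient image kills constants and localizes step edges", {
  expect_lt(max(abs(pixels(synthesizeGradientImage(matrix(7, 32, 32), 2)))),
            1e-12)
  # adding a constant leaves the gradient image unchanged
  x <- rand_image(32, seed = 3)
  g1 <- pixels(synthesizeGradientImage(x, 2, "db2"))
  g2 <- pixels(synthesizeGradientImage(x + 123.4, 2, "db2"))
  expect_lt(max(abs(g1 - g2)), 1e-8)
  # vertical step edge between columns 32|33: strongest response at the edge
  step <- matrix(0, 64, 64); step[, 33:64] <- 100
  g <- abs(pixels(synthesizeGradientImage(step, 3, "haar", "symmetric")))
  col_peak <- which.max(apply(g, 2, max))
  halfsup <- (2^3 - 1)  # haar support at the deepest level
  expect_lte(abs(col_peak - 32.5), halfsup)
})

test_that("invalid inputs are rejected", {
  expect_error(swtDecompose(rand_image(8), levels = 4, filters = "db4"),
               "too small")
  expect_error(waveletFilters("sym5"), "unknown wavelet")
  expect_error(swtDecompose(rand_image(16), levels = 0), "levels")
})

test_that("pyramids round-trip through the on-disk container", {
  pyr <- swtDecompose(rand_image(16, seed = 5), 2, "db2", "symmetric")
  d <- tempfile()
  writePyramid(pyr, d)
  back <- readPyramid(d)
  expect_equal(back@approx, pyr@approx, tolerance = 1e-12)
  expect_lt(max(abs(pixels(swtReconstruct(back)) -
                    pixels(swtReconstruct(pyr)))), 1e-10)
  unlink(d, recursive = TRUE)
})
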