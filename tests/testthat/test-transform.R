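test_that("identity and lattice-preserving transforms are exact", {
  img <- makePhantom(phantomSpec(shape = c(64, 64), seed = 1))
  expect_identical(pixels(applyRigid(img, rigidTransform(0, 0, 0), "nearest")),
                   pixels(img))
  expect_lt(max(abs(pixels(applyRigid(img, rigidTransform(0, 0, 0))) -
                    pixels(img))), 1e-12)
  # integer translation with nearest interpolation is an exact pixel shift
  sh <- pixels(applyRigid(img, rigidTransform(3, -2, 0), "nearest"))
  expect_equal(sh[10:50, 10:50], pixels(img)[(10:50) + 2, (10:50) - 3],
               ignore_attr = TRUE)
  # full turn
  expect_lt(max(abs(pixels(applyRigid(img, rigidTransform(0, 0, 360))) -
                    pixels(img))), 1e-6)
})

test_that("inversion matches the homogeneous-matrix oracle", {
  expect_equal(transformParams(invertTransform(rigidTransform(10, 15, 0))),
               c(dx = -10, dy = -15, theta = 0))
  expect_equal(transformParams(invertTransform(rigidTransform(0, 0, 30))),
               c(dx = 0, dy = 0, theta = -30))
  t <- rigidTransform(5, -3, 20)
  ti <- invertTransform(t)
  # oracle: invert the 3x3 homogeneous forward matrix directly
  th <- 20 * pi / 180
  A <- rbind(cbind(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                   c(5, -3)), c(0, 0, 1))
  Ainv <- solve(A)
  thi <- atan2(Ainv[2, 1], Ainv[1, 1]) * 180 / pi
  expect_equal(ti@theta, thi, tolerance = 1e-10)
  expect_equal(c(ti@dx, ti@dy), Ainv[1:2, 3], tolerance = 1e-10,
               ignore_attr = TRUE)
  # composing with the inverse yields identity parameters
  id <- composeTransforms(ti, t, center = c(31.5, 31.5))
  expect_equal(transformParams(id), c(dx = 0, dy = 0, theta = 0),
               tolerance = 1e-10)
})

test_that("composition satisfies the group law (matrix oracle)", {
  set.seed(14)
  for (i in 1:10) {
    t1 <- rigidTransform(runif(1, -10, 10), runif(1, -10, 10),
                         runif(1, -40, 40))
    t2 <- rigidTransform(runif(1, -10, 10), runif(1, -10, 10),
                         runif(1, -40, 40))
    cen <- c(runif(1, 0, 60), runif(1, 0, 60))
    t21 <- composeTransforms(t2, t1, center = cen)
    mat <- function(t) {
      th <- t@theta * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      cv <- c(cen[2], cen[1])
      rbind(cbind(R, cv + c(t@dx, t@dy) - R %*% cv), c(0, 0, 1))
    }
    expect_equal(mat(t21), mat(t2) %*% mat(t1), tolerance = 1e-10)
  }
})

test_that("round-trip warping returns close to the original away from borders", {
  img <- makePhantom(phantomSpec(shape = c(96, 96), seed = 6))
  t <- rigidTransform(6, -4, 12)
  back <- applyRigid(applyRigid(img, t), invertTransform(t))
  inner <- 25:72
  err <- abs(pixels(back)[inner, inner] - pixels(img)[inner, inner])
  # residual comes from double bilinear smoothing at region boundaries:
  # small relative to the ~1000-gray dynamic range
  expect_lt(mean(err), 0.01 * diff(range(pixels(img))))
  # and registration-style MSE drops relative to the misaligned state
  expect_lt(mseError(img, back), mseError(img, applyRigid(img, t)))
})

test_that("mm translations are converted through the pixel spacing", {
  img <- makePhantom(phantomSpec(shape = c(64, 64), spacing = c(2, 2),
                                 seed = 1))
  a <- pixels(applyRigid(img, rigidTransform(4, -2, 0, units = "mm")))
  b <- pixels(applyRigid(img, rigidTransform(2, -1, 0, units = "px")))
  expect_equal(a, b)
})

test_that("bilinear warping is continuous in the parameters", {
  img <- makePhantom(phantomSpec(shape = c(64, 64), seed = 8))
  base <- pixels(applyRigid(img, rigidTransform(2.3, -1.7, 5)))
  for (d in list(c(1e-3, 0, 0), c(0, 1e-3, 0), c(0, 0, 1e-3))) {
    pert <- pixels(applyRigid(img, rigidTransform(2.3 + d[1], -1.7 + d[2],
                                                  5 + d[3])))
    expect_lt(mean(abs(pert - base)), 0.5)
  }
})

test_that("transforms serialize to JSON and back", {
  t <- rigidTransform(10.25, -3.5, 2.75)
  f <- tempfile(fileext = ".json")
  writeTransform(t, f)
  back <- readTransform(f)
  expect_equal(transformParams(back), transformParams(t))
  expect_identical(back@units, "px")
})
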