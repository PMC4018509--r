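test_that("entropy matches closed forms and rejects invalid input", {
  expect_equal(entropyBits(c(0.5, 0.5)), 1)
  expect_equal(entropyBits(c(1, 0)), 0)
  expect_equal(entropyBits(rep(0.25, 4)), 2)
  expect_error(entropyBits(c(-0.1, 1.1)), "nonnegative")
})

test_that("joint entropy, MI and NMI agree with direct evaluation", {
  # construct a histogram model directly from a known joint table
  j <- rbind(c(0.4, 0.1), c(0.1, 0.4))
  h <- list(joint = j, marginal_a = rowSums(j), marginal_b = colSums(j))
  H <- -sum(j * log2(j))
  expect_equal(jointEntropy(h), H, tolerance = 1e-12)
  expect_equal(jointEntropy(h), 1.7219, tolerance = 1e-4)
  expect_equal(mutualInformation(h), 2 - H, tolerance = 1e-12)
  expect_equal(normalizedMI(h), 2 / H, tolerance = 1e-12)
  # independence: joint = outer product of marginals
  pa <- c(0.3, 0.7); pb <- c(0.6, 0.4)
  hi <- list(joint = outer(pa, pb), marginal_a = pa, marginal_b = pb)
  expect_equal(jointEntropy(hi), entropyBits(pa) + entropyBits(pb))
  expect_equal(mutualInformation(hi), 0, tolerance = 1e-12)
  expect_equal(normalizedMI(hi), 1, tolerance = 1e-12)
})

test_that("joint histogram matches construction and a hand tally", {
  cfg <- measureConfig(bins = 2)
  a <- matrix(c(0, 0, 1, 1), 2, 2)
  h <- jointHistogram(a, a, cfg)
  expect_equal(h$joint, rbind(c(0.5, 0), c(0, 0.5)), ignore_attr = TRUE)
  h2 <- jointHistogram(a, 1 - a, cfg)
  expect_equal(h2$joint, rbind(c(0, 0.5), c(0.5, 0)), ignore_attr = TRUE)
  # 4x4 toy pair against the brute-force per-pixel tally
  set.seed(8)
  x <- matrix(sample(0:9, 16, TRUE), 4, 4)
  y <- matrix(sample(0:9, 16, TRUE), 4, 4)
  h3 <- jointHistogram(x, y, measureConfig(bins = 4))
  expect_equal(h3$joint, bf_joint(x, y, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(jointHistogram(x, matrix(NA_real_, 4, 4), cfg,
                              range_flt = c(0, 1)),
               "degenerate overlap")
})

test_that("measure invariants hold over random pairs against the oracle", {
  set.seed(31)
  for (case in 1:40) {
    B <- sample(2:8, 1)
    x <- matrix(runif(64, 0, 10), 8, 8)
    y <- if (case %% 4 == 0) x else matrix(runif(64, 0, 10), 8, 8)
    h <- jointHistogram(x, y, measureConfig(bins = B))
    mi <- mutualInformation(h)
    nmi <- normalizedMI(h)
    # agreement with brute-force tally
    expect_equal(h$joint, bf_joint(x, y, B), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(nmi, bf_nmi(x, y, B), tolerance = 1e-10)
    # symmetry under swapping the images
    hs <- jointHistogram(y, x, measureConfig(bins = B))
    expect_equal(mutualInformation(hs), mi, tolerance = 1e-10)
    # ranges
    expect_gte(mi, -1e-12)
    expect_gte(nmi, 1 - 1e-12)
    expect_lte(nmi, 2 + 1e-12)
    # joint entropy bounds
    ha <- entropyBits(h$marginal_a); hb <- entropyBits(h$marginal_b)
    hab <- jointEntropy(h)
    expect_gte(hab + 1e-12, max(ha, hb))
    expect_lte(hab, ha + hb + 1e-12)
  }
  # identical non-constant images: functional dependence
  x <- matrix(runif(64, 0, 10), 8, 8)
  h <- jointHistogram(x, x, measureConfig(bins = 8))
  expect_equal(jointEntropy(h), entropyBits(h$marginal_a), tolerance = 1e-12)
  expect_equal(normalizedMI(h), 2, tolerance = 1e-12)
})

test_that("logistic weight has midpoint, monotonicity and symmetry", {
  expect_equal(logisticWeight(0.5), 0.5)
  expect_equal(logisticWeight(0.75, T = 0.04), 1 / (1 + exp(-6.25)),
               tolerance = 1e-12)
  v <- seq(0, 1, length.out = 101)
  f <- logisticWeight(v, 0.04)
  expect_true(all(diff(f) > 0))
  expect_equal(f + rev(f), rep(1, 101), tolerance = 1e-12)
  expect_error(logisticWeight(0.5, T = 0), "T must be > 0")
})

test_that("the combined measure is a convex combination of its inputs", {
  cfg <- measureConfig()
  expect_equal(combinedMeasure(1.7, 1.7, cfg), 1.7)
  set.seed(5)
  for (i in 1:50) {
    ni <- runif(1, 1, 2); ng <- runif(1, 1, 2)
    cm <- combinedMeasure(ni, ng, cfg)
    expect_gte(cm, min(ni, ng) - 1e-12)
    expect_lte(cm, max(ni, ng) + 1e-12)
  }
  # rescaled v at the logistic midpoint averages the two inputs:
  # (x + y)/2 = 0.5 on the NMI-1 scale
  expect_equal(combinedMeasure(1.2, 1.8, cfg), (1.2 + 1.8) / 2)
  # paper-literal mode saturates toward the intensity term
  cfg_raw <- measureConfig(nmi_rescale = FALSE)
  expect_equal(combinedMeasure(1.9, 1.1, cfg_raw), 1.9, tolerance = 1e-6)
})
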