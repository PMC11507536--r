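test_that("exhaustive canonical systems hit their exact O-information", {
  for (K in 2:8) {
    expect_equal(oinfoNaive(BinnedMatrix(copyMatrix(K), rep(K, 3))),
                 log2(K), tolerance = 1e-12)
    expect_equal(oinfoNaive(BinnedMatrix(modMatrix(K), rep(K, 3))),
                 -log2(K), tolerance = 1e-12)
    expect_equal(oinfoNaive(BinnedMatrix(productMatrix(K), rep(K, 3))),
                 0, tolerance = 1e-12)
  }
  # the XOR gate is the K = 2 synergistic system
  expect_equal(oinfoNaive(BinnedMatrix(modMatrix(2), rep(2L, 3))), -1,
               tolerance = 1e-12)
})

test_that("naive O-information matches the brute-force joint-table oracle", {
  set.seed(31)
  for (rep in 1:15) {
    card <- sample(2:5, 3, replace = TRUE)
    m <- randomBinned(sample(4:64, 1), 3, card, seed = 1000 + rep)
    expect_equal(oinfoNaive(m), oracleOinfo(binLabels(m), card),
                 tolerance = 1e-12)
  }
  # n = 4 as well: the estimator is not restricted to triplets
  m4 <- randomBinned(40, 4, c(2, 3, 2, 3), seed = 99)
  expect_equal(oinfoNaive(m4), oracleOinfo(binLabels(m4), c(2, 3, 2, 3)),
               tolerance = 1e-12)
})

test_that("O-information is symmetric under variable reordering", {
  set.seed(32)
  for (rep in 1:8) {
    m <- randomBinned(30, 3, sample(2:4, 3, replace = TRUE),
                      seed = 2000 + rep)
    base <- oinfoNaive(m)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      mp <- BinnedMatrix(binLabels(m)[, perm],
                         cardinalities(m)[perm])
      expect_equal(oinfoNaive(mp), base, tolerance = 1e-12)
    }
  }
})

test_that("estimates respect the theoretical bounds", {
  b <- theoreticalBounds(3, 50)
  expect_equal(unname(b["lower"]), -log2(50), tolerance = 1e-12)
  expect_equal(round(unname(b["lower"]), 2), -5.64)
  expect_equal(unname(b["lower"]), -unname(b["upper"]))
  expect_identical(unname(theoreticalBounds(3, 2)), c(-1, 1))
  expect_equal(unname(theoreticalBounds(4, 10)),
               c(-2 * log2(10), 2 * log2(10)), tolerance = 1e-12)
  expect_error(theoreticalBounds(2, 10), "n must be")
  set.seed(33)
  for (rep in 1:10) {
    card <- sample(2:6, 3, replace = TRUE)
    m <- randomBinned(25, 3, card, seed = 3000 + rep)
    om <- oinfoNaive(m)
    expect_gte(om, -log2(max(card)) - 1e-9)
    expect_lte(om, log2(max(card)) + 1e-9)
  }
})

test_that("deltaMM evaluates the closed forms of the canonical systems", {
  for (K in c(2, 5, 10, 30)) {
    for (N in c(100, 1000)) {
      # independent, full support: (K-1)^3 / (2 N ln 2)
      expect_equal(deltaMM(rep(K, 3), rep(K^2, 3), K^3, N),
                   (K - 1)^3 / (2 * N * log(2)), tolerance = 1e-12)
      # synergistic, full support: concave parabola (-2K^2+3K-1)/(2N ln 2)
      expect_equal(deltaMM(rep(K, 3), rep(K^2, 3), K^2, N),
                   (-2 * K^2 + 3 * K - 1) / (2 * N * log(2)),
                   tolerance = 1e-12)
      # redundant: (K-1)/(2 N ln 2)
      expect_equal(deltaMM(rep(K, 3), rep(K, 3), K, N),
                   (K - 1) / (2 * N * log(2)), tolerance = 1e-12)
    }
  }
  expect_equal(deltaMM(rep(10, 3), rep(100, 3), 1000, 1000),
               729 / (2000 * log(2)), tolerance = 1e-12)
  # a constant system carries no bias
  expect_equal(deltaMM(rep(1, 3), rep(1, 3), 1, 50), 0)
  expect_error(deltaMM(rep(2, 3), rep(4, 2), 8, 10), "length")
  expect_error(deltaMM(rep(2, 3), rep(4, 3), 8, 0), "N must be")
})

test_that("corrected estimate is naive plus deltaMM, per support mode", {
  set.seed(34)
  x <- simulateTriplet("independent", N = 500, K = 5, seed = 11)
  for (mode in c("observed", "theoretical")) {
    r <- oinfoCorrected(x, supportMode = mode)
    expect_equal(omegaCorrected(r), omegaNaive(r) + biasTerm(r),
                 tolerance = 1e-15)
    expect_equal(omegaNaive(r), oinfoNaive(x), tolerance = 1e-12)
  }
  rObs <- oinfoCorrected(x, "observed")
  expect_lte(rObs@supportN, min(500L, 125L))
  rTheo <- oinfoCorrected(x, "theoretical")
  expect_identical(rTheo@supportN, 125L)
  expect_identical(rTheo@supportsMinusJ, rep(25L, 3))
  rKnown <- oinfoCorrected(x, "known",
                           list(supportN = 125, supportsMinusJ = rep(25, 3)))
  expect_equal(omegaCorrected(rKnown), omegaCorrected(rTheo),
               tolerance = 1e-12)
  expect_error(oinfoCorrected(x, "known"), "knownSupports")
  expect_error(oinfoNaive(BinnedMatrix(cbind(0:1, 0:1), rep(2L, 2))),
               "at least 3")
})

test_that("the correction vanishes as N grows on a fixed system", {
  # exhaustive copy matrix: observed supports are all K, so
  # deltaMM = (K-1)/(2 N ln 2) > 0 and the corrected value overshoots
  K <- 6
  r <- oinfoCorrected(BinnedMatrix(copyMatrix(K), rep(K, 3)), "observed")
  expect_equal(biasTerm(r), (K - 1) / (2 * K * log(2)), tolerance = 1e-12)
  expect_gt(omegaCorrected(r), log2(K))
  # many copies of the exhaustive rows: same naive value, shrinking term
  big <- BinnedMatrix(copyMatrix(K)[rep(1:K, 200), ], rep(K, 3))
  rBig <- oinfoCorrected(big, "observed")
  expect_equal(omegaNaive(rBig), log2(K), tolerance = 1e-12)
  expect_lt(biasTerm(rBig), biasTerm(r) / 100)
})

test_that("independent-triplet estimates tighten towards zero with N", {
  K <- 3
  means <- vapply(c(27, 54, 108) * 4, function(N) {
    mean(vapply(1:30, function(t) {
      oinfoNaive(simulateTriplet("independent", N, K,
                                 seed = 40000 + 100 * N + t))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(abs(means)) < 0))
})
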