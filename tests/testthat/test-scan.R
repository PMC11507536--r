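writeScanFixture <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

test_that("missing values are imputed with the column median", {
  p <- writeScanFixture(c("a,b,c,d",
                          "1,1,5,1",
                          ",2,6,2",
                          "3,NA,7,100",
                          "4,100,NaN,4"))
  tab <- loadAndImpute(p)
  expect_identical(tab$a, c(1, 3, 3, 4))        # median of {1,3,4}
  expect_identical(tab$b, c(1, 2, 2, 100))      # lower-median rule: 2
  expect_identical(tab$c, c(5, 6, 7, 6))        # even case: mean(5,7)
  expect_identical(tab$d, c(1, 2, 100, 4))      # untouched
})

test_that("tables load from tsv and non-numeric columns are dropped", {
  p <- writeScanFixture(c("id\tx\ty\tz",
                          "s1\t1\t4\t7",
                          "s2\t2\t5\t8",
                          "s3\t3\t6\t9"), ext = "tsv")
  expect_warning(tab <- loadAndImpute(p), "non-numeric")
  expect_identical(names(tab), c("x", "y", "z"))
  expect_identical(tab$x, c(1, 2, 3))
})

test_that("unusable tables are rejected", {
  tooFew <- writeScanFixture(c("a,b", "1,2", "3,4"))
  expect_error(loadAndImpute(tooFew), "fewer than 3")
  allMissing <- writeScanFixture(c("a,b,c", "1,2,NA", "3,4,NA"))
  expect_error(loadAndImpute(allMissing), "no observed values")
  expect_error(loadAndImpute(tempfile()), "not found")
})

test_that("scans enumerate every triplet with deterministic ranks", {
  set.seed(51)
  tab3 <- as.data.frame(matrix(runif(50 * 3), 50))
  expect_identical(nrow(scanTriplets(tab3, K = 5)), 1L)
  tab10 <- as.data.frame(matrix(runif(60 * 10), 60))
  sc <- scanTriplets(tab10, K = 4)
  expect_identical(nrow(sc), 120L)   # C(10, 3)
  expect_identical(sort(sc$rank_naive), 1:120)
  expect_identical(sort(sc$rank_corrected), 1:120)
  expect_identical(sc$rank_naive, 1:120)   # records ordered by naive rank
  # bit-identical on re-run
  expect_identical(sc, scanTriplets(tab10, K = 4))
})

test_that("scan estimates equal the single-system estimator per triplet", {
  set.seed(52)
  tab <- as.data.frame(matrix(runif(80 * 4), 80))
  K <- 4
  sc <- scanTriplets(tab, K = K)
  bm <- binMatrix(tab, K)
  for (i in seq_len(nrow(sc))) {
    cols <- match(c(sc$var1[i], sc$var2[i], sc$var3[i]), colnames(tab))
    sub <- BinnedMatrix(binLabels(bm)[, cols], cardinalities(bm)[cols])
    r <- oinfoCorrected(sub, "observed")
    expect_equal(sc$omega_naive[i], omegaNaive(r), tolerance = 1e-12)
    expect_equal(sc$omega_corrected[i], omegaCorrected(r),
                 tolerance = 1e-12)
  }
})

test_that("a planted synergistic triple ranks most synergistic", {
  K <- 5
  planted <- simulateTriplet("synergistic", N = 400, K = K, seed = 9)
  set.seed(53)
  noise <- matrix(runif(400 * 4), 400)
  tab <- cbind(as.data.frame(binLabels(planted)),
               as.data.frame(noise))
  names(tab) <- c("s1", "s2", "s3", "n1", "n2", "n3", "n4")
  sc <- scanTriplets(tab, K = K)
  top <- sc[sc$rank_naive == 1, ]
  expect_identical(c(top$var1, top$var2, top$var3), c("s1", "s2", "s3"))
  # the correction preserves the strongest triple
  expect_identical(rankOverlap(sc, sc, topM = 1), 1L)
})

test_that("rank overlap behaves as a set intersection", {
  rec <- data.frame(var1 = letters[1:4], var2 = letters[5:8],
                    var3 = letters[9:12],
                    rank_naive = 1:4, rank_corrected = 4:1)
  # identical rankings: overlap is topM
  expect_identical(rankOverlap(rec, rec, 3, rankAfter = "naive"), 3L)
  # fully reversed rankings: top-2 sets are disjoint
  expect_identical(rankOverlap(rec, rec, 2), 0L)
  # but top-3 of 4 must share at least 2
  expect_identical(rankOverlap(rec, rec, 3), 2L)
  other <- rec
  other$var1 <- LETTERS[1:4]
  expect_error(rankOverlap(rec, other, 2), "same triplets")
})

test_that("independent tables scan near the matched null benchmark", {
  N <- 300; K <- 4
  set.seed(54)
  tab <- as.data.frame(matrix(runif(N * 6), N))
  sc <- scanTriplets(tab, K = K)
  nb <- nullBenchmark(N = N, K = K, trials = 30, seed = 55)
  se <- sd(nb$naiveSamples) / sqrt(nb$trials)
  expect_lt(abs(mean(sc$omega_naive) - nb$meanNaive), 4 * se)
  expect_identical(length(nb$naiveSamples), nb$trials)
  expect_identical(length(nb$correctedSamples), nb$trials)
  expect_equal(nb$meanNaive, mean(nb$naiveSamples), tolerance = 1e-15)
})

test_that("a benchmark far above K^3 has no appreciable bias", {
  nb <- nullBenchmark(N = 100000, K = 4, trials = 10, seed = 56)
  se <- sd(nb$naiveSamples) / sqrt(nb$trials)
  expect_lt(abs(nb$meanNaive), 3 * se + 1e-3)
  expect_lt(abs(nb$meanCorrected), 3 * se + 1e-3)
})
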