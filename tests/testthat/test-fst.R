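test_that("wcTheta honours its closed-form anchors", {
  expect_equal(wcTheta(50, 100, 50, 0), 1)     # fixed difference
  expect_equal(wcTheta(10, 20, 30, 0), 1)      # fixed difference, unequal n
  # identical sample frequencies: between-population component <= 0
  expect_lte(wcTheta(10, 10, 10, 10), 0)
  expect_lte(wcTheta(25, 20, 50, 40), 0)
  # pooled monomorphic is undefined
  expect_true(is.na(wcTheta(10, 0, 10, 0)))
  expect_true(is.na(wcTheta(10, 20, 10, 20)))
})

test_that("wcTheta equals the independent variance-components oracle", {
  expect_equal(wcTheta(10, 15, 10, 5), wcThetaOracle(10, 15, 10, 5),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:200) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    x1 <- sample(0:(2 * n1), 1); x2 <- sample(0:(2 * n2), 1)
    got <- wcTheta(n1, x1, n2, x2)
    want <- wcThetaOracle(n1, x1, n2, x2)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("wcTheta is invariant to population labels and allele coding", {
  set.seed(11)
  n1 <- 13; n2 <- 37; x1 <- 9; x2 <- 41
  expect_equal(wcTheta(n1, x1, n2, x2), wcTheta(n2, x2, n1, x1))
  expect_equal(wcTheta(n1, x1, n2, x2),
               wcTheta(n1, 2 * n1 - x1, n2, 2 * n2 - x2))
})

test_that("expected heterozygosity uses the unweighted mean frequency", {
  expect_equal(expectedHet(0.5, 0.5), 0.5)
  expect_equal(expectedHet(0, 0), 0)
  expect_equal(expectedHet(0.2, 0.6), 0.48)
  expect_true(is.na(expectedHet(NA, 0.3)))
})

test_that("window grid is anchored at 0 with 25 kb steps", {
  map <- SnpMap(c("a", "b"), c(1L, 1L), c(10000L, 110000L))
  w <- windowAverage(c(1, 3), map, fstScanConfig(minSnps = 1L))
  expect_true(all(w$start %% 25000 == 0))
  expect_true(all(w$end - w$start == 100000))
  # SNP at 10 kb: window starting at 0 only; SNP at 110 kb: windows
  # starting 25 kb through 100 kb
  w0 <- w[w$start == 0, ]
  expect_identical(w0$n_snps, 1L); expect_equal(w0$mean_value, 1)
  w25 <- w[w$start == 25000, ]
  expect_identical(w25$n_snps, 1L); expect_equal(w25$mean_value, 3)
  w100 <- w[w$start == 100000, ]
  expect_identical(w100$n_snps, 1L); expect_equal(w100$mean_value, 3)
  # a window covering both SNPs requires both inside [start, end)
  mapB <- SnpMap(c("a", "b"), c(1L, 1L), c(30000L, 110000L))
  wB <- windowAverage(c(1, 3), mapB, fstScanConfig(minSnps = 1L))
  expect_identical(wB$n_snps[wB$start == 25000], 2L)
  expect_equal(wB$mean_value[wB$start == 25000], 2)
  # grid extends only to the last SNP
  expect_lte(max(w$start), 110000)
})

test_that("windows below the SNP minimum are ineligible; NAs are excluded", {
  map <- SnpMap(sprintf("s%d", 1:6), rep(1L, 6),
                as.integer(seq(10000, 60000, by = 10000)))
  vals <- c(1, 2, NA, 4, 5, 6)
  w <- windowAverage(vals, map, fstScanConfig(minSnps = 6L))
  w0 <- w[w$start == 0, ]
  expect_identical(w0$n_snps, 5L)        # 6 SNPs in window, one NA
  expect_false(w0$eligible)              # 5 scored < minSnps
  expect_equal(w0$mean_value, mean(c(1, 2, 4, 5, 6)))
  # empty chromosome: no windows at all
  expect_identical(nrow(windowAverage(numeric(0),
                                      SnpMap(character(0), integer(0),
                                             integer(0)),
                                      fstScanConfig())), 0L)
})

test_that("degenerate identical-FST windows are never flagged", {
  n <- 200
  w <- data.frame(chrom = 1L, start = seq(0, by = 25000, length.out = n))
  w$end <- w$start + 100000; w$n_snps <- 10L
  w$mean_fst <- 0.2; w$mean_het <- runif(n, 0.1, 0.5)
  w$eligible <- TRUE
  f <- flagFstCandidates(w, w, fstScanConfig())
  expect_false(any(f$candidate))
  expect_false(any(f$top_1))
})

test_that("planted outliers are recovered exactly against a quantile oracle", {
  set.seed(12)
  n <- 1000
  mk <- function() {
    w <- data.frame(chrom = 1L, start = seq(0, by = 25000, length.out = n))
    w$end <- w$start + 100000
    w$n_snps <- sample(6:30, n, replace = TRUE)
    w$mean_fst <- rbeta(n, 2, 18)
    w$mean_het <- runif(n, 0.05, 0.5)
    w$eligible <- TRUE
    w
  }
  w1 <- mk(); w2 <- mk()
  planted <- sample(n, 10)
  w1$mean_fst[planted] <- 0.9 + runif(10) / 20
  w2$mean_fst[planted] <- 0.9 + runif(10) / 20
  # spread the planted windows across the heterozygosity range so each
  # is the outlier of its own bin
  hets <- seq(0.07, 0.48, length.out = 10)
  w1$mean_het[planted] <- w2$mean_het[planted] <- hets
  f <- flagFstCandidates(w1, w2, fstScanConfig())
  expect_setequal(which(f$candidate), planted)
  # brute-force top criterion oracle for comparison 1
  cut1 <- quantile(w1$mean_fst, 0.99, type = 7)
  expect_identical(f$top_1, w1$mean_fst > cut1)
})

test_that("a window outlying in one comparison only is not a candidate", {
  n <- 400
  set.seed(13)
  base <- data.frame(chrom = 1L, start = seq(0, by = 25000, length.out = n))
  base$end <- base$start + 100000; base$n_snps <- 10L
  base$mean_het <- runif(n, 0.1, 0.5); base$eligible <- TRUE
  w1 <- base; w1$mean_fst <- rbeta(n, 2, 18)
  w2 <- base; w2$mean_fst <- rbeta(n, 2, 18)
  w1$mean_fst[5] <- 0.95; w1$mean_het[5] <- 0.11   # extreme in cmp1 only
  f <- flagFstCandidates(w1, w2, fstScanConfig())
  expect_true(f$top_1[5])
  expect_false(f$candidate[5])
})

test_that("fstScan wires per-SNP estimates into flagged windows", {
  sim <- cachedSim("fstsmoke", simConfig(seed = 77, nChrom = 1,
    chromLengthBp = 6e6, nSnpsPerChrom = 1200, founderPopSize = 60,
    burninGenerations = 40, lineSizes = c(CTL = 40, SEL1 = 60, SEL2 = 60),
    selectedLabels = c("SEL1", "SEL2"), selectionGenerations = 4,
    recombRate = 4e-7))
  fs <- fstScan(sim$genotypes, sim$lines)
  ps <- fs$perSnp[[1]]
  expect_identical(nrow(ps), 1200L)
  expect_true(all(ps$het >= 0 & ps$het <= 0.5, na.rm = TRUE))
  # spot-check one defined SNP against the scalar oracle
  j <- which(!is.na(ps$theta))[50]
  expect_equal(ps$theta[j],
               wcThetaOracle(ps$n1[j], round(2 * ps$n1[j] * ps$p1[j]),
                             ps$n2[j], round(2 * ps$n2[j] * ps$p2[j])),
               tolerance = 1e-10)
  expect_true(all(fs$flagged$candidate))
  # estimator switch produces a different but sane scan
  fsN <- fstScan(sim$genotypes, sim$lines, fstScanConfig(estimator = "nei"))
  expect_false(identical(fsN$windows$mean_fst_1, fs$windows$mean_fst_1))
})
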