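test_that("EHH equals the pair-enumeration definition on a worked case", {
  # 4 carriers extending as {ab, ab, ac, ad}: classes {2,1,1} -> 1/6
  h <- rbind(c(1L, 0L, 0L),
             c(1L, 0L, 0L),
             c(1L, 0L, 1L),
             c(1L, 1L, 0L))
  hd <- HaplotypeData(h, c("i1", "i2"),
                      SnpMap(c("c", "f1", "f2"), c(1L, 1L, 1L),
                             c(100L, 200L, 300L)))
  cv <- ehhCurve(hd, 1, carriers = 1:4, direction = "right")
  expect_equal(cv$ehh[1], 1)                    # at the core itself
  expect_equal(cv$ehh[2], 3 / 6)                # classes {3, 1} at flank 1
  expect_equal(cv$ehh[3], 1 / 6)                # classes {2, 1, 1}: one pair
  bf <- bruteEhhCurve(h, 1, 1:4, "right")
  expect_equal(cv$ehh[-1], bf$ehh)
})

test_that("EHH collapses to zero when all carriers diverge immediately", {
  h <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L), c(0L, 1L))
  hd <- HaplotypeData(h, c("i1", "i2"),
                      SnpMap(c("c", "f"), c(1L, 1L), c(10L, 20L)))
  cv <- ehhCurve(hd, 1, carriers = c(1L, 2L), direction = "right")
  expect_equal(cv$ehh, c(1, 0))
  # a core at the chromosome edge has an empty left side
  cvL <- ehhCurve(hd, 1, direction = "left")
  expect_identical(nrow(cvL), 1L)
})

test_that("EHH is non-increasing and matches brute force on random data", {
  set.seed(21)
  for (rep in 1:20) {
    nh <- 2 * sample(3:16, 1)
    S <- sample(20:80, 1)
    hd <- randomHaps(nh, S, seed = rep)
    core <- sample(2:(S - 1), 1)
    car <- sample(nh, sample(2:nh, 1))
    dir <- sample(c("left", "right"), 1)
    cv <- ehhCurve(hd, core, car, dir)
    expect_true(all(diff(cv$ehh) <= 1e-12))
    bf <- bruteEhhCurve(haplotypes(hd), core, car, dir)
    expect_equal(cv$ehh[-1], bf$ehh, tolerance = 1e-12)
  }
})

test_that("iHH integrates the documented trapezoids and truncation rule", {
  cv <- data.frame(pos = c(0, 1000, 2000), ehh = c(1, 0.5, 0.04))
  r <- ihh(cv, ehhCutoff = 0.05)
  expect_true(r$valid)
  expect_equal(r$ihh, 1020)                       # hand-worked trapezoids
  # second point already below cutoff: single trapezoid
  r2 <- ihh(data.frame(pos = c(0, 500), ehh = c(1, 0.01)), ehhCutoff = 0.05)
  expect_equal(r2$ihh, (1 + 0.01) / 2 * 500)
  # points beyond the truncation point are ignored
  cv3 <- data.frame(pos = c(0, 1000, 2000, 3000), ehh = c(1, 0.5, 0.04, 0.9))
  expect_equal(ihh(cv3, ehhCutoff = 0.05)$ihh, 1020)
})

test_that("iHH is invalid when the curve never decays, is empty, or gaps", {
  flat <- data.frame(pos = c(0, 1000, 2000), ehh = c(1, 1, 1))
  expect_false(ihh(flat, ehhCutoff = 0.05)$valid)
  expect_false(ihh(data.frame(pos = 0, ehh = 1))$valid)
  gap <- data.frame(pos = c(0, 300000, 310000), ehh = c(1, 0.5, 0.01))
  expect_false(ihh(gap, ehhCutoff = 0.05, maxGapBp = 200000)$valid)
  # both sides sum
  side <- data.frame(pos = c(0, 1000, 2000), ehh = c(1, 0.5, 0.04))
  expect_equal(ihh(list(side, side))$ihh, 2040)
})

test_that("iHS standardization gives zero-mean unit-sd bins and determinism", {
  sim <- cachedSim("haplosmoke", simConfig(seed = 55, nChrom = 1,
    chromLengthBp = 8e6, nSnpsPerChrom = 1600, founderPopSize = 80,
    burninGenerations = 60, lineSizes = c(CTL = 40, SEL1 = 80, SEL2 = 80),
    selectedLabels = c("SEL1", "SEL2"), selectionGenerations = 4,
    recombRate = 4e-7))
  selIds <- names(lineOf(sim$lines))[lineOf(sim$lines) != "CTL"]
  hs <- subsetSamples(sim$haplotypes, selIds)
  cfg <- haploScanConfig(seed = 9)
  sc <- ihsScan(hs, cfg)
  expect_gt(nrow(sc), 200)
  expect_true(all(pmin(sc$p_ref, 1 - sc$p_ref) >= cfg$mafMin))
  for (b in unique(sc$bin)) {
    expect_lt(abs(mean(sc$z[sc$bin == b])), 1e-9)
    expect_lt(abs(sd(sc$z[sc$bin == b]) - 1), 1e-9)
  }
  expect_equal(sc$abs_z, abs(sc$z))
  expect_identical(ihsScan(hs, cfg), sc)          # same seed, same scan
  sc2 <- ihsScan(hs, haploScanConfig(seed = 10))  # new reference draw
  expect_false(identical(sc2$raw, sc$raw))
})

test_that("XP-EHH is exactly zero for identical populations", {
  hd <- randomHaps(40, 120, seed = 33)
  sc <- xpehhScan(hd, hd, haploScanConfig())
  expect_gt(nrow(sc), 0)
  expect_true(all(abs(sc$raw) < 1e-12))
})

test_that("a homogeneous selected line scores positive against a diverse control", {
  set.seed(34)
  S <- 120
  map <- SnpMap(sprintf("s%03d", 1:S), rep(1L, S),
                seq(5000, by = 5000, length.out = S))
  ctl <- matrix(rbinom(40 * S, 1, 0.5), 40, S)
  hapA <- rbinom(S, 1, 0.5)
  sel <- matrix(rep(hapA, each = 40), 40, S)
  # sprinkle 10% noise: selected haplotypes stay far more homozygous
  # than control ones, yet their EHH still decays so cores are valid
  noise <- matrix(rbinom(40 * S, 1, 0.1) == 1, 40, S)
  sel[noise] <- 1L - sel[noise]
  hSel <- HaplotypeData(sel, sprintf("a%02d", 1:20), map)
  hCtl <- HaplotypeData(ctl, sprintf("b%02d", 1:20), map)
  sc <- xpehhScan(hSel, hCtl, haploScanConfig())
  expect_gt(nrow(sc), 0)
  expect_true(all(sc$raw > 0))
})

test_that("XP-EHH matches a brute-force pair-enumeration oracle on a toy", {
  set.seed(35)
  S <- 60
  map <- SnpMap(sprintf("s%03d", 1:S), rep(1L, S),
                seq(4000, by = 4000, length.out = S))
  A <- matrix(rbinom(4 * S, 1, 0.5), 4, S)
  B <- matrix(rbinom(4 * S, 1, 0.5), 4, S)
  hA <- HaplotypeData(A, c("a1", "a2"), map)
  hB <- HaplotypeData(B, c("b1", "b2"), map)
  cfg <- haploScanConfig(ehhCutoff = 0.05, maxGapBp = 1e6)
  sc <- xpehhScan(hA, hB, cfg)
  # oracle: population EHH curves by pair enumeration over all 8 and per
  # population, truncation where the combined curve drops below cutoff
  oracleRaw <- function(j) {
    comb <- rbind(A, B)
    tot <- 0; iA <- 0; iB <- 0
    for (dir in c("left", "right")) {
      bfC <- bruteEhhCurve(comb, j, 1:8, dir)
      bfA <- bruteEhhCurve(A, j, 1:4, dir)
      bfB <- bruteEhhCurve(B, j, 1:4, dir)
      stop <- which(bfC$ehh < cfg$ehhCutoff)[1]
      if (is.na(stop)) return(NA_real_)
      dist <- abs(posBp(map)[bfC$flank[1:stop]] - posBp(map)[j])
      trap <- function(e) sum((c(1, e[-stop]) + e) / 2 * diff(c(0, dist)))
      iA <- iA + trap(bfA$ehh[1:stop]); iB <- iB + trap(bfB$ehh[1:stop])
    }
    log(iA / iB)
  }
  for (id in sc$snp_id[c(3, 17, 29)]) {
    j <- match(id, snpId(map))
    expect_equal(sc$raw[sc$snp_id == id], oracleRaw(j), tolerance = 1e-10)
  }
})

test_that("window flagging honours thresholds, joint rule and sign", {
  map <- SnpMap(sprintf("s%02d", 1:10), rep(1L, 10),
                as.integer(seq(5000, 95000, by = 10000)))
  mkScores <- function(z) data.frame(snp_id = snpId(map), z = z,
                                     abs_z = abs(z))
  cfg <- haploScanConfig()
  ih <- mkScores(rep(2.6, 10)); names(ih)[2] <- "z"
  w <- windowFlagHaplo(data.frame(snp_id = snpId(map), abs_z = rep(2.60, 10)),
                       map, cfg, "ihs")
  expect_true(any(w$flagged & w$n_snps >= 6))
  # above threshold in one comparison only: never flagged
  w2 <- windowFlagHaplo(list(mkScores(rep(3, 10)), mkScores(rep(1, 10))),
                        map, cfg, "xpehh")
  expect_false(any(w2$flagged))
  # strongly negative windows are never flagged
  w3 <- windowFlagHaplo(list(mkScores(rep(-5, 10)), mkScores(rep(-5, 10))),
                        map, cfg, "xpehh")
  expect_false(any(w3$flagged))
  w4 <- windowFlagHaplo(list(mkScores(rep(2.9, 10)), mkScores(rep(2.7, 10))),
                        map, cfg, "xpehh")
  expect_true(any(w4$flagged))
})
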