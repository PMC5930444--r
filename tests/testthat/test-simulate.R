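# tiny configurations: enough structure to exercise the generative
# model without desk-scale cost
tinyCfg <- function(seed, qtl = NULL, selectedFraction = 0.2,
                    generations = 8L)
  simConfig(seed = seed, nChrom = 1, chromLengthBp = 4e6,
            nSnpsPerChrom = 300, founderPopSize = 60,
            burninGenerations = 30,
            lineSizes = c(CTL = 30, SEL1 = 40, SEL2 = 40),
            selectedLabels = c("SEL1", "SEL2"),
            selectionGenerations = generations, qtl = qtl,
            selectedFraction = selectedFraction, recombRate = 4e-7,
            # a tiny founder population cannot hold a 1-3% allele;
            # start the trait allele at intermediate-low frequency
            qtlMafRange = c(0.05, 0.15))

test_that("identical seeds give bit-identical simulations", {
  a <- simulateLines(tinyCfg(7))
  b <- simulateLines(tinyCfg(7))
  expect_identical(haplotypes(a$haplotypes), haplotypes(b$haplotypes))
  expect_identical(posBp(snpMap(a$haplotypes)), posBp(snpMap(b$haplotypes)))
  c <- simulateLines(tinyCfg(8))
  expect_false(identical(haplotypes(a$haplotypes), haplotypes(c$haplotypes)))
})

test_that("simulator output is complete, binary and frequency-sane", {
  sim <- simulateLines(tinyCfg(3))
  h <- haplotypes(sim$haplotypes)
  expect_false(anyNA(h))
  expect_true(all(h %in% c(0L, 1L)))
  p <- colMeans(h)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(sort(unique(unname(lineOf(sim$lines)))),
                   c("CTL", "SEL1", "SEL2"))
  expect_identical(nSamples(sim$haplotypes), 110L)
})

test_that("zero-effect truncation leaves the lines exchangeable", {
  qtl <- data.frame(chrom = 1, pos_bp = 2e6, effect = 0)
  diffs <- vapply(1:6, function(s) {
    sim <- simulateLines(tinyCfg(s, qtl = qtl, selectedFraction = 1))
    q <- sim$truth$qtl
    mean(c(q$freq_final_SEL1, q$freq_final_SEL2)) - q$freq_final_CTL
  }, 0)
  # neutral null: no systematic favored-allele excess in "selected" lines
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("strong truncation selection drives the favored allele up", {
  qtl <- data.frame(chrom = 1, pos_bp = 2e6, effect = 2.5)
  res <- vapply(1:10, function(s) {
    sim <- simulateLines(tinyCfg(s, qtl = qtl))
    q <- sim$truth$qtl
    c(sel = mean(c(q$freq_final_SEL1, q$freq_final_SEL2)),
      ctl = q$freq_final_CTL, split = q$freq_split)
  }, c(sel = 0, ctl = 0, split = 0))
  expect_gt(mean(res["sel", ]), mean(res["ctl", ]))
  expect_gt(mean(res["sel", ]), 0.8)       # sweeps essentially complete
  expect_true(all(res["split", ] <= 0.5))  # favored allele = minor at split
})

test_that("missingness injection hits its target rates", {
  sim <- simulateLines(tinyCfg(5))
  g <- sim$genotypes
  expect_identical(dosages(injectMissingness(g, 0, seed = 1)), dosages(g))
  g1 <- injectMissingness(g, 0, sampleRates = c(CTL_001 = 1), seed = 1)
  expect_true(all(is.na(dosages(g1)["CTL_001", ])))
  expect_false(anyNA(dosages(g1)[-1, ]))
  big <- GenotypeData(matrix(0L, 2, 10000,
                             dimnames = list(c("a", "b"), NULL)),
                      SnpMap(sprintf("s%05d", 1:10000), rep(1L, 10000),
                             1:10000))
  g2 <- injectMissingness(big, 0.05, seed = 2)
  rate <- mean(is.na(dosages(g2)))
  expect_gt(rate, 0.04); expect_lt(rate, 0.06)
})

test_that("relocated SNPs move far but keep their genotype columns", {
  sim <- simulateLines(tinyCfg(9))
  g <- sim$genotypes
  r0 <- relocateSnps(g, 0, 1e6, seed = 1)
  expect_identical(dosages(r0$genotypes), dosages(g))
  r <- relocateSnps(g, 3, 2e6, seed = 1)
  expect_identical(nrow(r$truth), 3L)
  expect_true(all(abs(r$truth$new_pos - r$truth$old_pos) >= 2e6))
  for (id in r$truth$snp_id) {
    before <- dosages(g)[, match(id, snpId(snpMap(g)))]
    after <- dosages(r$genotypes)[, match(id, snpId(snpMap(r$genotypes)))]
    expect_identical(after, before)
  }
  expect_error(relocateSnps(g, 1, 1e9, seed = 1), "too short")
})
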