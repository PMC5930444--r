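mkGeno <- function(d, pos = NULL, chrom = NULL) {
  S <- ncol(d)
  if (is.null(pos)) pos <- seq(1e4, by = 1e4, length.out = S)
  if (is.null(chrom)) chrom <- rep(1L, S)
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  GenotypeData(d, SnpMap(sprintf("m%03d", seq_len(S)), chrom, pos))
}

test_that("sample call-rate filter is strict 'lower than'", {
  set.seed(1)
  d <- matrix(1L, 10, 20)
  d[1, ] <- NA                       # call rate 0
  d[2, 1:2] <- NA                    # call rate 0.90 exactly -> kept
  d[3, 1:3] <- NA                    # 0.85 -> removed
  g <- mkGeno(d)
  r <- filterSamples(g, qcConfig())
  expect_setequal(r$report$id, c("s001", "s003"))
  expect_true("s002" %in% sampleIds(r$genotypes))
  expect_error(filterSamples(mkGeno(matrix(NA_integer_, 2, 3))),
               "all samples")
})

test_that("SNP filters: call rate, autosome set, duplicates, all-line monomorphy", {
  lines <- LineAssignment(setNames(rep(c("A", "B"), each = 5),
                                   sprintf("s%03d", 1:10)), "A", "B")
  d <- matrix(1L, 10, 6)
  d[1:10, 1] <- c(0L, rep(1L, 9))       # polymorphic everywhere: kept
  d[1, 2] <- NA                         # call rate 0.9 < 0.95: removed
  d[, 3] <- 0L                          # monomorphic in A and B: removed
  d[, 4] <- c(rep(0L, 5), rep(2L, 5))   # fixed per line, poly overall: removed
  d[, 5] <- c(0L, 1L, rep(0L, 8))       # poly in A, mono in B: kept
  g <- mkGeno(d, pos = c(1e4, 2e4, 3e4, 4e4, 5e4, 5e4),
              chrom = c(1L, 1L, 1L, 1L, 1L, 1L))
  # SNPs 5 and 6 share (chrom,pos): both duplicates (6 polymorphic too)
  d2 <- d; d2[, 6] <- c(1L, 0L, rep(1L, 8))
  g <- mkGeno(d2, pos = c(1e4, 2e4, 3e4, 4e4, 5e4, 5e4))
  r <- filterSnps(g, lines, qcConfig())
  rep <- r$report
  expect_identical(rep$reason[rep$id == "m002"], "call_rate")
  expect_identical(rep$reason[rep$id == "m003"], "monomorphic_all_lines")
  expect_identical(rep$reason[rep$id == "m004"], "monomorphic_all_lines")
  expect_true(all(c("m005", "m006") %in%
                  rep$id[rep$reason == "duplicate_position"]))
  expect_identical(snpId(snpMap(r$genotypes)), "m001")
})

test_that("non-autosomal SNPs are removed; line-restricted monomorphy kept", {
  lines <- LineAssignment(setNames(rep(c("A", "B"), each = 3),
                                   sprintf("s%03d", 1:6)), "A", "B")
  d <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L,
                0L, 1L, 0L, 2L, 1L, 1L), 6, 2)
  g <- mkGeno(d, chrom = c(1L, 30L))
  r <- filterSnps(g, lines, qcConfig(autosomes = 1:29))
  expect_identical(r$report$reason[r$report$id == "m002"], "non_autosomal")
  expect_identical(snpId(snpMap(r$genotypes)), "m001")
})

test_that("genotype r2 equals the squared Pearson correlation", {
  x <- c(0, 0, 1, 2, 2); y <- c(0, 1, 1, 2, 2)
  # independent computation from the raw Pearson sums
  n <- 5
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  expect_equal(genotypeR2(x, y), (num / den)^2)
  expect_equal(genotypeR2(x, x), 1)
  expect_true(is.na(genotypeR2(x, rep(1, 5))))
  expect_true(is.na(genotypeR2(c(0, NA, NA, NA, NA), y)))
  # symmetry and allele-coding invariance
  expect_equal(genotypeR2(x, y), genotypeR2(y, x))
  expect_equal(genotypeR2(2 - x, y), genotypeR2(x, y))
})

# Constructed misplaced-SNP scenario: perfect-LD blocks of 10 SNPs
# clustered within < 10 Mb (so no intact pair is ever "distant"), with
# selected block members relocated >= 20 Mb away.
misplacedToy <- function(nBlocks = 6, blockSize = 10, seed = 42,
                         relocate = 1) {
  set.seed(seed)
  nSnp <- nBlocks * blockSize
  n <- 40
  base <- matrix(rbinom(n * nBlocks, 2, 0.5), n, nBlocks)
  d <- base[, rep(seq_len(nBlocks), each = blockSize)]
  rownames(d) <- sprintf("s%03d", 1:n)
  pos <- seq(5e4, by = 5e4, length.out = blockSize)     # 50 kb spacing
  pos <- rep(seq(0, by = 1e6, length.out = nBlocks), each = blockSize) +
    rep(pos, nBlocks)
  moved <- integer(0)
  if (relocate > 0) {
    moved <- seq_len(relocate) * blockSize - 4L    # one SNP per block
    pos[moved] <- pos[moved] + 2e7 + 4e6 * seq_len(relocate)
  }
  ord <- order(pos)
  g <- GenotypeData(d[, ord], SnpMap(sprintf("m%03d", seq_len(nSnp))[ord],
                                     rep(1L, nSnp), pos[ord]))
  list(geno = g, truth = sprintf("m%03d", moved))
}

test_that("no distant LD means no flags and no removals", {
  toy <- misplacedToy(relocate = 0)
  r <- detectMisplacedSnps(toy$geno, qcConfig())
  expect_identical(r$removed, character(0))
  expect_identical(nrow(r$report), 0L)
})

test_that("a relocated SNP draws the flag maximum and only it is removed", {
  toy <- misplacedToy(relocate = 1)
  r <- detectMisplacedSnps(toy$geno, qcConfig())
  expect_identical(r$removed, toy$truth)
  # its 9 abandoned block mates sit > 10 Mb away at r2 = 1
  expect_gte(r$report$flags[1], 9)
  expect_identical(r$report$iteration[1], 1L)
  # idempotence: a second pass removes nothing
  r2 <- detectMisplacedSnps(r$genotypes, qcConfig())
  expect_identical(r2$removed, character(0))
})

test_that("tied relocated SNPs are removed in the same iteration", {
  toy <- misplacedToy(relocate = 2)
  r <- detectMisplacedSnps(toy$geno, qcConfig())
  expect_setequal(r$removed, toy$truth)
  expect_true(all(r$report$iteration <= 2))
})

test_that("the QC chain runs in fixed order and is idempotent", {
  sim <- simulateLines(simConfig(seed = 31, nChrom = 1,
    chromLengthBp = 4e6, nSnpsPerChrom = 250, founderPopSize = 50,
    burninGenerations = 20, lineSizes = c(CTL = 20, SEL1 = 25, SEL2 = 25),
    selectedLabels = c("SEL1", "SEL2"), selectionGenerations = 2,
    recombRate = 4e-7))
  g <- injectMissingness(sim$genotypes, 0.02,
                         sampleRates = c(CTL_001 = 0.5), seed = 1)
  qc <- runQc(g, sim$lines, qcConfig())
  expect_true("CTL_001" %in% qc$report$id[qc$report$type == "sample"])
  qc2 <- runQc(qc$genotypes, qc$lines, qcConfig())
  expect_identical(nrow(qc2$report), 0L)
  expect_identical(dosages(qc2$genotypes), dosages(qc$genotypes))
})
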