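# Independent oracles used to validate the implementation. These are
# deliberately written from the definitions (pair enumeration, explicit
# variance-component sums) and share no code with the package.

# EHH by brute-force pair enumeration: for each flanking SNP, the
# fraction of carrier pairs identical over the interval from the core
# (exclusive) to that SNP (inclusive).
bruteEhhCurve <- function(h, core, carriers, direction) {
  S <- ncol(h)
  idx <- if (direction == "right") seq(core, S) else seq(core, 1)
  flank <- idx[-1]
  if (length(carriers) < 2) stop("need >= 2 carriers")
  pairs <- utils::combn(carriers, 2)
  if (length(flank) == 0)
    return(data.frame(flank = integer(0), ehh = numeric(0)))
  eq <- matrix(0, ncol(pairs), length(flank))
  for (p in seq_len(ncol(pairs))) {
    a <- h[pairs[1, p], flank]
    b <- h[pairs[2, p], flank]
    eq[p, ] <- cumprod(a == b)
  }
  data.frame(flank = flank, ehh = colMeans(eq))
}

# Weir & Cockerham (1984) two-population theta written as explicit
# scalar variance-component sums over populations (HWE-expected
# heterozygosity), evaluated one SNP at a time.
wcThetaOracle <- function(n1, x1, n2, x2) {
  n <- c(n1, n2)
  p <- c(x1 / (2 * n1), x2 / (2 * n2))
  r <- 2
  nbar <- mean(n)
  pbar <- sum(n * p) / sum(n)
  if (pbar == 0 || pbar == 1 || any(n < 1)) return(NA_real_)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * 2 * p * (1 - p)) / sum(n)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# convenience: random phased data with block LD so EHH decays
randomHaps <- function(nHap, nSnp, seed, chrom = 1L, spacingBp = 5000L) {
  set.seed(seed)
  h <- matrix(rbinom(nHap * nSnp, 1, 0.5), nHap, nSnp)
  map <- SnpMap(sprintf("s%04d", seq_len(nSnp)), rep(chrom, nSnp),
                seq(spacingBp, by = spacingBp, length.out = nSnp))
  n <- nHap %/% 2
  HaplotypeData(h[seq_len(2 * n), , drop = FALSE],
                sprintf("i%03d", seq_len(n)), map)
}
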