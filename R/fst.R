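#' Weir & Cockerham (1984) two-population theta
#'
#' Unequal-sample-size-corrected FST estimator from allele counts, in
#' the allele-frequency-only form: the within-population heterozygosity
#' term uses Hardy-Weinberg expected frequencies. Vectorized over SNPs.
#' Undefined (`NA`) when the SNP is monomorphic in the pooled sample or
#' a population has no called genotype.
#'
#' @param n1,n2 called diploid counts per population.
#' @param x1,x2 counted-allele (alleleB) copy counts, 0 <= x_i <= 2 n_i.
#' @return theta estimates (may be negative; 1 for a fixed difference).
#' @export
wcTheta <- function(n1, x1, n2, x2) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  p1 <- x1 / (2 * n1); p2 <- x2 / (2 * n2)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[n1 < 1 | n2 < 1 | pbar == 0 | pbar == 1] <- NA_real_
  theta
}

#' Nei & Chesser (1983) corrected GST for two populations
#'
#' Sample-size-corrected GST from allele frequencies, available as a
#' sensitivity alternative to [wcTheta()] (`estimator = "nei"` in the
#' scan functions). Uses the harmonic mean sample size.
#'
#' @inheritParams wcTheta
#' @return GST estimates; `NA` where undefined.
#' @export
neiGst <- function(n1, x1, n2, x2) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  p1 <- x1 / (2 * n1); p2 <- x2 / (2 * n2)
  nh <- 2 / (1 / n1 + 1 / n2)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hsHat <- (2 * nh / (2 * nh - 1)) * hs
  htHat <- ht + hsHat / (4 * nh)
  g <- 1 - hsHat / htHat
  g[n1 < 1 | n2 < 1 | htHat == 0] <- NA_real_
  g
}

#' Expected total heterozygosity of a population pair
#'
#' 2 p (1 - p) at the unweighted mean allele frequency of the two
#' populations (the convention of FST-heterozygosity outlier methods).
#'
#' @param p1,p2 counted-allele frequencies per population.
#' @return heterozygosity in \[0, 0.5\]; `NA` when a frequency is `NA`.
#' @export
expectedHet <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  2 * pbar * (1 - pbar)
}

#' Sliding-window configuration for the FST outlier scan
#'
#' Windows of `windowSize` bp advance by `windowSize - overlap` (100 kb
#' windows overlapping by 75 kb advance by 25 kb), anchored at 0 bp on
#' each chromosome. A window needs at least `minSnps` scored SNPs
#' ("more than five") to be eligible. Candidates must fall strictly
#' above the empirical `topQuantile` of window mean FST *and* above the
#' upper tail of the `ci` interval within their heterozygosity bin
#' (`hetBins` equal-count bins), in every cross-line comparison.
#'
#' @param windowSize window width in bp.
#' @param overlap window overlap in bp (step = windowSize - overlap).
#' @param minSnps minimum scored SNPs for an eligible window.
#' @param topQuantile empirical quantile defining the top criterion.
#' @param hetBins number of equal-count heterozygosity bins.
#' @param ci confidence level of the within-bin interval.
#' @param estimator "wc" (Weir-Cockerham theta) or "nei" (corrected GST).
#' @return list of class `FstScanConfig`. Empirical quantiles use
#'   linear interpolation between order statistics (type 7).
#' @export
fstScanConfig <- function(windowSize = 100000L, overlap = 75000L,
                          minSnps = 6L, topQuantile = 0.99,
                          hetBins = 20L, ci = 0.95,
                          estimator = c("wc", "nei")) {
  stopifnot(overlap < windowSize, topQuantile > 0, topQuantile < 1,
            ci > 0, ci < 1, minSnps >= 1L, hetBins >= 1L)
  structure(list(windowSize = as.integer(windowSize),
                 overlap = as.integer(overlap), minSnps = as.integer(minSnps),
                 topQuantile = topQuantile, hetBins = as.integer(hetBins),
                 ci = ci, estimator = match.arg(estimator),
                 quantileType = 7L),
            class = "FstScanConfig")
}

#' Per-SNP FST and heterozygosity for one pair of lines
#'
#' @param geno a [GenotypeData].
#' @param lines a [LineAssignment].
#' @param pop1,pop2 line labels to compare.
#' @param estimator "wc" or "nei".
#' @return data.frame with snp_id, chrom, pos_bp, n1, n2, p1, p2,
#'   theta (NA where undefined) and het.
#' @export
snpFst <- function(geno, lines, pop1, pop2, estimator = "wc") {
  ids1 <- names(lines@line)[lines@line == pop1]
  ids2 <- names(lines@line)[lines@line == pop2]
  ids1 <- intersect(ids1, rownames(geno@dosage))
  ids2 <- intersect(ids2, rownames(geno@dosage))
  if (!length(ids1) || !length(ids2))
    stop("both lines must have genotyped samples")
  d1 <- geno@dosage[ids1, , drop = FALSE]
  d2 <- geno@dosage[ids2, , drop = FALSE]
  n1 <- colSums(!is.na(d1)); x1 <- colSums(d1, na.rm = TRUE)
  n2 <- colSums(!is.na(d2)); x2 <- colSums(d2, na.rm = TRUE)
  est <- if (estimator == "nei") neiGst else wcTheta
  theta <- est(n1, x1, n2, x2)
  p1 <- ifelse(n1 > 0, x1 / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, x2 / (2 * n2), NA_real_)
  data.frame(snp_id = geno@map@snpId, chrom = geno@map@chrom,
             pos_bp = geno@map@posBp, n1 = n1, n2 = n2, p1 = p1, p2 = p2,
             theta = theta, het = expectedHet(p1, p2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average per-SNP values over overlapping genomic windows
#'
#' Windows are half-open \[start, start + windowSize) intervals anchored
#' at 0 bp, advancing by the window step on each chromosome up to the
#' last SNP. The mean is taken over SNPs with a defined (non-`NA`)
#' value; `n_snps` counts those SNPs. Windows with fewer than `minSnps`
#' scored SNPs carry `NA` means and are ineligible for flagging.
#'
#' @param values numeric per-SNP values aligned to `map` (`NA` =
#'   undefined, excluded).
#' @param map a [SnpMap].
#' @param cfg a config carrying `windowSize`, `overlap`, `minSnps`
#'   (e.g. [fstScanConfig()] or [haploScanConfig()]).
#' @return data.frame with chrom, start, end, n_snps, mean_value,
#'   eligible.
#' @export
windowAverage <- function(values, map, cfg = fstScanConfig()) {
  stopifnot(length(values) == length(map@snpId))
  step <- cfg$windowSize - cfg$overlap
  out <- vector("list", 0L)
  for (ch in unique(map@chrom)) {
    j <- which(map@chrom == ch & !is.na(values))
    jAll <- which(map@chrom == ch)
    if (!length(jAll)) next
    lastPos <- max(map@posBp[jAll])
    starts <- seq.int(0L, (lastPos %/% step) * step, by = step)
    if (!length(j)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts, end = starts + cfg$windowSize,
        n_snps = 0L, mean_value = NA_real_)
      next
    }
    pos <- map@posBp[j]; val <- values[j]
    o <- order(pos); pos <- pos[o]; val <- val[o]
    cumv <- c(0, cumsum(val))
    hi <- findInterval(starts + cfg$windowSize - 1L, pos)  # pos < end
    lo <- findInterval(starts - 1L, pos)                   # pos < start
    n <- hi - lo
    mv <- ifelse(n > 0L, (cumv[hi + 1L] - cumv[lo + 1L]) / n, NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = starts, end = starts + cfg$windowSize,
      n_snps = n, mean_value = mv)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = integer(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      mean_value = numeric(0))
  res$eligible <- res$n_snps >= cfg$minSnps & !is.na(res$mean_value)
  res
}

# equal-count bin assignment over a numeric vector; returns integer bins
.equalCountBins <- function(x, nBins) {
  n <- length(x)
  if (n < nBins) {
    nBins <- max(1L, n %/% 50L)
    warning(sprintf("fewer values than bins; reduced to %d bin(s)", nBins))
  }
  r <- rank(x, ties.method = "first")
  pmin(nBins, ceiling(r / (n / nBins)))
}

#' Joint FST outlier criterion across two cross-line comparisons
#'
#' Within each comparison, an eligible window is a *top* outlier when
#' its mean FST lies strictly above the empirical `topQuantile` of all
#' eligible windows, and a *het-bin* outlier when its mean FST lies
#' strictly above the upper (1 + ci)/2 empirical quantile of the
#' eligible windows in its equal-count heterozygosity bin (the upper
#' tail only: low-FST outliers are reported in the `low_*` columns but
#' never flagged as selection candidates). A window is a candidate iff
#' both criteria hold in both comparisons.
#'
#' @param windowsCmp1,windowsCmp2 window tables for the two comparisons
#'   (same grid), each with columns chrom, start, end, n_snps,
#'   mean_fst, mean_het, eligible.
#' @param cfg an [fstScanConfig()].
#' @return merged window data.frame with per-comparison criterion
#'   columns and a logical `candidate` column.
#' @export
flagFstCandidates <- function(windowsCmp1, windowsCmp2,
                              cfg = fstScanConfig()) {
  stopifnot(nrow(windowsCmp1) == nrow(windowsCmp2),
            all(windowsCmp1$start == windowsCmp2$start),
            all(windowsCmp1$chrom == windowsCmp2$chrom))
  crit <- function(w) {
    top <- bin <- low <- rep(FALSE, nrow(w))
    el <- which(w$eligible)
    if (length(el)) {
      cut <- stats::quantile(w$mean_fst[el], cfg$topQuantile,
                             type = cfg$quantileType, names = FALSE)
      top[el] <- w$mean_fst[el] > cut
      bins <- .equalCountBins(w$mean_het[el], cfg$hetBins)
      for (b in unique(bins)) {
        ib <- el[bins == b]
        up <- stats::quantile(w$mean_fst[ib], (1 + cfg$ci) / 2,
                              type = cfg$quantileType, names = FALSE)
        dn <- stats::quantile(w$mean_fst[ib], (1 - cfg$ci) / 2,
                              type = cfg$quantileType, names = FALSE)
        bin[ib] <- w$mean_fst[ib] > up
        low[ib] <- w$mean_fst[ib] < dn
      }
    }
    list(top = top, bin = bin, low = low)
  }
  c1 <- crit(windowsCmp1); c2 <- crit(windowsCmp2)
  data.frame(
    chrom = windowsCmp1$chrom, start = windowsCmp1$start,
    end = windowsCmp1$end,
    n_snps_1 = windowsCmp1$n_snps, n_snps_2 = windowsCmp2$n_snps,
    mean_fst_1 = windowsCmp1$mean_fst, mean_fst_2 = windowsCmp2$mean_fst,
    mean_het_1 = windowsCmp1$mean_het, mean_het_2 = windowsCmp2$mean_het,
    top_1 = c1$top, top_2 = c2$top, bin_1 = c1$bin, bin_2 = c2$bin,
    low_1 = c1$low, low_2 = c2$low,
    candidate = c1$top & c1$bin & c2$top & c2$bin)
}

#' Windowed FST outlier scan across control-vs-selected comparisons
#'
#' Computes per-SNP FST and heterozygosity for the comparison of the
#' control line with each selected line, averages both over the sliding
#' window grid, and applies the joint top-quantile + heterozygosity-bin
#' criterion of [flagFstCandidates()] across the two comparisons.
#'
#' @param geno a [GenotypeData].
#' @param lines a [LineAssignment] with exactly two selected lines.
#' @param cfg an [fstScanConfig()].
#' @return list with `perSnp` (per-comparison per-SNP tables),
#'   `windows` (merged window table with criterion flags) and `flagged`
#'   (candidate windows only).
#' @export
fstScan <- function(geno, lines, cfg = fstScanConfig()) {
  sel <- lines@selected
  if (length(sel) != 2L)
    stop("the joint criterion requires exactly two selected lines")
  perSnp <- lapply(sel, function(s)
    snpFst(geno, lines, lines@control, s, cfg$estimator))
  names(perSnp) <- paste0(lines@control, "_vs_", sel)
  win <- lapply(perSnp, function(ps) {
    w <- windowAverage(ps$theta, geno@map, cfg)
    names(w)[names(w) == "mean_value"] <- "mean_fst"
    wh <- windowAverage(ifelse(is.na(ps$theta), NA, ps$het), geno@map, cfg)
    w$mean_het <- wh$mean_value
    w
  })
  flags <- flagFstCandidates(win[[1]], win[[2]], cfg)
  list(perSnp = perSnp, windows = flags,
       flagged = flags[flags$candidate, , drop = FALSE], config = cfg)
}
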