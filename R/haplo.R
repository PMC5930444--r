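#' Configuration for the haplotype-based scans
#'
#' @param mafMin minimum minor allele frequency of core SNPs (applied
#'   by the iHS scan only; near-fixed cores are uninformative within a
#'   population).
#' @param nFreqBins number of equal-count reference-allele-frequency
#'   bins for iHS standardization.
#' @param ehhCutoff EHH level at which integration truncates; a core
#'   whose EHH never decays below it before the chromosome end is
#'   dropped as invalid.
#' @param maxGapBp cores whose EHH curve spans an inter-SNP gap larger
#'   than this before truncation are dropped.
#' @param windowSize,overlap,minSnps sliding-window grid (identical to
#'   the FST grid: 100 kb windows overlapping by 75 kb, at least 6
#'   scored SNPs).
#' @param threshold window-mean significance cut-off (2.58, i.e.
#'   p < 0.005 under normality).
#' @param seed seed of the random reference-allele assignment (iHS).
#' @return list of class `HaploScanConfig`.
#' @export
haploScanConfig <- function(mafMin = 0.01, nFreqBins = 20L,
                            ehhCutoff = 0.05, maxGapBp = 200000L,
                            windowSize = 100000L, overlap = 75000L,
                            minSnps = 6L, threshold = 2.58, seed = 1L) {
  stopifnot(ehhCutoff > 0, ehhCutoff < 1, threshold > 0,
            overlap < windowSize)
  structure(list(mafMin = mafMin, nFreqBins = as.integer(nFreqBins),
                 ehhCutoff = ehhCutoff, maxGapBp = as.integer(maxGapBp),
                 windowSize = as.integer(windowSize),
                 overlap = as.integer(overlap), minSnps = as.integer(minSnps),
                 threshold = threshold, seed = as.integer(seed)),
            class = "HaploScanConfig")
}

#' Subset a haplotype or genotype object to a set of samples
#'
#' @param x a [HaplotypeData] or [GenotypeData].
#' @param ids sample ids to keep (order preserved as given).
#' @return object of the same class restricted to `ids`.
#' @export
subsetSamples <- function(x, ids) {
  if (is(x, "HaplotypeData")) {
    i <- match(ids, x@sampleIds)
    if (anyNA(i)) stop("unknown sample id(s)")
    rows <- as.vector(rbind(2L * i - 1L, 2L * i))
    HaplotypeData(x@haplo[rows, , drop = FALSE], ids, x@map)
  } else if (is(x, "GenotypeData")) {
    if (!all(ids %in% rownames(x@dosage))) stop("unknown sample id(s)")
    GenotypeData(x@dosage[ids, , drop = FALSE], x@map)
  } else stop("unsupported class")
}

# 1-based column range of each chromosome in a (sorted) SnpMap
.chromRanges <- function(map) {
  lapply(split(seq_along(map@chrom), map@chrom), range)
}

#' One-sided EHH curve at a core SNP
#'
#' EHH at a flanking SNP x is the probability that two haplotypes drawn
#' at random from `carriers` are identical over the flanking interval
#' from the core (exclusive) to x (inclusive); it equals 1 at the core
#' itself and is non-increasing outward. When `carriers` is the set of
#' haplotypes sharing a core allele this is the classical
#' allele-conditioned EHH; with all haplotypes it is the
#' population-level EHH used by XP-EHH.
#'
#' @param haps a [HaplotypeData].
#' @param core 1-based SNP index of the core.
#' @param carriers haplotype row indices (default: all haplotypes);
#'   at least 2.
#' @param direction "right" (increasing position) or "left".
#' @param cutoff stop extending once EHH drops below this value (0 =
#'   extend to the chromosome end).
#' @return data.frame with columns `pos` and `ehh`; the first row is
#'   the core (ehh = 1). A core at the chromosome edge yields only the
#'   core row.
#' @export
ehhCurve <- function(haps, core, carriers = seq_len(nrow(haps@haplo)),
                     direction = c("right", "left"), cutoff = 0) {
  direction <- match.arg(direction)
  if (length(carriers) < 2L) stop("need at least 2 carrier haplotypes")
  map <- haps@map
  rng <- range(which(map@chrom == map@chrom[core]))
  dec <- ehh_decay_cpp(haps@haplo, core, rng[1], rng[2],
                       if (direction == "right") 1L else -1L,
                       list(as.integer(carriers)),
                       list(rep(1, length(carriers))), 1L, cutoff)
  idx <- dec$idx
  vals <- dec$ehh[, 1]
  # once every identity class is a single pattern the EHH is constant
  # to the chromosome end; extend the recorded plateau explicitly
  if (!dec$stopped && length(idx)) {
    last <- idx[length(idx)]
    restEnd <- if (direction == "right") rng[2] else rng[1]
    if (last != restEnd) {
      rest <- if (direction == "right") seq(last + 1L, restEnd) else
        seq(last - 1L, restEnd)
      idx <- c(idx, rest)
      vals <- c(vals, rep(vals[length(vals)], length(rest)))
    }
  }
  data.frame(pos = c(map@posBp[core], map@posBp[idx]),
             ehh = c(1, vals))
}

# trapezoidal integral of an EHH sequence against physical distance,
# starting from the core point (distance 0, EHH 1)
.trapz <- function(dist, ehh) {
  d <- c(0, dist); e <- c(1, ehh)
  sum((e[-1] + e[-length(e)]) / 2 * diff(d))
}

#' Integrated EHH (iHH) from one or two side curves
#'
#' Trapezoidal integral of EHH against physical distance, accumulated
#' outward until the first point with EHH below `ehhCutoff` (that final
#' trapezoid included), the two sides summed. The value is invalid ---
#' flagged, not an error --- when a side never drops below the cutoff
#' before its last point (chromosome end), when a side is empty (core
#' at the chromosome edge), or when an inter-SNP gap larger than
#' `maxGapBp` occurs before truncation.
#'
#' @param curves a single curve data.frame (columns pos, ehh; first row
#'   the core) or a list of one/two such curves, as from [ehhCurve()].
#' @param ehhCutoff truncation level.
#' @param maxGapBp maximum tolerated inter-SNP gap in bp.
#' @return list with `ihh` (bp x EHH units; `NA` if invalid) and
#'   `valid`.
#' @export
ihh <- function(curves, ehhCutoff = 0.05, maxGapBp = 200000L) {
  if (is.data.frame(curves)) curves <- list(curves)
  total <- 0
  for (cv in curves) {
    if (nrow(cv) < 2L) return(list(ihh = NA_real_, valid = FALSE))
    below <- which(cv$ehh[-1] < ehhCutoff)
    if (!length(below)) return(list(ihh = NA_real_, valid = FALSE))
    stopAt <- below[1] + 1L
    gaps <- abs(diff(cv$pos[seq_len(stopAt)]))
    if (any(gaps > maxGapBp)) return(list(ihh = NA_real_, valid = FALSE))
    dist <- abs(cv$pos[2:stopAt] - cv$pos[1])
    total <- total + .trapz(dist, cv$ehh[2:stopAt])
  }
  list(ihh = total, valid = TRUE)
}

# integrate one decay-result side for EHH column `col`; assumes the
# decay stopped by cutoff (validity checked by caller)
.sideIntegral <- function(posSeq, ehhSeq, corePos) {
  .trapz(abs(posSeq - corePos), ehhSeq)
}

# gap validity of one side: consecutive distances (core -> first flank,
# then flank to flank) must not exceed maxGap
.sideGapsOk <- function(posSeq, corePos, maxGap) {
  all(abs(diff(c(corePos, posSeq))) <= maxGap)
}

# Collapse exact duplicate haplotype rows of a matrix block into
# distinct patterns with multiplicities. EHH over weighted distinct
# patterns is identical to EHH over the raw rows; collapsing only
# removes redundant work.
.dedupRows <- function(M) {
  key <- vapply(seq_len(nrow(M)),
                function(i) rawToChar(as.raw(M[i, ] + 48L)), "")
  uidx <- which(!duplicated(key))
  g <- match(key, key[uidx])
  list(H = M[uidx, , drop = FALSE],
       weight = as.numeric(tabulate(g, length(uidx))),
       groupOf = g)
}

#' Integrated haplotype score (iHS) scan within one population
#'
#' For each core SNP passing the MAF filter, one allele is assigned as
#' the "reference" allele uniformly at random (seeded); iHH is
#' integrated separately over the reference-carrier and
#' other-carrier haplotypes (each side truncated at its own EHH
#' cutoff), and the raw score is ln(iHH_ref / iHH_other). Cores with an
#' invalid iHH on either allele, or fewer than 2 carriers of either
#' allele, are dropped. Raw scores are standardized to mean 0, sd 1
#' within equal-count reference-allele-frequency bins; the scan reports
#' both the signed standardized score and its absolute value, the
#' statistic used for window flagging.
#'
#' @param haps a [HaplotypeData] of the target population (e.g. the
#'   pooled directionally selected lines).
#' @param cfg a [haploScanConfig()].
#' @return data.frame with snp_id, chrom, pos_bp, p_ref, bin, raw, z,
#'   abs_z.
#' @export
ihsScan <- function(haps, cfg = haploScanConfig()) {
  H <- haps@haplo
  map <- haps@map
  p <- colMeans(H)
  cores <- which(pmin(p, 1 - p) >= cfg$mafMin)
  set.seed(cfg$seed)
  refAllele <- sample(c(0L, 1L), length(cores), replace = TRUE)
  n <- length(cores)
  raw <- rep(NA_real_, n)
  for (ch in unique(map@chrom)) {
    colsCh <- which(map@chrom == ch)
    dd <- .dedupRows(H[, colsCh, drop = FALSE])
    posCh <- map@posBp[colsCh]
    hiCh <- length(colsCh)
    coresCh <- which(cores %in% colsCh)
    for (i in coresCh) {
      jl <- match(cores[i], colsCh)
      carR <- which(dd$H[, jl] == refAllele[i])
      carA <- which(dd$H[, jl] != refAllele[i])
      if (sum(dd$weight[carR]) < 2 || sum(dd$weight[carA]) < 2) next
      vals <- numeric(2)
      ok <- TRUE
      for (a in 1:2) {
        car <- if (a == 1L) carR else carA
        tot <- 0
        for (dir in c(-1L, 1L)) {
          dec <- ehh_decay_cpp(dd$H, jl, 1L, hiCh, dir, list(car),
                               list(dd$weight[car]), 1L, cfg$ehhCutoff)
          if (!dec$stopped ||
              !.sideGapsOk(posCh[dec$idx], posCh[jl], cfg$maxGapBp)) {
            ok <- FALSE; break
          }
          tot <- tot + .sideIntegral(posCh[dec$idx], dec$ehh[, 1],
                                     posCh[jl])
        }
        if (!ok) break
        vals[a] <- tot
      }
      if (ok && vals[1] > 0 && vals[2] > 0) raw[i] <- log(vals[1] / vals[2])
    }
  }
  keep <- !is.na(raw)
  pRef <- ifelse(refAllele == 1L, p[cores], 1 - p[cores])
  out <- data.frame(snp_id = map@snpId[cores], chrom = map@chrom[cores],
                    pos_bp = map@posBp[cores], p_ref = pRef,
                    raw = raw, stringsAsFactors = FALSE)[keep, ]
  if (!nrow(out)) {
    out$bin <- integer(0); out$z <- numeric(0); out$abs_z <- numeric(0)
    return(out)
  }
  bins <- .equalCountBins(out$p_ref, cfg$nFreqBins)
  # merge undersized bins (fewer than 2 scores) with their left neighbour
  tab <- table(bins)
  while (any(tab < 2L) && length(tab) > 1L) {
    small <- as.integer(names(tab)[tab < 2L][1])
    target <- if (small > min(bins)) max(bins[bins < small]) else
      min(bins[bins > small])
    bins[bins == small] <- target
    warning("merged an undersized frequency bin with its neighbour")
    tab <- table(bins)
  }
  z <- numeric(nrow(out))
  for (b in unique(bins)) {
    ib <- bins == b
    mu <- mean(out$raw[ib]); s <- stats::sd(out$raw[ib])
    z[ib] <- if (is.na(s) || s == 0) 0 else (out$raw[ib] - mu) / s
  }
  out$bin <- bins
  out$z <- z
  out$abs_z <- abs(z)
  rownames(out) <- NULL
  out
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For each core SNP, population-level EHH (over all haplotypes of a
#' population, no allele conditioning) is extended outward in both
#' directions; truncation occurs where the EHH of the combined
#' populations drops below the cutoff, so both populations' integrals
#' share the same limits. The raw score is
#' ln(iHH_population1 / iHH_population2) --- positive when extended
#' homozygosity is longer in population 1 (the selected line) --- and
#' is standardized genome-wide to mean 0, sd 1. Cores where the
#' combined EHH never decays below the cutoff before a chromosome end,
#' or that span an over-gap interval, are dropped.
#'
#' @param hapsSel a [HaplotypeData] of the selected line (numerator).
#' @param hapsCtrl a [HaplotypeData] of the control line (denominator);
#'   must share the SNP map of `hapsSel`.
#' @param cfg a [haploScanConfig()].
#' @return data.frame with snp_id, chrom, pos_bp, raw, z.
#' @export
xpehhScan <- function(hapsSel, hapsCtrl, cfg = haploScanConfig()) {
  if (!identical(hapsSel@map@snpId, hapsCtrl@map@snpId) ||
      !identical(hapsSel@map@posBp, hapsCtrl@map@posBp))
    stop("the two populations must share the same SNP map")
  H <- rbind(hapsSel@haplo, hapsCtrl@haplo)
  nA <- nrow(hapsSel@haplo)
  map <- hapsSel@map
  S <- ncol(H)
  raw <- rep(NA_real_, S)
  for (ch in unique(map@chrom)) {
    colsCh <- which(map@chrom == ch)
    dd <- .dedupRows(H[, colsCh, drop = FALSE])
    # per-pattern multiplicity within each population
    wA <- as.numeric(tabulate(dd$groupOf[seq_len(nA)], nrow(dd$H)))
    wB <- dd$weight - wA
    rowsA <- which(wA > 0); rowsB <- which(wB > 0)
    sets <- list(seq_len(nrow(dd$H)), rowsA, rowsB)
    wts <- list(dd$weight, wA[rowsA], wB[rowsB])
    posCh <- map@posBp[colsCh]
    hiCh <- length(colsCh)
    for (jl in seq_along(colsCh)) {
      iA <- iB <- 0
      ok <- TRUE
      for (dir in c(-1L, 1L)) {
        dec <- ehh_decay_cpp(dd$H, jl, 1L, hiCh, dir, sets, wts, 1L,
                             cfg$ehhCutoff)
        if (!dec$stopped ||
            !.sideGapsOk(posCh[dec$idx], posCh[jl], cfg$maxGapBp)) {
          ok <- FALSE; break
        }
        pp <- posCh[dec$idx]
        iA <- iA + .sideIntegral(pp, dec$ehh[, 2], posCh[jl])
        iB <- iB + .sideIntegral(pp, dec$ehh[, 3], posCh[jl])
      }
      if (ok && iA > 0 && iB > 0) raw[colsCh[jl]] <- log(iA / iB)
    }
  }
  keep <- !is.na(raw)
  z <- rep(NA_real_, S)
  z[keep] <- (raw[keep] - mean(raw[keep])) / stats::sd(raw[keep])
  data.frame(snp_id = map@snpId, chrom = map@chrom, pos_bp = map@posBp,
             raw = raw, z = z, stringsAsFactors = FALSE)[keep, ]
}

#' Window flagging of standardized haplotype-scan scores
#'
#' Averages standardized scores over the sliding-window grid shared
#' with the FST scan. In iHS mode a window is flagged when its mean
#' |iHS| exceeds the threshold and it holds at least `minSnps` scored
#' SNPs. In XP-EHH mode a window is flagged when its mean standardized
#' XP-EHH exceeds the threshold in *both* control-vs-selected
#' comparisons (with at least `minSnps` scored SNPs in each); strongly
#' negative windows --- extended homozygosity in the control line,
#' attributable to drift --- are never flagged.
#'
#' @param scores iHS mode: the [ihsScan()] data.frame. XP-EHH mode: a
#'   list of the two [xpehhScan()] data.frames.
#' @param map the [SnpMap] defining the window grid.
#' @param cfg a [haploScanConfig()].
#' @param mode "ihs" or "xpehh".
#' @return window data.frame with per-window means and a `flagged`
#'   column.
#' @export
windowFlagHaplo <- function(scores, map, cfg = haploScanConfig(),
                            mode = c("ihs", "xpehh")) {
  mode <- match.arg(mode)
  toVec <- function(df, col) {
    v <- rep(NA_real_, length(map@snpId))
    v[match(df$snp_id, map@snpId)] <- df[[col]]
    v
  }
  if (mode == "ihs") {
    w <- windowAverage(toVec(scores, "abs_z"), map, cfg)
    names(w)[names(w) == "mean_value"] <- "mean_abs_ihs"
    w$flagged <- w$eligible & !is.na(w$mean_abs_ihs) &
      w$mean_abs_ihs > cfg$threshold
    w
  } else {
    stopifnot(is.list(scores), length(scores) == 2L)
    w1 <- windowAverage(toVec(scores[[1]], "z"), map, cfg)
    w2 <- windowAverage(toVec(scores[[2]], "z"), map, cfg)
    w <- data.frame(chrom = w1$chrom, start = w1$start, end = w1$end,
                    n_snps_1 = w1$n_snps, n_snps_2 = w2$n_snps,
                    mean_xpehh_1 = w1$mean_value,
                    mean_xpehh_2 = w2$mean_value)
    w$flagged <- w1$eligible & w2$eligible &
      w$mean_xpehh_1 > cfg$threshold & w$mean_xpehh_2 > cfg$threshold
    w$flagged[is.na(w$flagged)] <- FALSE
    w
  }
}
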