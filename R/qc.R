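#' Quality-control configuration
#'
#' @param minSampleCallRate samples with call rate strictly below this
#'   are removed (default 0.90).
#' @param minSnpCallRate SNPs with call rate strictly below this are
#'   removed (default 0.95).
#' @param autosomes the configured autosome set; SNPs on other
#'   chromosomes are removed (default 1:29, a cattle-style autosome
#'   complement).
#' @param topK number of highest-r2 same-chromosome partners inspected
#'   per SNP by the misplaced-SNP detector (default 10).
#' @param flagDistanceBp distance beyond which a high-r2 partner earns
#'   a flag (default 10 Mb).
#' @return list of class `QcConfig`.
#' @export
qcConfig <- function(minSampleCallRate = 0.90, minSnpCallRate = 0.95,
                     autosomes = 1:29, topK = 10L,
                     flagDistanceBp = 10e6) {
  stopifnot(minSampleCallRate >= 0, minSampleCallRate <= 1,
            minSnpCallRate >= 0, minSnpCallRate <= 1,
            topK >= 1L, flagDistanceBp > 0)
  structure(list(minSampleCallRate = minSampleCallRate,
                 minSnpCallRate = minSnpCallRate,
                 autosomes = as.integer(autosomes),
                 topK = as.integer(topK),
                 flagDistanceBp = flagDistanceBp),
            class = "QcConfig")
}

.emptyReport <- function() {
  data.frame(id = character(0), type = character(0), reason = character(0),
              iteration = integer(0), flags = integer(0),
              stringsAsFactors = FALSE)
}

#' Remove low-call-rate samples
#'
#' Call rate is the fraction of non-missing SNP calls; samples strictly
#' below `minSampleCallRate` are removed (a sample exactly at the
#' threshold is kept).
#'
#' @param geno a [GenotypeData].
#' @param cfg a [qcConfig()].
#' @return list with `genotypes` (filtered) and `report` (data.frame
#'   with columns id, type, reason, iteration, flags).
#' @export
filterSamples <- function(geno, cfg = qcConfig()) {
  d <- geno@dosage
  if (nrow(d) == 0L) stop("no samples")
  callRate <- rowMeans(!is.na(d))
  drop <- callRate < cfg$minSampleCallRate
  if (all(drop)) stop("all samples fail the call-rate filter")
  report <- .emptyReport()
  if (any(drop))
    report <- data.frame(id = rownames(d)[drop], type = "sample",
                         reason = "call_rate", iteration = NA_integer_,
                         flags = NA_integer_, stringsAsFactors = FALSE)
  list(genotypes = GenotypeData(d[!drop, , drop = FALSE], geno@map),
       report = report)
}

#' Remove low-call-rate, non-autosomal, duplicated and all-line
#' monomorphic SNPs
#'
#' A SNP is removed when its call rate is strictly below
#' `minSnpCallRate`; when its chromosome is outside the configured
#' autosome set; when it shares (chrom, pos) with another SNP (all
#' members of a duplicate group are removed); or when it is monomorphic
#' (allele frequency 0 or 1, or no calls) within every line
#' simultaneously. A SNP monomorphic in some lines but polymorphic in
#' at least one is kept. Each removed SNP is reported once, with the
#' first applicable reason in the order above.
#'
#' @param geno a [GenotypeData].
#' @param lines a [LineAssignment] covering all samples.
#' @param cfg a [qcConfig()].
#' @return list with `genotypes` (filtered) and `report`.
#' @export
filterSnps <- function(geno, lines, cfg = qcConfig()) {
  d <- geno@dosage
  map <- geno@map
  missing <- setdiff(rownames(d), names(lines@line))
  if (length(missing))
    stop("samples without line assignment: ", paste(missing, collapse = ", "))
  reason <- rep(NA_character_, ncol(d))

  callRate <- colMeans(!is.na(d))
  reason[callRate < cfg$minSnpCallRate] <- "call_rate"

  offAuto <- !(map@chrom %in% cfg$autosomes)
  reason[is.na(reason) & offAuto] <- "non_autosomal"

  key <- paste(map@chrom, map@posBp)
  dup <- key %in% key[duplicated(key)]
  reason[is.na(reason) & dup] <- "duplicate_position"

  lineLabs <- unique(lines@line)
  monoAll <- rep(TRUE, ncol(d))
  for (l in lineLabs) {
    dl <- d[rownames(d) %in% names(lines@line)[lines@line == l], ,
            drop = FALSE]
    nCalled <- colSums(!is.na(dl))
    p <- colSums(dl, na.rm = TRUE) / (2 * nCalled)
    monoLine <- nCalled == 0L | p == 0 | p == 1
    monoAll <- monoAll & monoLine
  }
  reason[is.na(reason) & monoAll] <- "monomorphic_all_lines"

  drop <- !is.na(reason)
  report <- .emptyReport()
  if (any(drop))
    report <- data.frame(id = map@snpId[drop], type = "snp",
                         reason = reason[drop], iteration = NA_integer_,
                         flags = NA_integer_, stringsAsFactors = FALSE)
  list(genotypes = subsetSnps(geno, !drop), report = report)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Computed over complete pairs (both non-missing). Undefined (fewer
#' than two complete pairs, or zero variance in either vector) yields
#' `NA`; the misplaced-SNP detector ranks undefined r2 as if it were 0,
#' so it never enters a top-k partner list.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return squared correlation in \[0, 1\], or `NA` if undefined.
#' @export
genotypeR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Iterative r2-decay detection of misplaced SNPs
#'
#' SNPs whose strongest linkage disequilibrium partners lie implausibly
#' far away are likely mapped to the wrong position. Per iteration, for
#' each SNP under scrutiny: (1) its `topK` same-chromosome SNPs with the
#' highest genotype r2 (among SNPs not yet removed) are recorded, ties
#' broken by smaller physical distance then map order; (2) the SNP earns
#' one flag per partner at distance > `flagDistanceBp`; (3) on each
#' chromosome, all SNPs attaining that chromosome's maximum flag count
#' (provided it is >= 1) are removed; (4) the SNPs that were flagged but
#' not removed form the candidate list for the next iteration, and the
#' steps repeat on that list until it is empty. In iteration 1 every SNP
#' is under scrutiny. Chromosomes with fewer than `topK` + 1 SNPs use
#' all available partners.
#'
#' @param geno a [GenotypeData] (map sorted, which the class enforces).
#' @param cfg a [qcConfig()].
#' @return list with `removed` (character SNP ids), `report` (with the
#'   removal iteration and flag count per SNP) and `genotypes` (the
#'   input minus removed SNPs).
#' @export
detectMisplacedSnps <- function(geno, cfg = qcConfig()) {
  d <- geno@dosage
  map <- geno@map
  report <- .emptyReport()
  removedAll <- character(0)
  for (ch in unique(map@chrom)) {
    onChrom <- which(map@chrom == ch)
    active <- onChrom                      # not yet removed, this chromosome
    cand <- onChrom                        # under scrutiny this iteration
    iter <- 0L
    while (length(cand) > 0L) {
      iter <- iter + 1L
      if (length(active) < 2L) break
      r2 <- suppressWarnings(
        stats::cor(d[, active, drop = FALSE], d[, cand, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      r2[is.na(r2)] <- -Inf               # undefined never enters top-k
      flags <- integer(length(cand))
      for (jj in seq_along(cand)) {
        j <- cand[jj]
        self <- match(j, active)
        dist <- abs(map@posBp[active] - map@posBp[j])
        ord <- order(-r2[, jj], dist, seq_along(active))
        ord <- ord[ord != self]
        top <- ord[seq_len(min(cfg$topK, length(ord)))]
        top <- top[r2[top, jj] > -Inf]
        flags[jj] <- sum(dist[top] > cfg$flagDistanceBp)
      }
      mx <- max(flags)
      if (mx < 1L) break
      rem <- cand[flags == mx]
      report <- rbind(report, data.frame(
        id = map@snpId[rem], type = "snp", reason = "misplaced",
        iteration = iter, flags = mx, stringsAsFactors = FALSE))
      removedAll <- c(removedAll, map@snpId[rem])
      active <- setdiff(active, rem)
      cand <- setdiff(cand[flags >= 1L], rem)
    }
  }
  keep <- !(map@snpId %in% removedAll)
  list(removed = removedAll, report = report,
       genotypes = subsetSnps(geno, keep))
}

#' Run the full QC stage
#'
#' Fixed filter order: sample call rate, then SNP filters (call rate /
#' autosome / duplicate / monomorphic in all lines), then the iterative
#' misplaced-SNP detector. Each stage is idempotent on its own output.
#'
#' @param geno a [GenotypeData].
#' @param lines a [LineAssignment].
#' @param cfg a [qcConfig()].
#' @return list with `genotypes` (filtered), `lines` (restricted to the
#'   surviving samples) and `report` (all removals).
#' @export
runQc <- function(geno, lines, cfg = qcConfig()) {
  s1 <- filterSamples(geno, cfg)
  keepIds <- rownames(s1$genotypes@dosage)
  lines2 <- LineAssignment(lines@line[names(lines@line) %in% keepIds],
                           lines@control, lines@selected)
  s2 <- filterSnps(s1$genotypes, lines2, cfg)
  s3 <- detectMisplacedSnps(s2$genotypes, cfg)
  list(genotypes = s3$genotypes, lines = lines2,
       report = rbind(s1$report, s2$report, s3$report))
}
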