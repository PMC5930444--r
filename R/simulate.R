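#' Configuration for the forward-in-time line simulator
#'
#' Defines a Wright-Fisher forward simulation emulating a divergent
#' selection experiment: a founder population accumulates linkage
#' disequilibrium by drift during a burn-in of random mating with
#' recombination, is then split into one control line and one or more
#' directionally selected lines, and each selected line undergoes
#' truncation selection on an additive trait controlled by known QTL.
#'
#' The defaults describe such an experiment at desk scale: chromosomes
#' are physically compressed (12 Mb at ~5 cM/Mb rather than ~120 Mb at
#' 1 cM/Mb) so that their *genetic* length, which controls haplotype
#' structure, matches a real autosome, and line censuses keep the
#' control line at half the selected-line size so that per-line
#' effective sizes stay in the proportions of a real
#' divergent-selection herd under the same parent-retention fraction.
#'
#' @param seed integer seed governing all randomness of the run.
#' @param nChrom number of autosomes.
#' @param chromLengthBp chromosome length in bp.
#' @param nSnpsPerChrom SNPs simulated per chromosome (positions drawn
#'   uniformly, then sorted).
#' @param founderPopSize diploid size of the burn-in population.
#' @param burninGenerations generations of random mating before the split.
#' @param lineSizes named integer vector of diploid census sizes per
#'   line; names are the line labels.
#' @param selectedLabels labels of the directionally selected lines;
#'   the remaining label is the control line.
#' @param selectionGenerations generations of selection after the split.
#' @param qtl `data.frame(chrom, pos_bp, effect)` of trait loci, or
#'   `NULL` for a neutral trait. Each QTL is snapped to the nearest
#'   simulated SNP whose post-burn-in MAF falls within `qtlMafRange`,
#'   and its favored allele is the minor allele at split time; `effect`
#'   is the additive trait increment per favored-allele copy. A rare
#'   favored allele rests on a narrow haplotype background, so its rise
#'   leaves the hard-sweep footprint that haplotype scans target.
#' @param envSd standard deviation of the environmental (noise) trait
#'   component.
#' @param selectedFraction proportion of each line retained as parents
#'   every generation: the top fraction by trait in selected lines, a
#'   uniformly random fraction in the control line.
#' @param recombRate per-bp per-meiosis crossover probability
#'   (default 1e-8, i.e. 1 cM/Mb). Scaled-down genomes should preserve
#'   *genetic* chromosome length (in Morgan) by raising this rate.
#' @param qtlMafRange post-burn-in MAF interval from which the SNP a
#'   QTL snaps to is drawn (nearest such SNP to the requested
#'   position); when no SNP qualifies, the nearest polymorphic SNP is
#'   used and a warning recorded.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 2L,
                      chromLengthBp = 12e6,
                      nSnpsPerChrom = 3000L,
                      founderPopSize = 100L,
                      burninGenerations = 100L,
                      lineSizes = c(CTL = 150L, SEL1 = 300L, SEL2 = 300L),
                      selectedLabels = c("SEL1", "SEL2"),
                      selectionGenerations = 8L,
                      qtl = NULL,
                      envSd = 1,
                      selectedFraction = 0.2,
                      recombRate = 4e-7,
                      qtlMafRange = c(0.01, 0.03)) {
  if (is.null(names(lineSizes)) || any(!nzchar(names(lineSizes))))
    stop("lineSizes must be a named vector")
  if (!all(selectedLabels %in% names(lineSizes)))
    stop("selectedLabels must name entries of lineSizes")
  control <- setdiff(names(lineSizes), selectedLabels)
  if (length(control) != 1L)
    stop("exactly one line must remain as the control line")
  if (selectedFraction <= 0 || selectedFraction > 1)
    stop("selectedFraction must be in (0, 1]")
  if (any(lineSizes < 2L) || founderPopSize < 2L)
    stop("all population sizes must be >= 2")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    if (!all(c("chrom", "pos_bp", "effect") %in% colnames(qtl)))
      stop("qtl must have columns chrom, pos_bp, effect")
    if (any(qtl$chrom > nChrom) || any(qtl$pos_bp > chromLengthBp))
      stop("qtl positions must lie on a simulated chromosome")
  }
  structure(list(
    seed = as.integer(seed), nChrom = as.integer(nChrom),
    chromLengthBp = as.integer(chromLengthBp),
    nSnpsPerChrom = as.integer(nSnpsPerChrom),
    founderPopSize = as.integer(founderPopSize),
    burninGenerations = as.integer(burninGenerations),
    lineSizes = lineSizes, selectedLabels = selectedLabels,
    control = control,
    selectionGenerations = as.integer(selectionGenerations),
    qtl = qtl, envSd = envSd, selectedFraction = selectedFraction,
    recombRate = recombRate, qtlMafRange = qtlMafRange
  ), class = "SimConfig")
}

# Produce nOff diploid offspring from the parent individuals `parents`
# (indices into the diploid population whose haplotypes are rows of H).
# Each offspring draws two distinct parents; gametes recombine with
# Poisson crossovers (compiled kernel, R RNG stream).
.nextGeneration <- function(H, parents, nOff, chromIdx, posList,
                            recombRate, chromLen) {
  p1 <- integer(nOff); p2 <- integer(nOff)
  for (i in seq_len(nOff)) {
    pr <- if (length(parents) >= 2L) sample(parents, 2L) else
      rep(parents, 2L)
    p1[i] <- pr[1]; p2[i] <- pr[2]
  }
  chromFirst <- vapply(chromIdx, function(x) x[1], 0L)
  chromLast <- vapply(chromIdx, function(x) x[length(x)], 0L)
  make_offspring_cpp(H, p1, p2, chromFirst, chromLast,
                     as.numeric(unlist(posList, use.names = FALSE)),
                     recombRate, chromLen)
}

#' Simulate a control line and directionally selected lines
#'
#' Runs the generative model described in [simConfig()]: burn-in drift
#' builds realistic LD, the population is split into lines, and each
#' line evolves under truncation (selected lines) or random (control
#' line) parent retention for `selectionGenerations` discrete
#' generations. Generations are non-overlapping and mating is
#' hermaphroditic random pairing. The final generation is exported
#' phased.
#'
#' @param cfg a [simConfig()] object.
#' @return A list with elements `haplotypes` ([HaplotypeData]),
#'   `genotypes` ([GenotypeData], the collapsed dosages), `lines`
#'   ([LineAssignment]) and `truth` (list with the realized QTL table
#'   --- snapped position, favored allele, split-time and per-line final
#'   favored-allele frequencies --- plus any warnings and the config).
#' @export
simulateLines <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  S <- cfg$nChrom * cfg$nSnpsPerChrom
  posList <- lapply(seq_len(cfg$nChrom), function(c)
    sort(sample.int(cfg$chromLengthBp, cfg$nSnpsPerChrom)))
  chromIdx <- split(seq_len(S), rep(seq_len(cfg$nChrom),
                                    each = cfg$nSnpsPerChrom))
  pos <- unlist(posList, use.names = FALSE)
  chromVec <- rep(seq_len(cfg$nChrom), each = cfg$nSnpsPerChrom)
  map <- SnpMap(sprintf("snp%06d", seq_len(S)), chromVec, pos)

  # founder frequencies: U-shaped folded SFS, truncated to avoid fixation
  p0 <- stats::rbeta(S, 0.5, 0.5)
  p0 <- pmin(pmax(p0, 0.05), 0.95)
  N0 <- cfg$founderPopSize
  H <- matrix(stats::rbinom(2L * N0 * S, 1L,
                            rep(p0, each = 2L * N0)), 2L * N0, S)

  for (g in seq_len(cfg$burninGenerations))
    H <- .nextGeneration(H, seq_len(N0), N0, chromIdx, posList,
                         cfg$recombRate, cfg$chromLengthBp)

  warnings <- character(0)
  qtlTab <- NULL
  qtlCols <- integer(0)
  qtlFavored <- integer(0)  # favored allele code (0/1) per QTL
  if (!is.null(cfg$qtl) && nrow(cfg$qtl)) {
    pSplit <- colMeans(H)
    maf <- pmin(pSplit, 1 - pSplit)
    qtlCols <- integer(nrow(cfg$qtl))
    qtlFavored <- integer(nrow(cfg$qtl))
    for (q in seq_len(nrow(cfg$qtl))) {
      onChrom <- chromIdx[[cfg$qtl$chrom[q]]]
      ok <- onChrom[maf[onChrom] >= cfg$qtlMafRange[1] &
                    maf[onChrom] <= cfg$qtlMafRange[2]]
      if (length(ok) == 0L) {
        ok <- onChrom[maf[onChrom] > 0]
        warnings <- c(warnings, sprintf(
          "QTL %d: no SNP with MAF in [%.2f, %.2f] on chromosome %d; using nearest polymorphic SNP",
          q, cfg$qtlMafRange[1], cfg$qtlMafRange[2], cfg$qtl$chrom[q]))
      }
      if (length(ok) == 0L) {
        warnings <- c(warnings, sprintf(
          "QTL %d: chromosome %d is monomorphic; sweep cannot proceed",
          q, cfg$qtl$chrom[q]))
        ok <- onChrom
      }
      qtlCols[q] <- ok[which.min(abs(pos[ok] - cfg$qtl$pos_bp[q]))]
      # favored allele = minor allele at split time
      qtlFavored[q] <- if (pSplit[qtlCols[q]] <= 0.5) 1L else 0L
      if (maf[qtlCols[q]] == 0)
        warnings <- c(warnings, sprintf(
          "QTL %d is monomorphic at split time; sweep cannot proceed", q))
    }
    qtlTab <- data.frame(
      chrom = cfg$qtl$chrom, pos_bp = pos[qtlCols],
      snp_id = map@snpId[qtlCols],
      favored_allele = ifelse(qtlFavored == 1L, "B", "A"),
      effect = cfg$qtl$effect,
      freq_split = ifelse(qtlFavored == 1L, pSplit[qtlCols],
                          1 - pSplit[qtlCols]),
      stringsAsFactors = FALSE)
  }

  traitOf <- function(Hl) {
    n <- nrow(Hl) / 2L
    tr <- stats::rnorm(n, 0, cfg$envSd)
    for (q in seq_along(qtlCols)) {
      a <- Hl[, qtlCols[q]]
      dos <- a[seq(1L, 2L * n, 2L)] + a[seq(2L, 2L * n, 2L)]
      if (qtlFavored[q] == 0L) dos <- 2L - dos
      tr <- tr + cfg$qtl$effect[q] * dos
    }
    tr
  }

  labels <- names(cfg$lineSizes)
  lineH <- vector("list", length(labels)); names(lineH) <- labels
  for (l in labels)  # line founders: one random-mating generation off burn-in
    lineH[[l]] <- .nextGeneration(H, seq_len(N0), cfg$lineSizes[[l]],
                                  chromIdx, posList, cfg$recombRate,
                                  cfg$chromLengthBp)

  for (g in seq_len(cfg$selectionGenerations)) {
    for (l in labels) {
      Hl <- lineH[[l]]
      n <- nrow(Hl) / 2L
      nPar <- max(2L, round(cfg$selectedFraction * n))
      if (l %in% cfg$selectedLabels) {
        parents <- order(traitOf(Hl), decreasing = TRUE)[seq_len(nPar)]
      } else {
        parents <- sample.int(n, nPar)
      }
      lineH[[l]] <- .nextGeneration(Hl, parents, n, chromIdx, posList,
                                    cfg$recombRate, cfg$chromLengthBp)
    }
  }

  haplo <- do.call(rbind, lineH)
  ids <- unlist(lapply(labels, function(l)
    sprintf("%s_%03d", l, seq_len(cfg$lineSizes[[l]]))), use.names = FALSE)
  lines <- LineAssignment(
    stats::setNames(rep(labels, times = cfg$lineSizes[labels]), ids),
    control = cfg$control, selected = cfg$selectedLabels)
  haps <- HaplotypeData(haplo, ids, map)

  if (!is.null(qtlTab)) {
    for (l in labels) {
      f <- colMeans(lineH[[l]][, qtlCols, drop = FALSE])
      f <- ifelse(qtlFavored == 1L, f, 1 - f)
      qtlTab[[paste0("freq_final_", l)]] <- f
    }
  }
  list(haplotypes = haps, genotypes = asGenotypes(haps), lines = lines,
       truth = list(qtl = qtlTab, warnings = warnings, config = cfg))
}

#' Inject missing genotype calls
#'
#' Sets dosage entries to missing independently, with a global per-entry
#' rate and optional per-sample overrides --- the ground truth for
#' call-rate QC tests.
#'
#' @param geno a [GenotypeData].
#' @param snpRate baseline per-entry missingness probability.
#' @param sampleRates optional named vector of per-sample rates that
#'   override `snpRate` for those samples.
#' @param seed integer seed.
#' @return A [GenotypeData] with injected missing calls.
#' @export
injectMissingness <- function(geno, snpRate = 0, sampleRates = NULL,
                              seed = 1L) {
  if (snpRate < 0 || snpRate > 1 || any(sampleRates < 0) ||
      any(sampleRates > 1))
    stop("rates must be in [0, 1]")
  set.seed(seed)
  d <- geno@dosage
  rates <- rep(snpRate, nrow(d))
  if (!is.null(sampleRates)) {
    i <- match(names(sampleRates), rownames(d))
    if (anyNA(i)) stop("sampleRates names must be sample ids")
    rates[i] <- sampleRates
  }
  mask <- matrix(stats::runif(length(d)), nrow(d)) < rates
  d[mask] <- NA_integer_
  GenotypeData(d, geno@map)
}

#' Relocate SNPs to distant positions on their chromosome
#'
#' Moves `n` randomly chosen SNPs at least `minShiftBp` away on the same
#' chromosome (genotype columns follow their SNPs; the map is re-sorted),
#' creating ground truth for the misplaced-SNP detector.
#'
#' @param geno a [GenotypeData].
#' @param n number of SNPs to relocate.
#' @param minShiftBp minimum displacement in bp; must exceed the
#'   detector's flag distance for the truth to be detectable.
#' @param seed integer seed.
#' @return list with `genotypes` (relocated [GenotypeData]) and `truth`
#'   (data.frame of snp_id, chrom, old position, new position).
#' @export
relocateSnps <- function(geno, n, minShiftBp, seed = 1L) {
  set.seed(seed)
  map <- geno@map
  if (n == 0L)
    return(list(genotypes = geno,
                truth = data.frame(snp_id = character(0), chrom = integer(0),
                                   old_pos = integer(0), new_pos = integer(0))))
  pick <- sample.int(length(map@snpId), n)
  newPos <- map@posBp
  for (j in pick) {
    L <- max(map@posBp[map@chrom == map@chrom[j]])
    lo <- map@posBp[j] - minShiftBp          # last valid position left
    hi <- map@posBp[j] + minShiftBp          # first valid position right
    nValid <- max(0L, lo) + max(0L, L - hi + 1L)
    if (nValid <= 0L)
      stop(sprintf("chromosome %d is too short for a %d bp shift",
                   map@chrom[j], minShiftBp))
    taken <- newPos[map@chrom == map@chrom[j]]
    for (try in 1:10000) {
      p <- sample.int(L, 1L)
      if (abs(p - map@posBp[j]) >= minShiftBp && !(p %in% taken)) break
      p <- NA_integer_
    }
    if (is.na(p)) stop("could not find a free relocated position")
    newPos[j] <- p
  }
  truth <- data.frame(snp_id = map@snpId[pick], chrom = map@chrom[pick],
                      old_pos = map@posBp[pick], new_pos = newPos[pick],
                      stringsAsFactors = FALSE)
  ord <- order(map@chrom, newPos)
  newMap <- SnpMap(map@snpId[ord], map@chrom[ord], newPos[ord],
                   map@alleleA[ord], map@alleleB[ord])
  list(genotypes = GenotypeData(geno@dosage[, ord, drop = FALSE], newMap),
       truth = truth)
}
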