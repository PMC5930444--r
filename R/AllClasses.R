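#' @import methods
NULL

#' SNP map: per-SNP chromosome, position and allele labels
#'
#' Ordered table of biallelic autosomal SNPs. Positions are 1-based base
#' pairs (VCF/MAP convention); rows must be sorted by chromosome then
#' position. `alleleB` is the counted allele: dosages in a
#' [GenotypeData] count copies of `alleleB`, and haplotype code 1 in a
#' [HaplotypeData] is `alleleB`.
#'
#' @slot snpId character vector of SNP identifiers (unique).
#' @slot chrom integer autosome numbers.
#' @slot posBp integer 1-based physical positions (>= 1).
#' @slot alleleA character labels of the uncounted allele.
#' @slot alleleB character labels of the counted allele.
#'
#' @examples
#' SnpMap(snpId = c("s1", "s2"), chrom = c(1L, 1L),
#'        posBp = c(100L, 200L), alleleA = c("A", "C"),
#'        alleleB = c("G", "T"))
#' @export
setClass("SnpMap", representation(
  snpId = "character",
  chrom = "integer",
  posBp = "integer",
  alleleA = "character",
  alleleB = "character"
))

setValidity("SnpMap", function(object) {
  n <- length(object@snpId)
  if (length(object@chrom) != n || length(object@posBp) != n ||
      length(object@alleleA) != n || length(object@alleleB) != n)
    return("all slots must have equal length")
  if (n == 0L) return(TRUE)
  if (anyNA(object@chrom) || anyNA(object@posBp))
    return("chrom/posBp must not contain NA")
  if (any(object@chrom < 1L)) return("chrom must be positive")
  if (any(object@posBp < 1L)) return("posBp must be >= 1 (1-based)")
  if (anyDuplicated(object@snpId)) return("snpId must be unique")
  o <- order(object@chrom, object@posBp)
  if (!identical(o, seq_len(n)))
    return("SNPs must be sorted by (chrom, posBp)")
  TRUE
})

#' Construct a SnpMap
#'
#' @param snpId,chrom,posBp,alleleA,alleleB see [SnpMap-class].
#' @return A [SnpMap] object.
#' @export
SnpMap <- function(snpId, chrom, posBp,
                   alleleA = rep("A", length(snpId)),
                   alleleB = rep("B", length(snpId))) {
  new("SnpMap", snpId = as.character(snpId), chrom = as.integer(chrom),
      posBp = as.integer(posBp), alleleA = as.character(alleleA),
      alleleB = as.character(alleleB))
}

#' Unphased genotype dosages aligned to a SnpMap
#'
#' Samples x SNPs matrix of counted-allele (alleleB) dosages in
#' \{0, 1, 2\}, with `NA` marking missing calls. Row names are sample
#' identifiers.
#'
#' @slot dosage integer matrix, samples in rows, SNPs in columns.
#' @slot map the aligned [SnpMap].
#' @export
setClass("GenotypeData", representation(
  dosage = "matrix",
  map = "SnpMap"
))

setValidity("GenotypeData", function(object) {
  d <- object@dosage
  if (!is.numeric(d)) return("dosage must be a numeric/integer matrix")
  if (ncol(d) != length(object@map@snpId))
    return("dosage column count must equal SnpMap length")
  if (is.null(rownames(d))) return("dosage must carry sample ids as rownames")
  if (anyDuplicated(rownames(d))) return("sample ids must be unique")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  TRUE
})

#' Construct a GenotypeData
#'
#' @param dosage samples x SNPs matrix with rownames = sample ids.
#' @param map the aligned [SnpMap].
#' @return A [GenotypeData] object.
#' @export
GenotypeData <- function(dosage, map) {
  storage.mode(dosage) <- "integer"
  new("GenotypeData", dosage = dosage, map = map)
}

#' Phased haplotypes aligned to a SnpMap
#'
#' (2 x samples) x SNPs binary matrix; rows 2i - 1 and 2i are the two
#' haplotypes of sample i (in `sampleIds` order). Code 1 is the counted
#' allele (alleleB of the map). No missing values are allowed: haplotype
#' statistics require complete phased data.
#'
#' @slot haplo integer matrix of 0/1, 2 rows per sample.
#' @slot sampleIds character vector of sample identifiers.
#' @slot map the aligned [SnpMap].
#' @export
setClass("HaplotypeData", representation(
  haplo = "matrix",
  sampleIds = "character",
  map = "SnpMap"
))

setValidity("HaplotypeData", function(object) {
  h <- object@haplo
  if (anyNA(h)) return("haplotypes must not contain missing values")
  if (nrow(h) != 2L * length(object@sampleIds))
    return("haplotype row count must be twice the number of samples")
  if (ncol(h) != length(object@map@snpId))
    return("haplotype column count must equal SnpMap length")
  if (length(h) && !all(h %in% c(0L, 1L)))
    return("haplotype values must be 0 or 1")
  if (anyDuplicated(object@sampleIds)) return("sample ids must be unique")
  TRUE
})

#' Construct a HaplotypeData
#'
#' @param haplo (2 x samples) x SNPs binary matrix.
#' @param sampleIds character sample identifiers (haplotype rows
#'   2i - 1, 2i belong to `sampleIds[i]`).
#' @param map the aligned [SnpMap].
#' @return A [HaplotypeData] object.
#' @export
HaplotypeData <- function(haplo, sampleIds, map) {
  storage.mode(haplo) <- "integer"
  new("HaplotypeData", haplo = haplo, sampleIds = as.character(sampleIds),
      map = map)
}

#' Sample-to-line assignment
#'
#' Maps every genotyped sample to a selection line and designates
#' exactly one control line plus one or more selected lines.
#'
#' @slot line named character vector: names are sample ids, values line
#'   labels.
#' @slot control label of the control (stabilizing-selection) line.
#' @slot selected labels of the directionally selected lines.
#' @export
setClass("LineAssignment", representation(
  line = "character",
  control = "character",
  selected = "character"
))

setValidity("LineAssignment", function(object) {
  if (is.null(names(object@line)) || any(!nzchar(names(object@line))))
    return("line must be a named vector (sample ids as names)")
  if (anyDuplicated(names(object@line))) return("duplicate sample ids")
  if (length(object@control) != 1L) return("exactly one control line required")
  if (length(object@selected) < 1L) return("at least one selected line required")
  labs <- c(object@control, object@selected)
  if (anyDuplicated(labs)) return("control/selected labels must be distinct")
  if (!all(object@line %in% labs))
    return("every sample's line must be a declared control or selected label")
  TRUE
})

#' Construct a LineAssignment
#'
#' @param line named character vector mapping sample id to line label.
#' @param control the control-line label.
#' @param selected character vector of selected-line labels.
#' @return A [LineAssignment] object.
#' @export
LineAssignment <- function(line, control, selected) {
  new("LineAssignment", line = line, control = as.character(control),
      selected = as.character(selected))
}

setMethod("show", "SnpMap", function(object) {
  n <- length(object@snpId)
  cat("SnpMap with", n, "SNPs on",
      length(unique(object@chrom)), "chromosome(s)\n")
  if (n) {
    k <- min(n, 4L)
    cat("  head:", paste0(object@snpId[seq_len(k)], " (chr",
        object@chrom[seq_len(k)], ":", object@posBp[seq_len(k)], ")",
        collapse = ", "), if (n > k) "..." else "", "\n")
  }
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "SNPs;",
      sum(is.na(object@dosage)), "missing calls\n")
})

setMethod("show", "HaplotypeData", function(object) {
  cat("HaplotypeData:", length(object@sampleIds), "samples (",
      nrow(object@haplo), "haplotypes ) x", ncol(object@haplo), "SNPs\n")
})

setMethod("show", "LineAssignment", function(object) {
  tab <- table(object@line)
  cat("LineAssignment:", length(object@line), "samples in",
      length(tab), "lines\n")
  cat("  control:", object@control, "; selected:",
      paste(object@selected, collapse = ", "), "\n")
  for (l in names(tab)) cat("  ", l, ": ", tab[[l]], " samples\n", sep = "")
})
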