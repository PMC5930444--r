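#' @rdname accessors
#' @name accessors
#' @title Accessors for sweepscan containers
#'
#' @description Read-only access to the slots of [SnpMap],
#' [GenotypeData], [HaplotypeData] and [LineAssignment]; plus
#' `asGenotypes()` which collapses phased haplotype pairs to dosages.
#'
#' @param x a sweepscan container object.
#' @return the corresponding slot value (see individual generics).
NULL

#' @rdname accessors
#' @export
setGeneric("snpId", function(x) standardGeneric("snpId"))
#' @rdname accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname accessors
#' @export
setGeneric("posBp", function(x) standardGeneric("posBp"))
#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("lineOf", function(x) standardGeneric("lineOf"))
#' @rdname accessors
#' @export
setGeneric("controlLine", function(x) standardGeneric("controlLine"))
#' @rdname accessors
#' @export
setGeneric("selectedLines", function(x) standardGeneric("selectedLines"))
#' @rdname accessors
#' @export
setGeneric("asGenotypes", function(x) standardGeneric("asGenotypes"))

#' @rdname accessors
setMethod("snpId", "SnpMap", function(x) x@snpId)
#' @rdname accessors
setMethod("chrom", "SnpMap", function(x) x@chrom)
#' @rdname accessors
setMethod("posBp", "SnpMap", function(x) x@posBp)
#' @rdname accessors
setMethod("alleles", "SnpMap", function(x)
  data.frame(snp_id = x@snpId, allele_a = x@alleleA, allele_b = x@alleleB,
             stringsAsFactors = FALSE))
#' @rdname accessors
setMethod("nSnps", "SnpMap", function(x) length(x@snpId))

#' @rdname accessors
setMethod("snpMap", "GenotypeData", function(x) x@map)
#' @rdname accessors
setMethod("dosages", "GenotypeData", function(x) x@dosage)
#' @rdname accessors
setMethod("sampleIds", "GenotypeData", function(x) rownames(x@dosage))
#' @rdname accessors
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosage))
#' @rdname accessors
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosage))

#' @rdname accessors
setMethod("snpMap", "HaplotypeData", function(x) x@map)
#' @rdname accessors
setMethod("haplotypes", "HaplotypeData", function(x) x@haplo)
#' @rdname accessors
setMethod("sampleIds", "HaplotypeData", function(x) x@sampleIds)
#' @rdname accessors
setMethod("nSnps", "HaplotypeData", function(x) ncol(x@haplo))
#' @rdname accessors
setMethod("nSamples", "HaplotypeData", function(x) length(x@sampleIds))

#' @rdname accessors
setMethod("lineOf", "LineAssignment", function(x) x@line)
#' @rdname accessors
setMethod("controlLine", "LineAssignment", function(x) x@control)
#' @rdname accessors
setMethod("selectedLines", "LineAssignment", function(x) x@selected)
#' @rdname accessors
setMethod("sampleIds", "LineAssignment", function(x) names(x@line))

#' @rdname accessors
setMethod("asGenotypes", "HaplotypeData", function(x) {
  h <- x@haplo
  n <- length(x@sampleIds)
  d <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(d) <- x@sampleIds
  GenotypeData(d, x@map)
})

# Subset a genotype/haplotype object to SNP columns `j` (logical or index),
# keeping the map aligned. Internal.
subsetSnps <- function(x, j) {
  if (is(x, "GenotypeData")) {
    GenotypeData(x@dosage[, j, drop = FALSE], subsetMap(x@map, j))
  } else if (is(x, "HaplotypeData")) {
    HaplotypeData(x@haplo[, j, drop = FALSE], x@sampleIds, subsetMap(x@map, j))
  } else stop("unsupported class")
}

subsetMap <- function(map, j) {
  SnpMap(map@snpId[j], map@chrom[j], map@posBp[j],
         map@alleleA[j], map@alleleB[j])
}
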