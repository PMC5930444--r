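#' Read PLINK text PED/MAP genotypes
#'
#' Parses whitespace-delimited PLINK text files: a PED file with six
#' leading columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele columns per SNP, and a four-column MAP file
#' (chromosome, SNP id, genetic position, bp position). "0" is the
#' missing-allele code.
#'
#' The counted allele (alleleB) of each SNP is the less frequent
#' observed allele at load time; ties are broken towards the
#' lexicographically larger label, so the coding is deterministic and
#' independent of sample order. Dosage is the count of alleleB copies;
#' a "0 0" genotype becomes `NA`.
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the MAP file.
#' @return A [GenotypeData] (SNPs sorted by chromosome and position).
#' @export
readPlinkText <- function(pedPath, mapPath) {
  mp <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) != 4L)
    stop("MAP file must have 4 columns (chrom, id, cM, bp)")
  nsnp <- nrow(mp)
  ped <- readLines(pedPath)
  ped <- ped[nzchar(trimws(ped))]
  fields <- strsplit(trimws(ped), "[ \t]+")
  want <- 6L + 2L * nsnp
  bad <- which(vapply(fields, length, 1L) != want)
  if (length(bad))
    stop(sprintf("PED row %d has %d fields; expected %d for %d SNPs",
                 bad[1], length(fields[[bad[1]]]), want, nsnp))
  n <- length(fields)
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  ids <- m[, 2L]
  a1 <- m[, 6L + 2L * seq_len(nsnp) - 1L, drop = FALSE]
  a2 <- m[, 6L + 2L * seq_len(nsnp), drop = FALSE]
  dosage <- matrix(NA_integer_, n, nsnp)
  alleleA <- alleleB <- character(nsnp)
  for (j in seq_len(nsnp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    al <- sort(unique(obs))
    if (length(al) > 2L)
      stop(sprintf("SNP '%s' has more than 2 observed alleles: %s",
                   mp[j, 2L], paste(al, collapse = ",")))
    if (length(al) == 0L) al <- c("A", "B")   # all missing: placeholder labels
    if (length(al) == 1L) {
      # monomorphic: counted allele is the (absent) other label
      alleleA[j] <- al; alleleB[j] <- al
      b <- NA_character_  # nothing counted; dosage 0 where called
      dosage[, j] <- ifelse(x1 == "0" | x2 == "0", NA_integer_, 0L)
      next
    }
    cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
    # counted allele: less frequent; tie -> lexicographically larger (al[2])
    b <- if (cnt[1] < cnt[2]) al[1] else al[2]
    a <- setdiff(al, b)
    alleleA[j] <- a; alleleB[j] <- b
    dosage[, j] <- ifelse(x1 == "0" | x2 == "0", NA_integer_,
                          (x1 == b) + (x2 == b))
  }
  rownames(dosage) <- ids
  ord <- order(as.integer(mp[, 1L]), as.integer(mp[, 4L]))
  map <- SnpMap(mp[ord, 2L], as.integer(mp[ord, 1L]), as.integer(mp[ord, 4L]),
                alleleA[ord], alleleB[ord])
  GenotypeData(dosage[, ord, drop = FALSE], map)
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [readPlinkText()]: dosage 0/1/2 become the allele pairs
#' A A / A B / B B (labels from the map) and `NA` becomes "0 0". Note
#' that [readPlinkText()] recodes the counted allele as the observed
#' minor allele, so a round trip reproduces dosages exactly only when
#' alleleB is the minor (or tie-lexicographically-larger) allele; the
#' genotypes themselves always round-trip exactly.
#'
#' @param geno a [GenotypeData].
#' @param pedPath,mapPath output paths.
#' @return invisibly, the input object.
#' @export
writePlinkText <- function(geno, pedPath, mapPath) {
  map <- geno@map
  utils::write.table(
    data.frame(map@chrom, map@snpId, 0, map@posBp),
    mapPath, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  d <- geno@dosage
  n <- nrow(d)
  a <- map@alleleA; b <- map@alleleB
  lines <- character(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    g1 <- ifelse(is.na(di), "0", ifelse(di >= 1L, b, a))
    g2 <- ifelse(is.na(di), "0", ifelse(di == 2L, b, a))
    lines[i] <- paste(rownames(d)[i], rownames(d)[i], 0, 0, 0, -9,
                      paste(rbind(g1, g2), collapse = " "))
  }
  writeLines(lines, pedPath)
  invisible(geno)
}

#' Read a phased VCF into a HaplotypeData
#'
#' Reads a VCF (v4.x) of biallelic SNPs with fully phased GT fields.
#' REF maps to haplotype code 0 and ALT to code 1, so alleleB = ALT.
#' Haplotype rows follow the VCF sample order.
#'
#' @param vcfPath path to a (plain-text or gzipped) VCF.
#' @return A [HaplotypeData].
#' @export
readPhasedVcf <- function(vcfPath) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop(sprintf("multiallelic record at %s:%s", fix[multi, "CHROM"][1],
                 fix[multi, "POS"][1]))
  gt <- v@gt[, -1, drop = FALSE]
  ids <- colnames(gt)
  # strip FORMAT subfields beyond GT
  gt <- sub(":.*$", "", gt)
  missing <- gt %in% c(".", "./.", ".|.") | is.na(gt)
  if (any(missing)) {
    i <- which(missing, arr.ind = TRUE)[1, 1]
    stop(sprintf("missing GT at %s:%s", fix[i, "CHROM"], fix[i, "POS"]))
  }
  unph <- grepl("/", gt, fixed = TRUE)
  if (any(unph)) {
    i <- which(matrix(unph, nrow = nrow(gt)), arr.ind = TRUE)[1, 1]
    stop(sprintf("unphased genotype at %s:%s", fix[i, "CHROM"], fix[i, "POS"]))
  }
  if (!all(gt %in% c("0|0", "0|1", "1|0", "1|1")))
    stop("GT fields must be phased biallelic (0|0, 0|1, 1|0, 1|1)")
  nsnp <- nrow(gt); n <- length(ids)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nsnp)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nsnp)
  haplo <- matrix(0L, 2L * n, nsnp)
  haplo[seq(1L, 2L * n, 2L), ] <- t(h1)
  haplo[seq(2L, 2L * n, 2L), ] <- t(h2)
  chromN <- suppressWarnings(as.integer(fix[, "CHROM"]))
  if (anyNA(chromN))
    stop("non-numeric chromosome names are not supported")
  snpid <- fix[, "ID"]
  if (any(is.na(snpid) | snpid == "."))
    snpid <- paste0("chr", fix[, "CHROM"], "_", fix[, "POS"])
  map <- SnpMap(snpid, chromN, as.integer(fix[, "POS"]),
                fix[, "REF"], alt)
  ord <- order(map@chrom, map@posBp)
  HaplotypeData(haplo[, ord, drop = FALSE], ids, subsetMap(map, ord))
}

#' Write a HaplotypeData as a phased VCF
#'
#' Emits a minimal plain-text VCFv4.2 with phased GT fields; code 0 is
#' written as REF (alleleA) and code 1 as ALT (alleleB).
#'
#' @param haps a [HaplotypeData].
#' @param vcfPath output path.
#' @return invisibly, the input object.
#' @export
writePhasedVcf <- function(haps, vcfPath) {
  map <- haps@map
  n <- length(haps@sampleIds)
  h1 <- haps@haplo[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- haps@haplo[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(h1))
  body <- paste(map@chrom, map@posBp, map@snpId, map@alleleA, map@alleleB,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", haps@sampleIds), collapse = "\t"))
  writeLines(c(hdr, body), vcfPath)
  invisible(haps)
}

#' Read / write a sample-to-line assignment table
#'
#' TSV with a header and columns `sample_id` and `line`.
#'
#' @param path TSV path.
#' @param control control-line label (must occur in the table).
#' @param selected selected-line labels; defaults to all non-control
#'   labels present.
#' @return [readLineAssignment()]: a [LineAssignment];
#'   [writeLineAssignment()]: invisibly, the input object.
#' @export
readLineAssignment <- function(path, control, selected = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "line") %in% colnames(tb)))
    stop("line TSV must have columns 'sample_id' and 'line'")
  line <- stats::setNames(as.character(tb$line), as.character(tb$sample_id))
  if (is.null(selected)) selected <- setdiff(unique(line), control)
  LineAssignment(line, control, selected)
}

#' @rdname readLineAssignment
#' @param lines a [LineAssignment] (for writing).
#' @export
writeLineAssignment <- function(lines, path) {
  utils::write.table(
    data.frame(sample_id = names(lines@line), line = unname(lines@line)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lines)
}

#' Per-SNP allele frequencies in a sample subset
#'
#' @param geno a [GenotypeData].
#' @param subset sample ids to use (default: all samples).
#' @return data.frame with columns `snp_id`, `n_called` (diploids with a
#'   call), `p_b` (frequency of the counted allele; `NA` when no sample
#'   is called) and `maf`.
#' @export
alleleFrequencies <- function(geno, subset = sampleIds(geno)) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  unknown <- setdiff(subset, rownames(geno@dosage))
  if (length(unknown))
    stop("unknown sample id(s) in subset: ", paste(unknown, collapse = ", "))
  d <- geno@dosage[subset, , drop = FALSE]
  nCalled <- colSums(!is.na(d))
  pB <- colSums(d, na.rm = TRUE) / (2 * nCalled)
  pB[nCalled == 0L] <- NA_real_
  data.frame(snp_id = geno@map@snpId, n_called = nCalled, p_b = pB,
             maf = pmin(pB, 1 - pB), row.names = NULL,
             stringsAsFactors = FALSE)
}
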