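#' Merge flagged windows into candidate regions
#'
#' Flagged windows on the same chromosome that overlap or exactly abut
#' (end == next start) are combined into one region spanning the
#' minimum start to the maximum end. Merging is idempotent and
#' independent of input order.
#'
#' @param windows a flagged window data.frame (columns chrom, start,
#'   end in half-open bp coordinates); typically the `flagged` subset
#'   of a scan, or a window table with a logical `flagged`/`candidate`
#'   column, which is honoured if present.
#' @param test label of the contributing test (e.g. "FST", "XPEHH",
#'   "IHS").
#' @param valueCol optional column whose per-window maximum is reported
#'   as the region's peak value.
#' @return data.frame with chrom, start, end, test, n_windows,
#'   peak_value.
#' @export
mergeWindows <- function(windows, test = "TEST", valueCol = NULL) {
  flagCol <- intersect(c("flagged", "candidate"), colnames(windows))
  if (length(flagCol))
    windows <- windows[windows[[flagCol[1]]], , drop = FALSE]
  if (!nrow(windows))
    return(data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0), test = character(0),
                      n_windows = integer(0), peak_value = numeric(0)))
  # half-open [start, end) bp -> closed 1-based IRanges; reduce() merges
  # overlapping and abutting ranges
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(windows$chrom),
    ranges = IRanges::IRanges(start = windows$start + 1L,
                              end = windows$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  nWin <- tabulate(S4Vectors::subjectHits(ov), length(red))
  peak <- rep(NA_real_, length(red))
  if (!is.null(valueCol) && valueCol %in% colnames(windows)) {
    v <- windows[[valueCol]][S4Vectors::queryHits(ov)]
    peak <- vapply(split(v, S4Vectors::subjectHits(ov)), max, 0)[
      as.character(seq_along(red))]
  }
  out <- data.frame(
    chrom = as.integer(as.character(GenomicRanges::seqnames(red))),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    test = test,
    n_windows = nWin,
    peak_value = unname(peak),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Consensus regions supported by at least two tests
#'
#' Computes the maximal genomic intervals covered by the regions of at
#' least two distinct tests; the reported interval is the intersection
#' footprint (every base is inside >= 2 per-test regions), so consensus
#' coordinates are conservative. Each consensus region lists all tests
#' whose regions overlap it.
#'
#' @param regionsByTest named list of [mergeWindows()]-style region
#'   data.frames, one per test.
#' @return data.frame with chrom, start, end (half-open bp), tests
#'   (comma-separated) and n_tests.
#' @export
crossTestConsensus <- function(regionsByTest) {
  regionsByTest <- regionsByTest[vapply(regionsByTest, nrow, 0L) > 0]
  empty <- data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0), tests = character(0),
                      n_tests = integer(0))
  if (length(regionsByTest) < 2L) return(empty)
  grl <- lapply(names(regionsByTest), function(tn) {
    r <- regionsByTest[[tn]]
    GenomicRanges::GRanges(as.character(r$chrom),
                           IRanges::IRanges(r$start + 1L, r$end),
                           test = tn)
  })
  all <- suppressWarnings(do.call(c, grl))  # per-test seqlevels may differ
  cov <- GenomicRanges::coverage(all)
  sl <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L,
                                              rangesOnly = TRUE))
  if (!length(sl)) return(empty)
  ov <- GenomicRanges::findOverlaps(sl, all)
  tests <- vapply(seq_along(sl), function(i) {
    tn <- sort(unique(all$test[S4Vectors::subjectHits(ov)[
      S4Vectors::queryHits(ov) == i]]))
    paste(tn, collapse = ",")
  }, "")
  nT <- lengths(strsplit(tests, ","))
  out <- data.frame(
    chrom = as.integer(as.character(GenomicRanges::seqnames(sl))),
    start = GenomicRanges::start(sl) - 1L,
    end = GenomicRanges::end(sl),
    tests = tests, n_tests = nT, stringsAsFactors = FALSE)
  # only slices genuinely supported by >= 2 *distinct* tests qualify
  out <- out[out$n_tests >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}

#' Read a BED interval file
#'
#' Minimal BED3+/BED4 parser (chrom, 0-based start, end, optional
#' name); malformed lines raise an error naming the line number.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end, name.
#' @export
readBed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^(track|browser|#)", ln)]
  out <- vector("list", length(ln))
  for (i in seq_along(ln)) {
    if (!nzchar(trimws(ln[i]))) next
    f <- strsplit(trimws(ln[i]), "[ \t]+")[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("malformed BED line %d: bad interval [%s, %s)",
                   i, f[2], f[3]))
    out[[i]] <- data.frame(chrom = f[1], start = s, end = e,
                           name = if (length(f) >= 4L) f[4] else
                             sprintf("feature_%d", i),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0),
                                      name = character(0))
  res
}

#' Annotate regions with overlapping features
#'
#' Interval-overlap join of candidate regions against a user feature
#' set (e.g. genes or QTL intervals from a BED file). Both sides use
#' half-open coordinates, so a feature that merely abuts a region
#' boundary is not a hit.
#'
#' @param regions region data.frame (chrom, start, end half-open bp).
#' @param features either a BED file path or a data.frame as returned
#'   by [readBed()] (chrom may be "chr1"-style or plain numbers).
#' @return data.frame with one row per (region, overlapping feature):
#'   region coordinates, feature name and interval, overlap length bp.
#' @export
annotateRegions <- function(regions, features) {
  if (is.character(features)) features <- readBed(features)
  hit0 <- data.frame(chrom = integer(0), region_start = numeric(0),
                     region_end = numeric(0), feature = character(0),
                     feature_start = numeric(0), feature_end = numeric(0),
                     overlap_bp = numeric(0))
  if (!nrow(regions) || !nrow(features)) return(hit0)
  featChrom <- sub("^chr", "", as.character(features$chrom))
  gr <- GenomicRanges::GRanges(as.character(regions$chrom),
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  gf <- GenomicRanges::GRanges(featChrom,
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  ov <- GenomicRanges::findOverlaps(gr, gf)
  if (!length(ov)) return(hit0)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::pintersect(gr[qi], gf[si])
  data.frame(chrom = as.integer(as.character(regions$chrom[qi])),
             region_start = regions$start[qi], region_end = regions$end[qi],
             feature = features$name[si], feature_start = features$start[si],
             feature_end = features$end[si],
             overlap_bp = GenomicRanges::width(inter),
             stringsAsFactors = FALSE)
}
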