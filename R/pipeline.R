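.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeBed <- function(regions, path) {
  # internal 1-based positions were already converted: region start is
  # 0-based half-open, matching the BED convention
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(regions$end, scientific = FALSE,
                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Run the full selection-signature pipeline
#'
#' Executes QC (sample/SNP filters and misplaced-SNP detection),
#' population-structure ordination (IBS distances + classical MDS),
#' the windowed FST outlier scan, the iHS scan on the pooled selected
#' lines, XP-EHH scans of each selected line against the control line,
#' merging of flagged windows into per-test regions, and the
#' two-of-three cross-test consensus; optionally annotates consensus
#' regions against a BED feature file. Any stage failure aborts with
#' the stage name and cause. With identical inputs and configuration
#' the run --- including the written summary --- is byte-identical.
#'
#' @param haps a [HaplotypeData] (phased, complete), or `NULL` to read
#'   from `vcfPath`.
#' @param lines a [LineAssignment], or `NULL` to read from `linesPath`.
#' @param vcfPath,linesPath,control,selected file-based input: a phased
#'   VCF and a sample-to-line TSV plus the control / selected labels.
#' @param bedPath optional BED file of features for region annotation.
#' @param outDir optional output directory; when given, all tables
#'   (TSV), flagged regions (BED), a machine-readable `summary.json`
#'   and a parameter log are written there.
#' @param qcCfg,fstCfg,haploCfg module configurations.
#' @param mdsAxes number of principal coordinates to retain.
#' @return list with the per-stage results (`qc`, `mds`, `silhouette`,
#'   `fst`, `ihs`, `ihsWindows`, `xpehh`, `xpehhWindows`, `regions`,
#'   `consensus`, `annotation`, `summary`).
#' @export
runPipeline <- function(haps = NULL, lines = NULL,
                        vcfPath = NULL, linesPath = NULL,
                        control = NULL, selected = NULL,
                        bedPath = NULL, outDir = NULL,
                        qcCfg = qcConfig(), fstCfg = fstScanConfig(),
                        haploCfg = haploScanConfig(), mdsAxes = 2L) {
  if (is.null(haps))
    haps <- .stage("input", readPhasedVcf(vcfPath))
  if (is.null(lines))
    lines <- .stage("input", readLineAssignment(linesPath, control, selected))

  geno <- asGenotypes(haps)
  qc <- .stage("qc", runQc(geno, lines, qcCfg))
  genoQc <- qc$genotypes
  lines <- qc$lines
  keepSnps <- match(genoQc@map@snpId, haps@map@snpId)
  hapsQc <- .stage("qc", {
    h <- subsetSamples(haps, rownames(genoQc@dosage))
    HaplotypeData(h@haplo[, keepSnps, drop = FALSE], h@sampleIds, genoQc@map)
  })

  mds <- .stage("structure", {
    D <- ibsDistanceMatrix(genoQc)
    classicalMds(D, mdsAxes)
  })
  ctl <- lines@line[rownames(mds$points)] == lines@control
  sil <- if (ncol(mds$points) >= 1L)
    silhouetteWidth(mds$points[, 1], ctl) else NA_real_

  fst <- .stage("fst_scan", fstScan(genoQc, lines, fstCfg))

  selIds <- names(lines@line)[lines@line %in% lines@selected]
  ctlIds <- names(lines@line)[lines@line == lines@control]
  ihs <- .stage("ihs_scan",
                ihsScan(subsetSamples(hapsQc, selIds), haploCfg))
  ihsWin <- windowFlagHaplo(ihs, hapsQc@map, haploCfg, "ihs")

  hapsCtl <- subsetSamples(hapsQc, ctlIds)
  xp <- .stage("xpehh_scan", lapply(lines@selected, function(s) {
    ids <- names(lines@line)[lines@line == s]
    xpehhScan(subsetSamples(hapsQc, ids), hapsCtl, haploCfg)
  }))
  names(xp) <- paste0(lines@selected, "_vs_", lines@control)
  xpWin <- windowFlagHaplo(xp, hapsQc@map, haploCfg, "xpehh")

  regions <- .stage("regions", {
    fw <- fst$windows
    fw$peak <- pmin(fw$mean_fst_1, fw$mean_fst_2)
    xw <- xpWin
    xw$peak <- pmin(xw$mean_xpehh_1, xw$mean_xpehh_2)
    list(FST = mergeWindows(fw, "FST", "peak"),
         XPEHH = mergeWindows(xw, "XPEHH", "peak"),
         IHS = mergeWindows(ihsWin, "IHS", "mean_abs_ihs"))
  })
  consensus <- .stage("consensus", crossTestConsensus(regions))

  annotation <- NULL
  if (!is.null(bedPath))
    annotation <- .stage("annotation", annotateRegions(consensus, bedPath))

  summary <- list(
    n_samples_in = nSamples(geno), n_snps_in = nSnps(geno),
    n_samples_qc = nSamples(genoQc), n_snps_qc = nSnps(genoQc),
    n_removed_samples = sum(qc$report$type == "sample"),
    n_removed_snps = sum(qc$report$type == "snp"),
    n_misplaced = sum(qc$report$reason == "misplaced"),
    mds_explained = round(unname(mds$explained), 10),
    pco1_silhouette_control = round(sil, 10),
    n_windows_fst_candidate = sum(fst$windows$candidate),
    n_windows_ihs_flagged = sum(ihsWin$flagged),
    n_windows_xpehh_flagged = sum(xpWin$flagged),
    n_regions = lapply(regions, nrow),
    n_consensus_regions = nrow(consensus),
    consensus = consensus,
    params = list(qc = unclass(qcCfg), fst = unclass(fstCfg),
                  haplo = unclass(haploCfg), mds_axes = mdsAxes))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(qc$report, file.path(outDir, "qc_report.tsv"))
    pts <- data.frame(sample_id = rownames(mds$points),
                      line = unname(lines@line[rownames(mds$points)]),
                      mds$points)
    .writeTsv(pts, file.path(outDir, "mds_coordinates.tsv"))
    .writeTsv(fst$windows, file.path(outDir, "fst_windows.tsv"))
    .writeTsv(ihs, file.path(outDir, "ihs_scores.tsv"))
    .writeTsv(ihsWin, file.path(outDir, "ihs_windows.tsv"))
    for (nm in names(xp))
      .writeTsv(xp[[nm]], file.path(outDir, paste0("xpehh_", nm, ".tsv")))
    .writeTsv(xpWin, file.path(outDir, "xpehh_windows.tsv"))
    for (nm in names(regions)) {
      .writeTsv(regions[[nm]],
                file.path(outDir, paste0("regions_", tolower(nm), ".tsv")))
      .writeBed(regions[[nm]],
                file.path(outDir, paste0("regions_", tolower(nm), ".bed")))
    }
    .writeTsv(consensus, file.path(outDir, "consensus_regions.tsv"))
    .writeBed(consensus, file.path(outDir, "consensus_regions.bed"))
    if (!is.null(annotation))
      .writeTsv(annotation, file.path(outDir, "annotation_hits.tsv"))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(outDir, "summary.json"))
    log <- c("sweepscan pipeline run",
             paste0("samples: ", nSamples(geno), " -> ", nSamples(genoQc)),
             paste0("snps: ", nSnps(geno), " -> ", nSnps(genoQc)),
             "parameters:",
             utils::capture.output(utils::str(summary$params)))
    writeLines(log, file.path(outDir, "run_log.txt"))
  }

  list(qc = qc, mds = mds, silhouette = sil, fst = fst,
       ihs = ihs, ihsWindows = ihsWin, xpehh = xp, xpehhWindows = xpWin,
       regions = regions, consensus = consensus, annotation = annotation,
       summary = summary)
}
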