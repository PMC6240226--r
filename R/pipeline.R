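#' Run the full species-comparison pipeline
#'
#' End-to-end driver: load contigs per sample, apply the minimum-length
#' filter, optionally classify against reference sets and extract coding
#' sequences, run the all-vs-all similarity search, cluster homologous
#' groups at the E-value threshold, resolve paralogy into orthologous
#' subgroups at the distance cutoff, summarize intra-/inter-species
#' p-distances per OSG, and partition OSGs by copy status, identification
#' and reference-cluster support.
#'
#' @param sampleSheet Data.frame or TSV path (see [readSampleSheet()]), or a
#'   ready-made [ContigSet].
#' @param outDir Optional output directory for TSV products.
#' @param minLen Minimum contig length (bp); default 300.
#' @param classifyRefsets Optional named list of reference
#'   [Biostrings::DNAStringSet]s for [classifyContigs()]. When supplied,
#'   ribosomal and bacterial contigs are excluded from the comparison.
#' @param classifyEvalue E-value threshold for classification; default
#'   `1e-10`.
#' @param useCds Extract coding sequences and compare those; contigs with
#'   no qualifying ORF are dropped. Default TRUE for real transcriptome
#'   contigs; set FALSE when the inputs are already coding-region-level
#'   sequences (e.g. simulated genes).
#' @param minOrfLen Minimum ORF length for [extractCds()]; default 300.
#' @param evalueMax Strict E-value threshold for homologous-group
#'   clustering; default `1e-15`.
#' @param cutoff Within-sample subdivision cutoff in percent; default 2
#'   (the barcode gap).
#' @param engine See [builtinEngine()]; a [tabularHitsEngine()] may replace
#'   the built-in search.
#' @param aligner See [builtinAligner()].
#' @param occupancyMin,trimWindow Alignment end-trimming parameters, see
#'   [trimMsaEnds()].
#' @param refClusters Optional [ReferenceClusterSet] (or list with elements
#'   `genesA`, `genesB` to build one) for the reference-matched partition.
#' @param refEvalue E-value threshold for OSG-to-cluster matching; default
#'   `1e-15`.
#' @param writeHits Also write the all-vs-all hit table (can be large);
#'   default FALSE.
#' @param verbose Log per-stage counts with `message()`.
#' @return A [SpeciesComparison].
#' @export
runComparison <- function(sampleSheet, outDir = NULL,
                          minLen = 300L,
                          classifyRefsets = NULL, classifyEvalue = 1e-10,
                          useCds = TRUE, minOrfLen = 300L,
                          evalueMax = 1e-15, cutoff = 2.0,
                          engine = builtinEngine(),
                          aligner = builtinAligner(),
                          occupancyMin = 1.0, trimWindow = 10L,
                          refClusters = NULL, refEvalue = 1e-15,
                          writeHits = FALSE, verbose = TRUE) {
  log <- function(...) if (verbose) message(sprintf(...))
  counts <- c()
  contigs <- if (methods::is(sampleSheet, "ContigSet")) sampleSheet
             else readContigs(sampleSheet)
  counts["contigs_in"] <- length(contigs)
  contigs <- filterByLength(contigs, minLen = minLen)
  counts["contigs_after_length"] <- length(contigs)
  log("length filter (>= %d bp): %d contigs", minLen,
      counts[["contigs_after_length"]])

  if (!is.null(classifyRefsets)) {
    contigs <- classifyContigs(contigs, classifyRefsets,
                               evalueMax = classifyEvalue, engine = engine)
    if (!is.null(outDir)) writeCategoryFastas(contigs, outDir)
    keep <- contigData(contigs)$category %in% c("eukaryotic", "unidentified")
    contigs <- contigs[which(keep)]
    log("classification: %d eukaryotic/unidentified contigs kept",
        length(contigs))
  }
  counts["contigs_classified_kept"] <- length(contigs)

  if (useCds) {
    contigs <- extractCds(contigs, minOrfLen = minOrfLen)
    contigs <- contigs[which(names(contigSeqs(contigs)) %in%
                               names(cdsSeqs(contigs)))]
    log("CDS extraction: %d contigs with ORF >= %d nt", length(contigs),
        minOrfLen)
  }
  counts["contigs_compared"] <- length(contigs)
  if (length(contigs) < 2L)
    stop("fewer than 2 contigs left to compare")

  hits <- allVsAllHits(contigs, engine = engine, evalueMax = evalueMax)
  counts["hits"] <- nrow(hits)
  groups <- buildHomologousGroups(hits, contigs, evalueMax = evalueMax)
  cs <- copyStatus(groups)
  counts["hgs"] <- length(cs)
  counts["multi_copy_hgs"] <- sum(cs == "multi")
  log("clustering: %d HGs (%d multi-copy)", counts[["hgs"]],
      counts[["multi_copy_hgs"]])

  orthologs <- resolveOrthologs(contigs, groups, cutoff = cutoff,
                                aligner = aligner)
  counts["osgs"] <- length(osgIds(orthologs))
  counts["removed_by_triplet"] <- nrow(removedContigs(orthologs))
  log("paralog resolution: %d OSGs (%d contigs removed by triplet rule)",
      counts[["osgs"]], counts[["removed_by_triplet"]])

  summaries <- summarizeOsgs(contigs, orthologs, aligner = aligner,
                             occupancyMin = occupancyMin,
                             window = trimWindow)

  clusterMap <- NULL
  if (!is.null(refClusters)) {
    if (!methods::is(refClusters, "ReferenceClusterSet"))
      refClusters <- buildReferenceClusters(refClusters$genesA,
                                            refClusters$genesB,
                                            engine = engine,
                                            evalueMax = refEvalue)
    clusterMap <- matchOsgsToClusters(contigs, orthologs, refClusters,
                                      engine = engine,
                                      evalueMax = refEvalue)
    log("reference matching: %d OSGs uniquely matched to %d clusters",
        length(clusterMap), nrow(referenceClusters(refClusters)))
  }
  flags <- osgFlagTable(contigs, orthologs, clusterMap)
  partitions <- partitionSummaries(flags)
  counts["partition_all"] <- length(partitions$all)
  counts["partition_single_copy_euk"] <-
    length(partitions$single_copy_eukaryotic)
  counts["partition_reference_matched"] <-
    length(partitions$reference_matched)
  log("partitions: all=%d, single-copy eukaryotic=%d, reference-matched=%d",
      counts[["partition_all"]], counts[["partition_single_copy_euk"]],
      counts[["partition_reference_matched"]])

  res <- new("SpeciesComparison", contigs = contigs, groups = groups,
             orthologs = orthologs, summaries = summaries,
             osgFlags = flags, partitions = partitions, counts = counts)
  if (!is.null(outDir)) writeComparison(res, outDir, writeHits = writeHits)
  res
}

#' Write the TSV products of a comparison run
#'
#' Emits `hg_membership.tsv`, `osg_membership.tsv`, `osg_removed.tsv`,
#' `osg_summaries.tsv` (the master spreadsheet: one row per OSG and
#' comparison with min/max/average distances, flags and partition
#' membership), `osg_flags.tsv` and `stage_counts.tsv`. Rows are sorted so
#' identical runs produce byte-identical files.
#'
#' @param x A [SpeciesComparison].
#' @param outDir Output directory (created if needed).
#' @param writeHits Also write `hits.tsv`.
#' @return Invisibly, the output directory.
#' @export
writeComparison <- function(x, outDir, writeHits = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(hgMembership(x), "hg_membership.tsv")
  wt(osgMembership(x), "osg_membership.tsv")
  wt(removedContigs(x), "osg_removed.tsv")
  master <- merge(osgSummaries(x), osgFlags(x), by = "osg_id", sort = TRUE)
  parts <- resultPartitions(x)
  master$in_single_copy_eukaryotic <-
    master$osg_id %in% parts$single_copy_eukaryotic
  master$in_reference_matched <- master$osg_id %in% parts$reference_matched
  master <- master[order(master$osg_id, master$type, master$species1,
                         master$species2), ]
  wt(master, "osg_summaries.tsv")
  wt(osgFlags(x), "osg_flags.tsv")
  wt(data.frame(stage = names(stageCounts(x)),
                count = unname(stageCounts(x))), "stage_counts.tsv")
  if (writeHits) wt(hgHits(x@groups), "hits.tsv")
  invisible(outDir)
}
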