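#' Contigs from one or more transcriptome samples
#'
#' `ContigSet` holds assembled transcript sequences together with per-contig
#' metadata: the sample each contig was assembled from, the species and clade
#' labels of that sample, the contig's classification category, and (after
#' CDS extraction) its coding region.
#'
#' @slot sequences A named [Biostrings::DNAStringSet] of contig sequences.
#' @slot contigData A [S4Vectors::DataFrame] with one row per contig and
#'   columns `contig_id`, `sample_id`, `species`, `clade`, `category`.
#' @slot cds A named [Biostrings::DNAStringSet] of extracted coding
#'   sequences; names are a subset of the contig ids and every width is a
#'   multiple of three.
#'
#' @seealso [readContigs()], [filterByLength()], [classifyContigs()],
#'   [extractCds()]
#' @export
setClass("ContigSet",
  slots = c(sequences = "DNAStringSet",
            contigData = "DataFrame",
            cds = "DNAStringSet"))

setValidity("ContigSet", function(object) {
  ids <- names(object@sequences)
  msg <- character()
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "contig ids must be unique and non-NULL")
  if (nrow(object@contigData) != length(object@sequences))
    msg <- c(msg, "contigData must have one row per sequence")
  need <- c("contig_id", "sample_id", "species", "clade", "category")
  if (!all(need %in% colnames(object@contigData)))
    msg <- c(msg, paste("contigData must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (!identical(as.character(object@contigData$contig_id), ids))
      msg <- c(msg, "contigData$contig_id must match sequence names")
    bad <- setdiff(unique(object@contigData$category), .CATEGORIES)
    if (length(bad))
      msg <- c(msg, paste("unknown categories:", paste(bad, collapse = ", ")))
  }
  if (length(object@sequences) && any(width(object@sequences) < 1L))
    msg <- c(msg, "all sequences must have length >= 1")
  if (length(object@cds)) {
    if (!all(names(object@cds) %in% ids))
      msg <- c(msg, "cds names must be a subset of contig ids")
    if (any(width(object@cds) %% 3L != 0L))
      msg <- c(msg, "cds lengths must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

#' Homologous groups from single-linkage clustering of similarity hits
#'
#' Contigs connected by similarity hits with an E-value strictly below the
#' clustering threshold form one homologous group (HG); contigs with no
#' qualifying hit are retained as singleton HGs flagged non-comparable.
#'
#' @slot hits A data.frame of pairwise similarity hits (tabular 12-column
#'   style, 0-based half-open coordinates).
#' @slot membership A data.frame with columns `hg_id`, `contig_id`,
#'   `sample_id`, `copy_status`, `comparable`; every contig appears exactly
#'   once.
#' @slot evalueMax The strict E-value threshold used for clustering.
#'
#' @seealso [buildHomologousGroups()], [classifyCopyStatus()]
#' @export
setClass("HomologousGroups",
  slots = c(hits = "data.frame",
            membership = "data.frame",
            evalueMax = "numeric"))

setValidity("HomologousGroups", function(object) {
  msg <- character()
  need <- c("hg_id", "contig_id", "sample_id", "copy_status", "comparable")
  if (!all(need %in% colnames(object@membership)))
    msg <- c(msg, paste("membership must have columns:",
                        paste(need, collapse = ", ")))
  else if (anyDuplicated(object@membership$contig_id))
    msg <- c(msg, "every contig must belong to exactly one HG")
  if (length(msg)) msg else TRUE
})

#' Orthologous subgroups after paralog resolution
#'
#' Each orthologous subgroup (OSG) is a putatively orthologous set of
#' contigs: at most one within-sample subgroup per sample, produced either
#' directly from a single-copy HG, by subdivision and tree-guided matching,
#' or by the three-sequence (triplet) rule. Contigs discarded by the triplet
#' rule are kept in a removal ledger.
#'
#' @slot membership data.frame with columns `osg_id`, `hg_id`, `contig_id`,
#'   `sample_id`, `provenance` (one of `single_copy_hg`, `subdivided`,
#'   `triplet_rule`).
#' @slot removed data.frame with columns `contig_id`, `hg_id`, `reason`.
#'
#' @seealso [resolveOrthologs()], [resolveTriplet()]
#' @export
setClass("OrthologSet",
  slots = c(membership = "data.frame",
            removed = "data.frame"))

setValidity("OrthologSet", function(object) {
  msg <- character()
  need <- c("osg_id", "hg_id", "contig_id", "sample_id", "provenance")
  if (!all(need %in% colnames(object@membership)))
    msg <- c(msg, paste("membership must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@membership$contig_id))
      msg <- c(msg, "a contig may appear in only one OSG")
    both <- intersect(object@membership$contig_id, object@removed$contig_id)
    if (length(both))
      msg <- c(msg, "a contig may not be both assigned and removed")
  }
  if (length(msg)) msg else TRUE
})

#' Reference clusters of single-copy genes shared by two genomes
#'
#' Each cluster pairs exactly one gene from each of two reference genomes,
#' built by reciprocal best hits with in-genome duplicates excluded, so that
#' a match vouches that an OSG is truly single-copy.
#'
#' @slot clusters data.frame with columns `cluster_id`, `geneA_id`,
#'   `geneB_id`.
#' @slot genesA,genesB The reference gene sequences.
#'
#' @seealso [buildReferenceClusters()], [matchOsgsToClusters()]
#' @export
setClass("ReferenceClusterSet",
  slots = c(clusters = "data.frame",
            genesA = "DNAStringSet",
            genesB = "DNAStringSet"))

setValidity("ReferenceClusterSet", function(object) {
  msg <- character()
  cl <- object@clusters
  if (!all(c("cluster_id", "geneA_id", "geneB_id") %in% colnames(cl)))
    msg <- c(msg, "clusters needs cluster_id, geneA_id, geneB_id")
  else if (anyDuplicated(cl$geneA_id) || anyDuplicated(cl$geneB_id))
    msg <- c(msg, "each reference gene may appear in at most one cluster")
  if (length(msg)) msg else TRUE
})

#' Results of a full species-comparison run
#'
#' Container returned by [runComparison()]: the classified contigs, the
#' homologous groups, the resolved orthologous subgroups, the per-OSG
#' distance summaries and flags, the three reporting partitions, and the
#' per-stage counts.
#'
#' @slot contigs A [ContigSet].
#' @slot groups A [HomologousGroups].
#' @slot orthologs An [OrthologSet].
#' @slot summaries Long-format data.frame of per-OSG min/max/average intra-
#'   and inter-species percent p-distances.
#' @slot osgFlags data.frame with per-OSG `copy_status`, `identified` and
#'   `reference_cluster_id`.
#' @slot partitions Named list of OSG id vectors: `all`,
#'   `single_copy_eukaryotic`, `reference_matched`.
#' @slot counts Named numeric vector of per-stage counts.
#'
#' @export
setClass("SpeciesComparison",
  slots = c(contigs = "ContigSet",
            groups = "HomologousGroups",
            orthologs = "OrthologSet",
            summaries = "data.frame",
            osgFlags = "data.frame",
            partitions = "list",
            counts = "numeric"))
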