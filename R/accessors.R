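#' @describeIn ContigSet-accessors contig sequences as a `DNAStringSet`
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))

#' @describeIn ContigSet-accessors per-contig metadata `DataFrame`
#' @export
setGeneric("contigData", function(x) standardGeneric("contigData"))

#' @describeIn ContigSet-accessors extracted coding sequences
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' Accessors for ContigSet
#'
#' @param x A [ContigSet].
#' @name ContigSet-accessors
#' @aliases contigSeqs contigData cdsSeqs
NULL

#' @rdname ContigSet-accessors
#' @export
setMethod("contigSeqs", "ContigSet", function(x) x@sequences)

#' @rdname ContigSet-accessors
#' @export
setMethod("contigData", "ContigSet", function(x) x@contigData)

#' @rdname ContigSet-accessors
#' @export
setMethod("cdsSeqs", "ContigSet", function(x) x@cds)

#' @export
setMethod("length", "ContigSet", function(x) length(x@sequences))

#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  cds <- x@cds
  keep <- names(x@sequences)[i]
  new("ContigSet",
      sequences = x@sequences[i],
      contigData = x@contigData[i, , drop = FALSE],
      cds = cds[names(cds) %in% keep])
})

setMethod("show", "ContigSet", function(object) {
  cd <- object@contigData
  cat("ContigSet with", length(object), "contigs from",
      length(unique(cd$sample_id)), "sample(s)\n")
  if (length(object)) {
    tab <- table(cd$sample_id)
    for (s in names(tab)) {
      sp <- unique(cd$species[cd$sample_id == s])
      cat(sprintf("  %s (%s): %d contigs\n", s, sp[1], tab[[s]]))
    }
    cat("categories:",
        paste(sprintf("%s=%d", names(table(cd$category)), table(cd$category)),
              collapse = ", "), "\n")
    if (length(object@cds))
      cat("coding sequences extracted for", length(object@cds), "contigs\n")
  }
  invisible(object)
})

#' Accessors for HomologousGroups
#'
#' @param x A [HomologousGroups].
#' @return `hgMembership()` the membership data.frame; `hgHits()` the hit
#'   table; `hgIds()` the HG ids; `copyStatus()` a named character vector
#'   (`"single"`/`"multi"`) indexed by HG id.
#' @name HomologousGroups-accessors
NULL

#' @rdname HomologousGroups-accessors
#' @export
setGeneric("hgMembership", function(x) standardGeneric("hgMembership"))

#' @rdname HomologousGroups-accessors
#' @export
setGeneric("hgHits", function(x) standardGeneric("hgHits"))

#' @rdname HomologousGroups-accessors
#' @export
setGeneric("hgIds", function(x) standardGeneric("hgIds"))

#' @rdname HomologousGroups-accessors
#' @export
setGeneric("copyStatus", function(x) standardGeneric("copyStatus"))

#' @rdname HomologousGroups-accessors
#' @export
setMethod("hgMembership", "HomologousGroups", function(x) x@membership)

#' @rdname HomologousGroups-accessors
#' @export
setMethod("hgHits", "HomologousGroups", function(x) x@hits)

#' @rdname HomologousGroups-accessors
#' @export
setMethod("hgIds", "HomologousGroups",
          function(x) unique(x@membership$hg_id))

#' @rdname HomologousGroups-accessors
#' @export
setMethod("copyStatus", "HomologousGroups", function(x) {
  m <- x@membership[!duplicated(x@membership$hg_id), ]
  setNames(m$copy_status, m$hg_id)
})

setMethod("show", "HomologousGroups", function(object) {
  m <- object@membership
  n_hg <- length(unique(m$hg_id))
  cs <- copyStatus(object)
  cat("HomologousGroups:", n_hg, "HGs over", nrow(m), "contigs",
      sprintf("(e-value < %g)\n", object@evalueMax))
  cat(sprintf("  single-copy: %d, multi-copy: %d, singletons: %d\n",
              sum(cs == "single"), sum(cs == "multi"),
              sum(!m$comparable[!duplicated(m$hg_id)])))
  invisible(object)
})

#' Accessors for OrthologSet
#'
#' @param x An [OrthologSet].
#' @name OrthologSet-accessors
NULL

#' @rdname OrthologSet-accessors
#' @export
setGeneric("osgMembership", function(x) standardGeneric("osgMembership"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("osgIds", function(x) standardGeneric("osgIds"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("removedContigs", function(x) standardGeneric("removedContigs"))

#' @rdname OrthologSet-accessors
#' @export
setMethod("osgMembership", "OrthologSet", function(x) x@membership)

#' @rdname OrthologSet-accessors
#' @export
setMethod("osgIds", "OrthologSet", function(x) unique(x@membership$osg_id))

#' @rdname OrthologSet-accessors
#' @export
setMethod("removedContigs", "OrthologSet", function(x) x@removed)

setMethod("show", "OrthologSet", function(object) {
  m <- object@membership
  cat("OrthologSet:", length(unique(m$osg_id)), "OSGs over", nrow(m),
      "contigs\n")
  tab <- table(m$provenance[!duplicated(m$osg_id)])
  cat("  provenance:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (nrow(object@removed))
    cat("  removed by triplet rule:", nrow(object@removed), "contig(s)\n")
  invisible(object)
})

#' Accessors for ReferenceClusterSet
#'
#' @param x A [ReferenceClusterSet].
#' @name ReferenceClusterSet-accessors
NULL

#' @rdname ReferenceClusterSet-accessors
#' @export
setGeneric("referenceClusters", function(x) standardGeneric("referenceClusters"))

#' @rdname ReferenceClusterSet-accessors
#' @export
setMethod("referenceClusters", "ReferenceClusterSet", function(x) x@clusters)

setMethod("show", "ReferenceClusterSet", function(object) {
  cat("ReferenceClusterSet:", nrow(object@clusters),
      "single-copy clusters from", length(object@genesA), "+",
      length(object@genesB), "reference genes\n")
  invisible(object)
})

#' Accessors for SpeciesComparison
#'
#' @param x A [SpeciesComparison].
#' @name SpeciesComparison-accessors
NULL

#' @rdname SpeciesComparison-accessors
#' @export
setGeneric("osgSummaries", function(x) standardGeneric("osgSummaries"))

#' @rdname SpeciesComparison-accessors
#' @export
setGeneric("osgFlags", function(x) standardGeneric("osgFlags"))

#' @rdname SpeciesComparison-accessors
#' @export
setGeneric("resultPartitions", function(x) standardGeneric("resultPartitions"))

#' @rdname SpeciesComparison-accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("osgSummaries", "SpeciesComparison", function(x) x@summaries)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("osgFlags", "SpeciesComparison", function(x) x@osgFlags)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("resultPartitions", "SpeciesComparison", function(x) x@partitions)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("stageCounts", "SpeciesComparison", function(x) x@counts)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("contigSeqs", "SpeciesComparison", function(x) x@contigs@sequences)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("hgMembership", "SpeciesComparison",
          function(x) x@groups@membership)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("osgMembership", "SpeciesComparison",
          function(x) x@orthologs@membership)

#' @rdname SpeciesComparison-accessors
#' @export
setMethod("removedContigs", "SpeciesComparison",
          function(x) x@orthologs@removed)

setMethod("show", "SpeciesComparison", function(object) {
  cat("SpeciesComparison\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-28s %d\n", nm, object@counts[[nm]]))
  invisible(object)
})
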