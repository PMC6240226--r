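#' Cluster contigs into homologous groups
#'
#' Single-linkage clustering: the undirected graph whose edges are hits with
#' E-value strictly below `evalueMax` is built over all contigs, and each
#' connected component becomes one homologous group (HG). This permissive
#' rule lets contigs with little mutual overlap still group together when
#' they come from the same gene. Contigs with no qualifying edge are kept as
#' singleton HGs flagged non-comparable so that copy-status accounting stays
#' complete.
#'
#' HG ids are assigned deterministically: components are ranked by their
#' lexicographically smallest member id.
#'
#' @param hits Hit data.frame from [allVsAllHits()].
#' @param contigs A [ContigSet] (or data.frame with `contig_id`,
#'   `sample_id`) covering every contig, including those without hits.
#' @param evalueMax Strict E-value threshold for clustering edges; default
#'   `1e-15`.
#' @return A [HomologousGroups] object.
#' @export
buildHomologousGroups <- function(hits, contigs, evalueMax = 1e-15) {
  cd <- if (methods::is(contigs, "ContigSet"))
    as.data.frame(contigData(contigs)) else as.data.frame(contigs)
  stopifnot(all(c("contig_id", "sample_id") %in% colnames(cd)))
  ids <- as.character(cd$contig_id)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown))
    stop("hits reference unknown contig ids: ",
         paste(head(unknown, 5), collapse = ", "))
  edges <- hits[hits$evalue < evalueMax, c("query_id", "subject_id")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  # deterministic ids: rank components by smallest member contig id
  smallest <- vapply(split(ids, comp), min, character(1))
  hg_num <- match(as.character(comp), names(smallest)[order(smallest)])
  hg_id <- sprintf("HG%05d", hg_num)
  memb <- data.frame(hg_id = hg_id, contig_id = ids,
                     sample_id = as.character(cd$sample_id),
                     stringsAsFactors = FALSE)
  memb <- memb[order(memb$hg_id, memb$contig_id), ]
  rownames(memb) <- NULL
  cs <- vapply(split(memb$sample_id, memb$hg_id), classifyCopyStatus,
               character(1))
  size <- vapply(split(memb$sample_id, memb$hg_id), length, integer(1))
  memb$copy_status <- cs[memb$hg_id]
  memb$comparable <- size[memb$hg_id] >= 2L
  new("HomologousGroups", hits = hits, membership = memb,
      evalueMax = evalueMax)
}

#' Copy status of a group
#'
#' A group is `"multi"` when any sample contributes two or more members
#' (i.e. putative within-sample paralogs are present), `"single"` otherwise.
#'
#' @param sampleIds Character vector: the sample label of each member.
#' @return `"single"` or `"multi"`.
#' @export
classifyCopyStatus <- function(sampleIds) {
  if (!length(sampleIds)) stop("group is empty")
  if (any(table(sampleIds) >= 2L)) "multi" else "single"
}

#' Write HG membership as TSV
#'
#' @param x A [HomologousGroups].
#' @param path Output path.
#' @export
writeHgMembership <- function(x, path) {
  write.table(hgMembership(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
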