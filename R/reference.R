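#' Build single-copy reference clusters from two gene sets
#'
#' Reciprocal best hits (RBH) between the gene sets of two reference
#' genomes, with single-copy enforcement: a gene that has any within-genome
#' hit at E-value at most `evalueMax` (an in-genome duplicate) is excluded.
#' Each resulting cluster holds exactly one gene per genome and vouches
#' that a transcript group matching it is truly single-copy.
#'
#' @param genesA,genesB Named [Biostrings::DNAStringSet]s of the two
#'   genomes' gene sequences; ids must be unique.
#' @param engine See [builtinEngine()].
#' @param evalueMax Maximum E-value for hits; default `1e-15`.
#' @return A [ReferenceClusterSet].
#' @export
buildReferenceClusters <- function(genesA, genesB,
                                   engine = builtinEngine(),
                                   evalueMax = 1e-15) {
  if (!length(genesA) || !length(genesB))
    stop("both gene sets must be non-empty")
  if (anyDuplicated(names(genesA)) || anyDuplicated(names(genesB)))
    stop("duplicate gene ids in reference gene sets")
  dup <- intersect(names(genesA), names(genesB))
  if (length(dup))
    stop("gene ids shared between genomes: ", paste(head(dup, 5),
                                                    collapse = ", "))
  ab <- searchHits(genesA, genesB, engine = engine, evalueMax = evalueMax)
  ba <- searchHits(genesB, genesA, engine = engine, evalueMax = evalueMax)
  bestAB <- .best_hit_per_query(ab)
  bestBA <- .best_hit_per_query(ba)
  # in-genome duplicates (self-hits are already excluded by searchHits)
  dupA <- unique(allVsAllHitsSafe(genesA, engine, evalueMax)$query_id)
  dupB <- unique(allVsAllHitsSafe(genesB, engine, evalueMax)$query_id)
  back <- bestBA[unname(bestAB)]
  rbh <- bestAB[!is.na(back) & back == names(bestAB)]
  rbh <- rbh[!(names(rbh) %in% dupA) & !(rbh %in% dupB)]
  ord <- order(names(rbh))
  clusters <- data.frame(cluster_id = sprintf("RC%04d", seq_along(ord)),
                         geneA_id = names(rbh)[ord],
                         geneB_id = unname(rbh)[ord],
                         stringsAsFactors = FALSE)
  new("ReferenceClusterSet", clusters = clusters,
      genesA = DNAStringSet(genesA), genesB = DNAStringSet(genesB))
}

# all-vs-all that tolerates sets of size 1 (no possible duplicate)
allVsAllHitsSafe <- function(seqs, engine, evalueMax) {
  if (length(seqs) < 2L)
    return(data.frame(query_id = character(), stringsAsFactors = FALSE))
  allVsAllHits(seqs, engine = engine, evalueMax = evalueMax)
}

# best subject per query by bit score; ties by evalue then subject id
.best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(setNames(character(), character()))
  h <- hits[order(hits$query_id, -hits$bitscore, hits$evalue,
                  hits$subject_id), ]
  h <- h[!duplicated(h$query_id), ]
  setNames(h$subject_id, h$query_id)
}

#' Match OSGs to single-copy reference clusters
#'
#' Each OSG is represented by its longest member sequence (ties broken by
#' id) and searched against the clusters' gene sequences; the best-hit
#' cluster at E-value at most `evalueMax` is recorded. Matches that are not
#' unique are then removed entirely: if two or more OSGs claim the same
#' cluster, all of them are dropped, leaving an injective OSG-to-cluster
#' map.
#'
#' @param contigs A [ContigSet].
#' @param orthologs An [OrthologSet].
#' @param refClusters A [ReferenceClusterSet].
#' @param engine See [builtinEngine()].
#' @param evalueMax Maximum E-value; default `1e-15` (consistent with the
#'   clustering threshold).
#' @return Named character vector `osg_id -> cluster_id`.
#' @export
matchOsgsToClusters <- function(contigs, orthologs, refClusters,
                                engine = builtinEngine(),
                                evalueMax = 1e-15) {
  seqs <- analysisSeqs(contigs)
  memb <- osgMembership(orthologs)
  reps <- vapply(split(memb$contig_id, memb$osg_id), function(m) {
    w <- width(seqs[m])
    m[order(-w, m)][1]
  }, character(1))
  cl <- referenceClusters(refClusters)
  genes <- c(refClusters@genesA[cl$geneA_id], refClusters@genesB[cl$geneB_id])
  gene2cluster <- setNames(rep(cl$cluster_id, 2L),
                           c(cl$geneA_id, cl$geneB_id))
  if (!length(genes)) return(setNames(character(), character()))
  repseqs <- seqs[unname(reps)]
  names(repseqs) <- names(reps)  # rename reps by their OSG id
  hits <- searchHits(repseqs, genes, engine = engine, evalueMax = evalueMax)
  if (!nrow(hits)) return(setNames(character(), character()))
  hits$cluster_id <- gene2cluster[hits$subject_id]
  h <- hits[order(hits$query_id, -hits$bitscore, hits$evalue,
                  hits$cluster_id), ]
  h <- h[!duplicated(h$query_id), ]
  map <- setNames(h$cluster_id, h$query_id)
  shared <- names(which(table(map) >= 2L))
  map <- map[!(map %in% shared)]
  map
}

#' Select barcode-marker candidates from cluster-matched OSGs
#'
#' Candidate DNA barcode markers are reference clusters whose matched OSGs
#' have every available designated intraspecific average below
#' `intraCutoff` percent (missing intraspecific comparisons do not
#' disqualify) and which are represented in at least `minClades` clades.
#' Clusters present in every analyzed sample are additionally flagged
#' `universal`.
#'
#' @param clusterTable data.frame with one row per matched OSG and columns
#'   `cluster_id`, `osg_id`, `clade`, `sample_ids` (comma-separated sample
#'   ids carrying the OSG) and `intra_max` (largest designated
#'   intraspecific average for that OSG, `NA` when no intraspecific
#'   comparison exists).
#' @param intraCutoff Intraspecific threshold in percent; default 2.
#' @param minClades Minimum number of distinct clades; default 2.
#' @param allSamples Optional character vector of every analyzed sample id,
#'   used for the `universal` flag.
#' @return data.frame with one row per cluster: `cluster_id`, `n_clades`,
#'   `max_intra`, `selected`, `universal`.
#' @export
selectBarcodeCandidates <- function(clusterTable, intraCutoff = 2.0,
                                    minClades = 2L, allSamples = NULL) {
  stopifnot(all(c("cluster_id", "clade", "sample_ids", "intra_max") %in%
                  colnames(clusterTable)))
  out <- lapply(split(clusterTable, clusterTable$cluster_id), function(ct) {
    intra <- ct$intra_max[!is.na(ct$intra_max)]
    samples <- unique(unlist(strsplit(ct$sample_ids, ",", fixed = TRUE)))
    data.frame(cluster_id = ct$cluster_id[1],
               n_clades = length(unique(ct$clade)),
               max_intra = if (length(intra)) max(intra) else NA_real_,
               selected = all(intra < intraCutoff) &&
                 length(unique(ct$clade)) >= minClades,
               universal = if (is.null(allSamples)) NA else
                 all(allSamples %in% samples),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$cluster_id), ]
  rownames(res) <- NULL
  res
}

#' Write reference clusters as TSV
#'
#' @param x A [ReferenceClusterSet].
#' @param path Output path.
#' @export
writeReferenceClusters <- function(x, path) {
  write.table(referenceClusters(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
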