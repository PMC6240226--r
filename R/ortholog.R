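#' Subdivide within-sample paralogs at a distance cutoff
#'
#' For each sample independently, members are clustered by single linkage
#' over edges with pairwise p-distance at most `cutoff` percent (chaining is
#' deliberate: low-overlap variants of one gene stay together). Subgroup
#' numbering is deterministic, by the lexicographically smallest member id.
#'
#' @param members data.frame with columns `contig_id`, `sample_id`.
#' @param dm Percent distance matrix covering all members (see
#'   [distanceMatrix()]).
#' @param cutoff Maximum within-subgroup linkage distance, percent;
#'   default 2.
#' @return data.frame with columns `subgroup_id`, `contig_id`, `sample_id`.
#' @export
subdivideWithinSample <- function(members, dm, cutoff = 2.0) {
  stopifnot(all(members$contig_id %in% rownames(dm)))
  out <- NULL
  for (s in sort(unique(members$sample_id))) {
    ids <- sort(members$contig_id[members$sample_id == s])
    comp <- .single_linkage(ids, dm, cutoff)
    sg <- vapply(split(ids, comp), min, character(1))
    num <- match(as.character(comp), names(sg)[order(sg)])
    out <- rbind(out, data.frame(
      subgroup_id = sprintf("%s.%d", s, num),
      contig_id = ids, sample_id = s, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# connected components over edges d <= cutoff among ids (union-find)
.single_linkage <- function(ids, dm, cutoff) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) {
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      if (dm[ids[a], ids[b]] <= cutoff) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Neighbor-joining gene tree from a distance matrix
#'
#' A distance tree stands in for likelihood inference here: the tree is
#' used only to keep paralog clusters apart during subgroup matching, for
#' which neighbor joining on the p-distance matrix suffices. Negative
#' branch lengths are clamped to zero. An externally built tree can be
#' supplied to [resolveOrthologs()] through its `treeFun` seam.
#'
#' @param dm Symmetric, finite percent distance matrix with at least 3
#'   labels.
#' @return An unrooted `phylo` tree.
#' @export
buildGeneTree <- function(dm) {
  dm <- as.matrix(dm)
  if (!all(is.finite(dm))) stop("distance matrix has non-finite entries")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (nrow(dm) < 3L) stop("need at least 3 labels for a tree")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Edge set (as "a-b" strings with a < b) of the path between two tips.
.path_edges <- function(tree, t1, t2) {
  np <- ape::nodepath(tree,
                      which(tree$tip.label == t1),
                      which(tree$tip.label == t2))
  if (length(np) < 2L) return(character())
  a <- np[-length(np)]; b <- np[-1]
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

# Edges of the minimal subtree spanning a set of tips.
.span_edges <- function(tree, tips) {
  if (length(tips) < 2L) return(character())
  e <- character()
  for (a in 1:(length(tips) - 1L)) for (b in (a + 1L):length(tips))
    e <- union(e, .path_edges(tree, tips[a], tips[b]))
  e
}

#' Match within-sample subgroups into orthologous subgroups
#'
#' Greedy agglomeration: candidate pairs of subgroups from different
#' samples are processed in increasing order of their average
#' inter-subgroup p-distance (ties broken by the smaller lexicographic pair
#' of subgroup ids). A merge is applied when (i) the two clusters share no
#' sample (at most one subgroup per sample per OSG) and (ii) it is
#' tree-consistent: when a gene tree is available, the tree path between
#' the two subgroups may not run through the spanning subtree of a third,
#' already-merged cluster. Unmatched subgroups become singleton OSGs.
#'
#' There is deliberately no distance ceiling on cross-sample matching, so
#' orphaned distant paralogs can end up matched; this reproduces the
#' high-distance tail seen in real transcriptome comparisons and is
#' intended behavior.
#'
#' @param subgroups data.frame from [subdivideWithinSample()].
#' @param dm Percent distance matrix over all member contigs.
#' @param tree Optional `phylo` gene tree with member contigs as tips.
#' @return data.frame with columns `osg_index`, `contig_id`, `sample_id`;
#'   `osg_index` is ordered by smallest member contig id.
#' @export
matchSubgroupsToOsgs <- function(subgroups, dm, tree = NULL) {
  stopifnot(all(subgroups$contig_id %in% rownames(dm)))
  sgs <- sort(unique(subgroups$subgroup_id))
  members <- split(subgroups$contig_id, subgroups$subgroup_id)[sgs]
  samples <- vapply(sgs, function(g)
    subgroups$sample_id[subgroups$subgroup_id == g][1], character(1))
  n <- length(sgs)
  # candidate pairs across samples, by mean cross distance
  cand <- NULL
  if (n >= 2L) {
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      if (samples[a] == samples[b]) next
      d <- mean(dm[members[[a]], members[[b]], drop = FALSE])
      cand <- rbind(cand, data.frame(a = a, b = b, d = d))
    }
  }
  cl_of <- seq_len(n)
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$d, sgs[cand$a], sgs[cand$b]), ]
    for (r in seq_len(nrow(cand))) {
      ca <- cl_of[cand$a[r]]; cb <- cl_of[cand$b[r]]
      if (ca == cb) next
      sa <- samples[cl_of == ca]; sb <- samples[cl_of == cb]
      if (length(intersect(sa, sb))) next
      if (!is.null(tree) &&
          !.tree_consistent(cand$a[r], cand$b[r], ca, cb, cl_of, members,
                            tree, dm))
        next
      cl_of[cl_of == cb] <- ca
    }
  }
  # emit OSGs ordered by smallest member contig id
  osgs <- lapply(split(seq_len(n), cl_of), function(ix)
    sort(unlist(members[ix], use.names = FALSE)))
  osgs <- osgs[order(vapply(osgs, min, character(1)))]
  out <- do.call(rbind, lapply(seq_along(osgs), function(k) {
    ids <- osgs[[k]]
    data.frame(osg_index = k, contig_id = ids,
               sample_id = subgroups$sample_id[match(ids,
                                                     subgroups$contig_id)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Merge of subgroups a, b (clusters ca, cb) is tree-consistent when the
# tree path between their closest tips does not use an edge inside the
# spanning subtree of any other multi-subgroup cluster.
.tree_consistent <- function(a, b, ca, cb, cl_of, members, tree, dm) {
  ta <- intersect(members[[a]], tree$tip.label)
  tb <- intersect(members[[b]], tree$tip.label)
  if (!length(ta) || !length(tb)) return(TRUE)
  sub <- dm[ta, tb, drop = FALSE]
  best <- arrayInd(which.min(sub), dim(sub))
  path <- .path_edges(tree, ta[best[1]], tb[best[2]])
  for (cc in setdiff(unique(cl_of), c(ca, cb))) {
    ix <- which(cl_of == cc)
    if (length(ix) < 2L) next
    tips <- intersect(unlist(members[ix], use.names = FALSE),
                      tree$tip.label)
    if (length(tips) < 2L) next
    if (length(intersect(path, .span_edges(tree, tips)))) return(FALSE)
  }
  TRUE
}

#' Resolve a 2+1 homologous group by the three-sequence rule
#'
#' When a homologous group holds exactly two paralogs from one sample and a
#' single sequence from another sample (and the paralogs were not merged by
#' within-sample subdivision), the less distant paralog is matched with the
#' single sequence and the more distant paralog is removed. Distance ties
#' keep the lexicographically smaller paralog id.
#'
#' @param members data.frame with columns `contig_id`, `sample_id`:
#'   exactly 3 rows, two from one sample and one from another.
#' @param dm Percent distance matrix over the three contigs.
#' @return list with `kept` (character vector of the two matched contig
#'   ids) and `removed` (the discarded paralog id).
#' @export
resolveTriplet <- function(members, dm) {
  stopifnot(nrow(members) == 3L)
  tab <- table(members$sample_id)
  if (length(tab) != 2L || !setequal(as.integer(tab), c(1L, 2L)))
    stop("triplet rule needs two sequences from one sample and one from another")
  dup_sample <- names(tab)[tab == 2L]
  paralogs <- sort(members$contig_id[members$sample_id == dup_sample])
  single <- members$contig_id[members$sample_id != dup_sample]
  d <- dm[paralogs, single]
  keep <- paralogs[which.min(d)]  # which.min takes the first (smaller id) on ties
  list(kept = sort(c(keep, single)),
       removed = setdiff(paralogs, keep))
}

#' Resolve all homologous groups into orthologous subgroups
#'
#' Driver over every HG: single-copy HGs pass through unchanged as OSGs;
#' multi-copy HGs are aligned, their within-sample paralogs subdivided at
#' the distance cutoff, and the subgroups matched across samples with a
#' neighbor-joining gene tree as guide; 2+1 groups needing subdivision use
#' the three-sequence rule instead. Every contig ends up in exactly one OSG
#' or in the triplet-removal ledger.
#'
#' @param contigs A [ContigSet]; comparison sequences come from
#'   [analysisSeqs()].
#' @param hgroups A [HomologousGroups].
#' @param cutoff Within-sample subdivision cutoff, percent; default 2.
#' @param aligner See [alignSequences()].
#' @param treeFun Function `(msa, dm) -> phylo` used for gene trees;
#'   defaults to [buildGeneTree()] on the distance matrix. Supply a wrapper
#'   around an external tool for production parity.
#' @return An [OrthologSet].
#' @export
resolveOrthologs <- function(contigs, hgroups, cutoff = 2.0,
                             aligner = builtinAligner(),
                             treeFun = NULL) {
  seqs <- analysisSeqs(contigs)
  memb <- hgMembership(hgroups)
  res <- vector("list", length(unique(memb$hg_id)))
  removed <- NULL
  k <- 0L
  for (hg in unique(memb$hg_id)) {
    k <- k + 1L
    m <- memb[memb$hg_id == hg, c("contig_id", "sample_id")]
    if (classifyCopyStatus(m$sample_id) == "single") {
      res[[k]] <- data.frame(hg_id = hg, osg_local = 1L,
                             contig_id = sort(m$contig_id),
                             provenance = "single_copy_hg",
                             stringsAsFactors = FALSE)
      next
    }
    msa <- alignSequences(seqs[m$contig_id], aligner = aligner)
    dm <- distanceMatrix(msa)
    sg <- subdivideWithinSample(m, dm, cutoff = cutoff)
    n_sub <- length(unique(sg$subgroup_id))
    tab <- table(m$sample_id)
    if (nrow(m) == 3L && length(tab) == 2L && max(tab) == 2L &&
        n_sub == 3L) {
      tri <- resolveTriplet(m, dm)
      res[[k]] <- data.frame(hg_id = hg, osg_local = 1L,
                             contig_id = tri$kept,
                             provenance = "triplet_rule",
                             stringsAsFactors = FALSE)
      removed <- rbind(removed,
                       data.frame(contig_id = tri$removed, hg_id = hg,
                                  reason = "triplet_rule",
                                  stringsAsFactors = FALSE))
      next
    }
    tree <- NULL
    if (nrow(m) >= 4L) {
      tree <- if (is.null(treeFun)) buildGeneTree(dm) else treeFun(msa, dm)
    }
    osg <- matchSubgroupsToOsgs(sg, dm, tree = tree)
    res[[k]] <- data.frame(hg_id = hg, osg_local = osg$osg_index,
                           contig_id = osg$contig_id,
                           provenance = "subdivided",
                           stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, res)
  # global OSG ids ordered by (hg_id, local index by smallest member)
  key <- paste(all$hg_id, sprintf("%06d", all$osg_local))
  all$osg_id <- sprintf("OSG%05d", match(key, sort(unique(key))))
  cd <- as.data.frame(contigData(contigs))
  out <- data.frame(osg_id = all$osg_id, hg_id = all$hg_id,
                    contig_id = all$contig_id,
                    sample_id = cd$sample_id[match(all$contig_id,
                                                   cd$contig_id)],
                    provenance = all$provenance, stringsAsFactors = FALSE)
  out <- out[order(out$osg_id, out$contig_id), ]
  rownames(out) <- NULL
  if (is.null(removed))
    removed <- data.frame(contig_id = character(), hg_id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  new("OrthologSet", membership = out, removed = removed)
}

#' Write OSG membership as TSV
#'
#' @param x An [OrthologSet].
#' @param path Output path.
#' @export
writeOsgMembership <- function(x, path) {
  write.table(osgMembership(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
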