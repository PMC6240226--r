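#' Trim poor-quality alignment ends
#'
#' Sequencing error concentrates at contig termini, so terminal alignment
#' columns are removed up to the first (and after the last) run of `window`
#' consecutive columns whose non-gap occupancy is at least `occupancyMin`.
#' If no qualifying window exists the alignment is returned unchanged with
#' attribute `noWindow = TRUE` and a warning.
#'
#' @param msa Alignment rows (DNAStringSet or named character vector).
#' @param occupancyMin Minimum fraction of non-gap rows per column;
#'   default 1 (fully occupied).
#' @param window Number of consecutive qualifying columns required;
#'   default 10.
#' @return Trimmed alignment as a named [Biostrings::DNAStringSet].
#' @export
trimMsaEnds <- function(msa, occupancyMin = 1.0, window = 10L) {
  rows <- .as_named_character(msa)
  mat <- do.call(rbind, strsplit(rows, ""))
  occ <- colMeans(mat != "-")
  ok <- occ >= occupancyMin
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  good <- which(runs$values & runs$lengths >= window)
  if (!length(good)) {
    warning("no run of ", window, " columns with occupancy >= ",
            occupancyMin, "; alignment left untrimmed")
    return(structure(DNAStringSet(rows), noWindow = TRUE))
  }
  keep <- starts[good[1]]:ends[good[length(good)]]
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  DNAStringSet(setNames(out, names(rows)))
}

#' Summarize intra- and inter-species distances in one OSG
#'
#' All member pairs are grouped by the species labels of their samples:
#' same-species pairs contribute to that species' intraspecific summary
#' (reported only for species with at least two members), cross-species
#' pairs to the species-pair interspecific summary. Minimum, maximum and
#' arithmetic mean of the pairwise percent p-distances are collected.
#'
#' @param osgId OSG identifier carried into the output.
#' @param members data.frame with columns `contig_id`, `sample_id`,
#'   `species` for the OSG's members.
#' @param msa Trimmed alignment covering the members.
#' @return data.frame with columns `osg_id`, `type` (`intra`/`inter`),
#'   `species1`, `species2`, `dmin`, `dmax`, `davg`, `n_pairs`.
#' @export
summarizeOsg <- function(osgId, members, msa) {
  if (any(is.na(members$species)))
    stop("OSG ", osgId, ": member(s) missing from the sample sheet: ",
         paste(members$contig_id[is.na(members$species)], collapse = ", "))
  dm <- distanceMatrix(msa)
  ids <- members$contig_id
  sp <- members$species
  rows <- NULL
  add <- function(type, s1, s2, vals) {
    rbind(rows, data.frame(osg_id = osgId, type = type, species1 = s1,
                           species2 = s2, dmin = min(vals),
                           dmax = max(vals), davg = mean(vals),
                           n_pairs = length(vals),
                           stringsAsFactors = FALSE))
  }
  for (s in sort(unique(sp))) {
    within <- ids[sp == s]
    if (length(within) >= 2L) {
      vals <- dm[within, within][upper.tri(diag(length(within)))]
      rows <- add("intra", s, s, vals)
    }
  }
  us <- sort(unique(sp))
  if (length(us) >= 2L) {
    for (a in 1:(length(us) - 1L)) for (b in (a + 1L):length(us)) {
      vals <- as.vector(dm[ids[sp == us[a]], ids[sp == us[b]],
                           drop = FALSE])
      rows <- add("inter", us[a], us[b], vals)
    }
  }
  if (is.null(rows))
    rows <- data.frame(osg_id = character(), type = character(),
                       species1 = character(), species2 = character(),
                       dmin = numeric(), dmax = numeric(), davg = numeric(),
                       n_pairs = integer(), stringsAsFactors = FALSE)
  rows
}

#' Summarize every OSG of a run
#'
#' Each OSG with at least two members is re-aligned from its comparison
#' sequences, end-trimmed, and summarized with [summarizeOsg()].
#'
#' @param contigs A [ContigSet].
#' @param orthologs An [OrthologSet].
#' @param aligner See [alignSequences()].
#' @param trim Trim alignment ends before computing distances
#'   (default TRUE).
#' @param occupancyMin,window Passed to [trimMsaEnds()].
#' @return Long-format data.frame of per-OSG summaries.
#' @export
summarizeOsgs <- function(contigs, orthologs, aligner = builtinAligner(),
                          trim = TRUE, occupancyMin = 1.0, window = 10L) {
  seqs <- analysisSeqs(contigs)
  cd <- as.data.frame(contigData(contigs))
  memb <- osgMembership(orthologs)
  memb$species <- cd$species[match(memb$contig_id, cd$contig_id)]
  out <- vector("list", length(unique(memb$osg_id)))
  k <- 0L
  for (osg in unique(memb$osg_id)) {
    m <- memb[memb$osg_id == osg, ]
    if (nrow(m) < 2L) next
    msa <- alignSequences(seqs[m$contig_id], aligner = aligner)
    if (trim)
      msa <- suppressWarnings(trimMsaEnds(msa, occupancyMin, window))
    k <- k + 1L
    out[[k]] <- summarizeOsg(osg, m, msa)
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res))
    res <- data.frame(osg_id = character(), type = character(),
                      species1 = character(), species2 = character(),
                      dmin = numeric(), dmax = numeric(), davg = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-OSG copy, identification and reference flags
#'
#' @param contigs A [ContigSet].
#' @param orthologs An [OrthologSet].
#' @param clusterMap Optional named vector `osg_id -> cluster_id` from
#'   [matchOsgsToClusters()].
#' @return data.frame with columns `osg_id`, `copy_status` (single iff the
#'   parent HG needed no subdividing), `identified` (any member classified
#'   eukaryotic), `reference_cluster_id`.
#' @export
osgFlagTable <- function(contigs, orthologs, clusterMap = NULL) {
  cd <- as.data.frame(contigData(contigs))
  memb <- osgMembership(orthologs)
  ids <- unique(memb$osg_id)
  prov <- memb$provenance[match(ids, memb$osg_id)]
  identified <- vapply(split(memb$contig_id, memb$osg_id)[ids], function(m)
    any(cd$category[match(m, cd$contig_id)] == "eukaryotic"), logical(1))
  flags <- data.frame(osg_id = ids,
                      copy_status = ifelse(prov == "single_copy_hg",
                                           "single", "multi"),
                      identified = identified,
                      reference_cluster_id = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(clusterMap) && length(clusterMap)) {
    idx <- match(flags$osg_id, names(clusterMap))
    flags$reference_cluster_id <- unname(clusterMap[idx])
  }
  flags
}

#' Partition OSG summaries into the three reporting sets
#'
#' `all` contains every OSG; `single_copy_eukaryotic` the OSGs whose parent
#' HG was single-copy and which contain at least one eukaryotic-identified
#' member; `reference_matched` the subset of those with a unique
#' single-copy reference-cluster match. The three sets are nested by
#' construction.
#'
#' @param flags data.frame from [osgFlagTable()].
#' @return Named list of OSG id vectors.
#' @export
partitionSummaries <- function(flags) {
  all <- flags$osg_id
  sce <- flags$osg_id[flags$copy_status == "single" & flags$identified]
  refd <- flags[!is.na(flags$reference_cluster_id), ]
  uniq <- refd$reference_cluster_id %in%
    names(which(table(refd$reference_cluster_id) == 1L))
  refm <- intersect(sce, refd$osg_id[uniq])
  list(all = all, single_copy_eukaryotic = sce, reference_matched = refm)
}

# rows of `summaries` matching a comparison: one species (intra) or a
# species pair (inter)
.comparison_rows <- function(summaries, comparison) {
  comparison <- sort(as.character(comparison))
  if (length(comparison) == 1L)
    summaries$type == "intra" & summaries$species1 == comparison
  else if (length(comparison) == 2L)
    summaries$type == "inter" &
      summaries$species1 == comparison[1] &
      summaries$species2 == comparison[2]
  else stop("comparison must name one species or a species pair")
}

#' Proportion of OSGs with average distance above a cutoff
#'
#' The per-OSG statistic is the average pairwise percent distance for the
#' named comparison; the proportion uses a strict `>` and the denominator
#' counts only OSGs for which the comparison is defined (both partners
#' present).
#'
#' @param summaries Summary data.frame from [summarizeOsgs()], optionally
#'   subset to a partition.
#' @param comparison One species name (intraspecific) or a character vector
#'   of two species (interspecific).
#' @param cutoff Percent cutoff; default 2.
#' @return Fraction in `[0, 1]`.
#' @export
proportionAboveCutoff <- function(summaries, comparison, cutoff = 2.0) {
  sel <- summaries[.comparison_rows(summaries, comparison), ]
  if (!nrow(sel))
    stop("comparison '", paste(comparison, collapse = " vs "),
         "' is not defined for any OSG (no data; this is not a 0 proportion)")
  mean(sel$davg > cutoff)
}

#' Histogram of per-OSG average distances
#'
#' Counts per-OSG average distances for one comparison into half-open bins
#' `[k*w, (k+1)*w)`; the counts sum to the number of OSGs with that
#' comparison defined.
#'
#' @inheritParams proportionAboveCutoff
#' @param binWidth Bin width in percent; default 1.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
distanceHistogram <- function(summaries, comparison, binWidth = 1.0) {
  if (binWidth <= 0) stop("binWidth must be positive")
  sel <- summaries[.comparison_rows(summaries, comparison), ]
  if (!nrow(sel)) {
    warning("comparison '", paste(comparison, collapse = " vs "),
            "' is not defined for any OSG; empty histogram")
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  }
  bins <- floor(sel$davg / binWidth)
  tab <- table(factor(bins, levels = 0:max(bins)))
  data.frame(bin_lo = as.numeric(names(tab)) * binWidth,
             bin_hi = (as.numeric(names(tab)) + 1) * binWidth,
             count = as.integer(tab))
}
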