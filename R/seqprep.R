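#' Remove contigs below a minimum length
#'
#' Contigs shorter than `minLen` base pairs are dropped; the boundary is
#' inclusive (a contig exactly `minLen` long is kept) and input order is
#' preserved. The operation is idempotent.
#'
#' @param x A [ContigSet] or [Biostrings::DNAStringSet].
#' @param minLen Minimum contig length in bp; default 300.
#' @return Object of the same class as `x`, restricted to contigs with
#'   length `>= minLen`.
#' @export
filterByLength <- function(x, minLen = 300L) {
  stopifnot(minLen >= 1L)
  if (methods::is(x, "ContigSet")) {
    keep <- width(contigSeqs(x)) >= minLen
    x[which(keep)]
  } else {
    x[width(x) >= minLen]
  }
}

#' Classify contigs against reference sequence sets
#'
#' Each contig is searched against per-category reference sets (ribosomal,
#' bacterial, eukaryotic) and assigned the category of its best-scoring hit
#' (highest bit score) with E-value at most `evalueMax`; score ties are
#' broken ribosomal > bacterial > eukaryotic so that contaminant-prone
#' categories are removed first. Contigs with no qualifying hit become
#' `"unidentified"`.
#'
#' The E-value threshold of this classification step is a package default
#' (1e-10), independent of the stricter threshold used downstream for
#' homologous-group clustering.
#'
#' @param x A [ContigSet].
#' @param refsets Named list of [Biostrings::DNAStringSet]s; names must be
#'   among `"ribosomal"`, `"bacterial"`, `"eukaryotic"`.
#' @param evalueMax Maximum E-value for a qualifying hit; default `1e-10`.
#' @param engine Search engine, see [builtinEngine()].
#' @return `x` with `contigData(x)$category` filled in; categories partition
#'   the set.
#' @export
classifyContigs <- function(x, refsets, evalueMax = 1e-10,
                            engine = builtinEngine()) {
  stopifnot(is.list(refsets), length(refsets) >= 1L)
  bad <- setdiff(names(refsets), c("ribosomal", "bacterial", "eukaryotic"))
  if (length(bad))
    stop("unknown reference categories: ", paste(bad, collapse = ", "))
  seqs <- contigSeqs(x)
  best_cat <- rep("unidentified", length(seqs))
  best_bit <- rep(-Inf, length(seqs))
  for (cat in intersect(c("ribosomal", "bacterial", "eukaryotic"),
                        names(refsets))) {
    hits <- searchHits(seqs, refsets[[cat]], engine = engine,
                       evalueMax = evalueMax)
    if (!nrow(hits)) next
    top <- vapply(split(hits$bitscore, hits$query_id), max, numeric(1))
    idx <- match(names(top), names(seqs))
    # strictly better wins; ties keep the earlier (higher-priority) category
    upd <- top > best_bit[idx]
    best_bit[idx[upd]] <- top[upd]
    best_cat[idx[upd]] <- cat
  }
  cd <- x@contigData
  cd$category <- best_cat
  methods::initialize(x, contigData = cd)
}

# Longest ORF over the 6 frames of one sequence (character scalar).
# Returns the ORF in the sense orientation of the reading frame, stop codon
# excluded; an ORF with no downstream stop runs to the last complete codon.
# Tie-break: longest first, then frame order +1,+2,+3,-1,-2,-3, then
# leftmost start.
.longest_orf <- function(seq) {
  rev <- as.character(reverseComplement(DNAStringSet(seq)))
  best <- NULL
  frame_rank <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rev
    L <- nchar(s)
    for (off in 0:2) {
      frame_rank <- frame_rank + 1L
      if (L - 2L < 1L + off) next
      starts <- seq.int(1L + off, L - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      if (!any(is_atg)) next
      # segment = run of codons ending just before each stop (or seq end)
      seg <- cumsum(c(0L, head(is_stop, -1L)))
      for (g in unique(seg[is_atg])) {
        in_seg <- seg == g & !is_stop
        first_atg <- which(is_atg & seg == g)[1]
        last_codon <- max(which(in_seg))
        if (is.na(first_atg) || last_codon < first_atg) next
        len <- (last_codon - first_atg + 1L) * 3L
        cand <- list(orf = substr(s, starts[first_atg],
                                  starts[last_codon] + 2L),
                     len = len, frame = frame_rank,
                     start = starts[first_atg])
        if (is.null(best) ||
            cand$len > best$len ||
            (cand$len == best$len && (cand$frame < best$frame ||
             (cand$frame == best$frame && cand$start < best$start))))
          best <- cand
      }
    }
  }
  best
}

#' Extract coding sequences by the longest-ORF rule
#'
#' For each contig the longest open reading frame (ATG to the next in-frame
#' stop, stop codon excluded; open-ended at the 3' terminus if no stop
#' occurs) is located across all six reading frames and returned in the
#' sense orientation of its frame. Contigs whose longest ORF is shorter than
#' `minOrfLen` get no CDS. This deliberately simple rule trims non-coding
#' regions; it is not a full coding-potential model, and the CDS source is
#' pluggable downstream.
#'
#' @param x A [ContigSet] (or a single character/DNAString sequence, in
#'   which case the CDS string or `NULL` is returned).
#' @param minOrfLen Minimum ORF length in nt; default 300.
#' @return `x` with `cdsSeqs(x)` populated for contigs with a qualifying
#'   ORF.
#' @export
extractCds <- function(x, minOrfLen = 300L) {
  if (!methods::is(x, "ContigSet")) {
    orf <- .longest_orf(toupper(as.character(x)))
    if (is.null(orf) || orf$len < minOrfLen) return(NULL)
    return(orf$orf)
  }
  seqs <- as.character(contigSeqs(x))
  cds <- character()
  for (id in names(seqs)) {
    if (nchar(seqs[[id]]) < 3L) next
    orf <- .longest_orf(seqs[[id]])
    if (!is.null(orf) && orf$len >= minOrfLen) cds[[id]] <- orf$orf
  }
  methods::initialize(x, cds = DNAStringSet(cds))
}
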