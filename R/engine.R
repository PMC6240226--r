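#' Built-in similarity search engine
#'
#' A k-mer-seeded, banded local-alignment search. Candidate pairs share at
#' least one exact k-mer; each candidate is aligned by banded Smith-Waterman
#' around the modal seed diagonal, and significance is assessed with the
#' ungapped Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)` on
#' the raw score `S` (`m`, `n` the sequence lengths).
#'
#' @param k Seed k-mer length.
#' @param match,mismatch Match/mismatch scores (N counts as a mismatch).
#' @param gapOpen,gapExt Affine gap penalties; a gap of length g costs
#'   `gapOpen + g * gapExt`.
#' @param K,lambda Karlin-Altschul parameters for the E-value (nat-scaled
#'   score).
#' @param band Half-width of the alignment band around the seed diagonal.
#' @param maxKmerOcc Seeds occurring at more positions than this are skipped
#'   as low-complexity.
#' @return An engine object usable by [allVsAllHits()], [searchHits()],
#'   [classifyContigs()] and [buildReferenceClusters()].
#' @export
builtinEngine <- function(k = 12L, match = 1L, mismatch = -1L,
                          gapOpen = -4, gapExt = -1,
                          K = 0.13, lambda = 0.318,
                          band = 16L, maxKmerOcc = 100L) {
  structure(list(k = as.integer(k), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gapOpen = gapOpen, gapExt = gapExt,
                 K = K, lambda = lambda, band = as.integer(band),
                 maxKmerOcc = as.integer(maxKmerOcc)),
            class = c("builtin_engine", "search_engine"))
}

#' External tabular-hit engine adapter
#'
#' Wraps a precomputed 12-column tabular hit file (the classic tabular
#' output of external search tools) so it can stand in for the built-in
#' engine in [allVsAllHits()].
#'
#' @param path Path to a 12-column tab-separated hit file with columns
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore (1-based inclusive coordinates).
#' @return An engine object.
#' @export
tabularHitsEngine <- function(path) {
  structure(list(path = path),
            class = c("tabular_engine", "search_engine"))
}

#' Read a 12-column tabular hit file
#'
#' Coordinates are converted from 1-based inclusive to the 0-based half-open
#' convention used internally; minus-strand subject coordinates (start >
#' end) are normalized to start < end.
#'
#' @param path Path to the tab-separated file (no header).
#' @return A hit data.frame.
#' @export
readTabularHits <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  h <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               stringsAsFactors = FALSE),
    error = function(e) stop("failed to read tabular hits from '", path,
                             "': ", conditionMessage(e)))
  flip <- h$sstart > h$send
  tmp <- h$sstart[flip]; h$sstart[flip] <- h$send[flip]; h$send[flip] <- tmp
  h$qstart <- h$qstart - 1L
  h$sstart <- h$sstart - 1L
  h
}

#' Write hits as a 12-column tabular file
#'
#' @param hits Hit data.frame (internal 0-based half-open coordinates).
#' @param path Output path.
#' @export
writeTabularHits <- function(hits, path) {
  out <- hits[c("query_id", "subject_id", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")]
  out$qstart <- out$qstart + 1L
  out$sstart <- out$sstart + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.as_named_character <- function(x) {
  s <- as.character(x)
  names(s) <- names(x)
  if (is.null(names(s))) stop("sequences must be named")
  s
}

#' All-vs-all similarity search
#'
#' Runs the search engine over all ordered pairs of contigs and returns
#' hits with E-value at most `evalueMax`; self-hits are excluded. With the
#' built-in engine each unordered pair is aligned once and reported in both
#' orientations.
#'
#' @param x A [ContigSet] or named [Biostrings::DNAStringSet]. For a
#'   `ContigSet` the extracted CDS is used where present, the full contig
#'   otherwise.
#' @param engine [builtinEngine()] or [tabularHitsEngine()].
#' @param evalueMax Maximum reported E-value.
#' @return Hit data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`
#'   (0-based half-open), `score` (built-in only), `bitscore`, `evalue`.
#' @export
allVsAllHits <- function(x, engine = builtinEngine(), evalueMax = 1e-15) {
  seqs <- if (methods::is(x, "ContigSet")) analysisSeqs(x) else x
  if (length(seqs) < 2L) stop("need at least 2 contigs")
  if (inherits(engine, "tabular_engine")) {
    h <- readTabularHits(engine$path)
    h <- h[h$query_id != h$subject_id & h$evalue <= evalueMax, ]
    unknown <- setdiff(unique(c(h$query_id, h$subject_id)), names(seqs))
    if (length(unknown))
      stop("hit file '", engine$path, "' references unknown contigs: ",
           paste(head(unknown, 5), collapse = ", "))
    rownames(h) <- NULL
    return(h)
  }
  s <- .as_named_character(seqs)
  h <- search_hits_cpp(s, s, TRUE,
                       k = engine$k, band_extra = engine$band,
                       match = engine$match, mismatch = engine$mismatch,
                       gap_open = engine$gapOpen, gap_ext = engine$gapExt,
                       K = engine$K, lambda = engine$lambda,
                       evalue_max = evalueMax,
                       max_kmer_occ = engine$maxKmerOcc)
  h <- h[order(h$query_id, h$subject_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Search one sequence set against another
#'
#' Cross-search used for classification, OSG-to-cluster matching, and
#' reciprocal-best-hit construction.
#'
#' @param query,subject Named [Biostrings::DNAStringSet]s (or named
#'   character vectors).
#' @inheritParams allVsAllHits
#' @return Hit data.frame as in [allVsAllHits()].
#' @export
searchHits <- function(query, subject, engine = builtinEngine(),
                       evalueMax = 1e-15) {
  q <- .as_named_character(query)
  s <- .as_named_character(subject)
  h <- search_hits_cpp(q, s, FALSE,
                       k = engine$k, band_extra = engine$band,
                       match = engine$match, mismatch = engine$mismatch,
                       gap_open = engine$gapOpen, gap_ext = engine$gapExt,
                       K = engine$K, lambda = engine$lambda,
                       evalue_max = evalueMax,
                       max_kmer_occ = engine$maxKmerOcc)
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  h <- h[order(h$query_id, h$subject_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Sequences used for comparison: CDS where extracted, contig otherwise
#'
#' @param x A [ContigSet].
#' @return Named [Biostrings::DNAStringSet].
#' @export
analysisSeqs <- function(x) {
  seqs <- contigSeqs(x)
  cds <- cdsSeqs(x)
  if (length(cds)) {
    idx <- match(names(cds), names(seqs))
    seqs[idx] <- cds
  }
  seqs
}
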