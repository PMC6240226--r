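#' Built-in progressive aligner
#'
#' Progressive multiple alignment: the longest sequence (ties broken by id)
#' seeds the profile, the remaining sequences are added in decreasing order
#' of their pairwise global-alignment score against the seed, and each is
#' aligned to the growing profile by affine-gap dynamic programming
#' ("once a gap, always a gap"). Pairwise steps use Needleman-Wunsch with
#' match +1, mismatch -1, gap open -4, gap extend -1.
#'
#' @param match,mismatch,gapOpen,gapExt Scoring parameters.
#' @return An aligner object for [alignSequences()].
#' @export
builtinAligner <- function(match = 1L, mismatch = -1L,
                           gapOpen = -4, gapExt = -1) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = gapOpen, gapExt = gapExt),
            class = c("builtin_aligner", "msa_aligner"))
}

#' External aligner adapter
#'
#' Wraps a command-line multiple aligner that reads FASTA on stdin-style
#' file arguments and writes aligned FASTA (e.g. `mafft`). Provided as a
#' production-parity seam; the built-in aligner is the default everywhere.
#'
#' @param command Executable name or path (default `"mafft"`).
#' @param args Extra command-line arguments before the input path.
#' @return An aligner object for [alignSequences()].
#' @export
externalAligner <- function(command = "mafft",
                            args = c("--quiet", "--auto")) {
  structure(list(command = command, args = args),
            class = c("external_aligner", "msa_aligner"))
}

#' Multiple sequence alignment
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector;
#'   at least one non-empty sequence.
#' @param aligner [builtinAligner()] (default) or [externalAligner()].
#' @return A named [Biostrings::DNAStringSet] of equal-length gapped rows in
#'   the input order; removing gaps from a row reproduces its input
#'   sequence.
#' @export
alignSequences <- function(seqs, aligner = builtinAligner()) {
  s <- .as_named_character(seqs)
  if (!length(s)) stop("no sequences to align")
  if (any(nchar(s) == 0L)) stop("empty sequence in alignment input")
  if (length(s) == 1L) return(DNAStringSet(s))
  if (inherits(aligner, "external_aligner")) {
    rows <- .run_external_aligner(s, aligner)
  } else {
    ord <- order(-nchar(s), names(s))
    center <- ord[1]
    rest <- ord[-1]
    if (length(rest) > 1L) {
      sc <- vapply(rest, function(i)
        nw_align_cpp(s[[center]], s[[i]], aligner$match, aligner$mismatch,
                     aligner$gapOpen, aligner$gapExt)$score, numeric(1))
      rest <- rest[order(-sc, names(s)[rest])]
    }
    first <- nw_align_cpp(s[[center]], s[[rest[1]]], aligner$match,
                          aligner$mismatch, aligner$gapOpen, aligner$gapExt)
    prof <- c(first$a, first$b)
    prof_names <- c(names(s)[center], names(s)[rest[1]])
    for (i in rest[-1]) {
      pa <- profile_align_cpp(prof, s[[i]], aligner$match, aligner$mismatch,
                              aligner$gapOpen, aligner$gapExt)
      prof <- c(pa$rows, pa$seq)
      prof_names <- c(prof_names, names(s)[i])
    }
    rows <- setNames(prof, prof_names)[names(s)]
  }
  stopifnot(identical(gsub("-", "", rows, fixed = TRUE), s))
  DNAStringSet(rows)
}

.run_external_aligner <- function(s, aligner) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeXStringSet(DNAStringSet(s), fin, width = 60L)
  status <- tryCatch(
    system2(aligner$command, c(aligner$args, fin), stdout = fout),
    error = function(e) stop("external aligner '", aligner$command,
                             "' failed: ", conditionMessage(e)))
  if (!identical(status, 0L))
    stop("external aligner '", aligner$command, "' exited with status ",
         status)
  aln <- readDNAStringSet(fout)
  names(aln) <- sub("\\s.*$", "", names(aln))
  rows <- toupper(as.character(aln))[names(s)]
  setNames(rows, names(s))
}

#' Uncorrected p-distance between two alignment rows
#'
#' `100 * mismatches / compared`, where compared columns are those with a
#' non-gap, non-N character in both rows (pairwise deletion). When no
#' column is comparable the distance is 0 with a warning and attribute
#' `noOverlap = TRUE`.
#'
#' @param msa Alignment from [alignSequences()] (DNAStringSet or named
#'   character vector of equal-length rows).
#' @param i,j Row labels.
#' @return Percent distance in `[0, 100]`.
#' @export
pDistance <- function(msa, i, j) {
  rows <- .as_named_character(msa)
  if (!all(c(i, j) %in% names(rows)))
    stop("unknown row label(s): ",
         paste(setdiff(c(i, j), names(rows)), collapse = ", "))
  d <- p_distance_cpp(rows[[i]], rows[[j]])
  if (d < 0) {
    warning("no comparable columns between '", i, "' and '", j,
            "'; returning 0")
    return(structure(0, noOverlap = TRUE))
  }
  d
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param msa Alignment rows (DNAStringSet or named character).
#' @return Symmetric labeled matrix of percent distances; zero diagonal.
#'   Non-overlapping pairs are scored 0 and flagged in the `"noOverlap"`
#'   attribute matrix.
#' @export
distanceMatrix <- function(msa) {
  rows <- .as_named_character(msa)
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  noov <- matrix(FALSE, n, n, dimnames = dimnames(D))
  if (n >= 2L) {
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      d <- p_distance_cpp(rows[[a]], rows[[b]])
      if (d < 0) { d <- 0; noov[a, b] <- noov[b, a] <- TRUE }
      D[a, b] <- D[b, a] <- d
    }
  }
  structure(D, noOverlap = noov)
}
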