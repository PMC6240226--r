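#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `fasta_path`,
#' `species`, `clade`, mapping each transcriptome sample to its contig FASTA
#' and to the species/clade labels used for intra- vs inter-species distance
#' grouping.
#'
#' @param path Path to a tab-separated file, or a data.frame with the same
#'   columns.
#' @return A data.frame with the four required columns.
#' @export
readSampleSheet <- function(path) {
  sheet <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fasta_path", "species", "clade")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("sample_ids must be unique")
  if (!is.data.frame(path)) {
    # resolve relative FASTA paths against the sheet's directory
    rel <- !grepl("^(/|[A-Za-z]:)", sheet$fasta_path)
    sheet$fasta_path[rel] <- file.path(dirname(path), sheet$fasta_path[rel])
  }
  sheet[need]
}

#' Load contigs for the samples in a sample sheet
#'
#' Reads one FASTA per sample and assembles a single [ContigSet]. Sequences
#' are uppercased; FASTA ids (the first whitespace-delimited token of each
#' header) become contig ids and must be unique across samples.
#'
#' @param sampleSheet Data.frame or TSV path accepted by [readSampleSheet()].
#' @return A [ContigSet] with category `"unclassified"` throughout.
#' @export
readContigs <- function(sampleSheet) {
  sheet <- readSampleSheet(sampleSheet)
  seqs <- vector("list", nrow(sheet))
  meta <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    s <- readDNAStringSet(sheet$fasta_path[i])
    names(s) <- sub("\\s.*$", "", names(s))
    seqs[[i]] <- s
    meta[[i]] <- data.frame(contig_id = names(s),
                            sample_id = sheet$sample_id[i],
                            species = sheet$species[i],
                            clade = sheet$clade[i],
                            category = "unclassified",
                            stringsAsFactors = FALSE)
  }
  allseq <- do.call(c, seqs)
  md <- do.call(rbind, meta)
  if (anyDuplicated(names(allseq)))
    stop("contig ids must be unique across samples")
  new("ContigSet", sequences = allseq, contigData = DataFrame(md),
      cds = DNAStringSet())
}

#' Construct a ContigSet from sequences in memory
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @param sampleId Sample label, recycled over contigs.
#' @param species,clade Species and clade labels, recycled.
#' @param category Initial category, default `"unclassified"`.
#' @return A [ContigSet].
#' @export
ContigSet <- function(sequences, sampleId, species = NA_character_,
                      clade = NA_character_, category = "unclassified") {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("sequences must be named")
  n <- length(sequences)
  md <- data.frame(contig_id = names(sequences),
                   sample_id = rep_len(sampleId, n),
                   species = rep_len(species, n),
                   clade = rep_len(clade, n),
                   category = rep_len(category, n),
                   stringsAsFactors = FALSE)
  new("ContigSet", sequences = sequences, contigData = DataFrame(md),
      cds = DNAStringSet())
}

#' Combine ContigSets from several samples
#'
#' @param ... [ContigSet] objects with disjoint contig ids.
#' @return A single [ContigSet].
#' @export
combineContigSets <- function(...) {
  xs <- list(...)
  seqs <- do.call(c, lapply(xs, contigSeqs))
  cds <- do.call(c, lapply(xs, cdsSeqs))
  md <- do.call(rbind, lapply(xs, function(x) as.data.frame(contigData(x))))
  if (anyDuplicated(names(seqs)))
    stop("contig ids must be unique across samples")
  new("ContigSet", sequences = seqs, contigData = DataFrame(md), cds = cds)
}

#' Write one FASTA per sample and category
#'
#' Emits `<sample>.<category>.fasta` files (60-column wrapped) for every
#' sample/category combination present in `x`.
#'
#' @param x A classified [ContigSet].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCategoryFastas <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- as.data.frame(contigData(x))
  paths <- character()
  for (s in unique(cd$sample_id)) {
    for (cat in unique(cd$category[cd$sample_id == s])) {
      sel <- cd$sample_id == s & cd$category == cat
      p <- file.path(dir, sprintf("%s.%s.fasta", s, cat))
      writeXStringSet(contigSeqs(x)[sel], p, width = 60L)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
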