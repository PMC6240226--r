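#' Specification for the synthetic transcriptome generator
#'
#' Describes a multi-sample, multi-species transcriptome simulation with
#' known ortholog/paralog structure. The defaults encode the reference
#' study conditions used throughout the package's end-to-end validation:
#' 300 gene families of 1 kb, two same-species samples diverging at 0.5%
#' plus one sister species at a mean of 14%, a 10% pre-speciation paralog
#' rate, 20% transcript dropout, and elevated substitution error on 2% of
#' sequence termini.
#'
#' @slot nFamilies Number of gene families.
#' @slot lengthRange Min and max ancestral gene length (nt).
#' @slot samples data.frame with `sample_id`, `species`, `clade`.
#' @slot intraDivergence Per-site substitution probability between
#'   same-species samples (split evenly across the two sample branches).
#' @slot interMean,interSd Mean and sd of the per-site substitution
#'   probability separating each non-baseline species from the family
#'   ancestor (draws truncated to `[0, 0.75]`).
#' @slot paralogRate Probability that a family carries a pre-speciation
#'   duplicate.
#' @slot paralogDivergence Per-site divergence of the duplicate's ancestor.
#' @slot dropoutRate Probability that a given family copy is absent from a
#'   given sample.
#' @slot endErrorRate Probability that a contig terminus carries elevated
#'   error.
#' @slot endErrorSpan Length (nt) of the error-affected terminal span.
#' @slot endErrorProb Per-site substitution probability within an affected
#'   span.
#' @slot indelRate Optional per-site indel probability on sample branches
#'   (0 by default; substitution-only matches what p-distances measure).
#' @slot identifiedFraction Fraction of families whose ancestor is emitted
#'   in the eukaryotic reference set (these become "identified").
#' @slot refClusterFraction Fraction of families represented in the two
#'   reference genome gene sets.
#' @slot refDivergence Divergence of the two reference genomes' genes from
#'   the family ancestor.
#' @slot seed Integer seed; a fixed seed gives byte-identical outputs.
#'
#' @seealso [syntheticSpec()], [simulateTranscriptomes()]
#' @export
setClass("SyntheticSpec",
  slots = c(nFamilies = "integer", lengthRange = "integer",
            samples = "data.frame",
            intraDivergence = "numeric", interMean = "numeric",
            interSd = "numeric", paralogRate = "numeric",
            paralogDivergence = "numeric", dropoutRate = "numeric",
            endErrorRate = "numeric", endErrorSpan = "integer",
            endErrorProb = "numeric", indelRate = "numeric",
            identifiedFraction = "numeric", refClusterFraction = "numeric",
            refDivergence = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  probs <- c(intra = object@intraDivergence, interMean = object@interMean,
             paralogRate = object@paralogRate,
             paralogDivergence = object@paralogDivergence,
             dropout = object@dropoutRate, endErrorRate = object@endErrorRate,
             endErrorProb = object@endErrorProb, indel = object@indelRate,
             identified = object@identifiedFraction,
             refCluster = object@refClusterFraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste("probabilities outside [0,1]:",
                        paste(bad, collapse = ", ")))
  if (object@nFamilies < 1L) msg <- c(msg, "nFamilies must be >= 1")
  if (length(object@lengthRange) != 2L ||
      any(object@lengthRange < 1L) ||
      object@lengthRange[1] > object@lengthRange[2])
    msg <- c(msg, "lengthRange must be c(min, max) with 1 <= min <= max")
  if (!all(c("sample_id", "species", "clade") %in%
             colnames(object@samples)) ||
      anyDuplicated(object@samples$sample_id))
    msg <- c(msg, "samples needs unique sample_id plus species and clade")
  if (object@interSd < 0) msg <- c(msg, "interSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-data specification
#'
#' @param nFamilies,lengthRange,samples,intraDivergence,interMean,interSd
#'   See [SyntheticSpec-class].
#' @param paralogRate,paralogDivergence,dropoutRate,endErrorRate See
#'   [SyntheticSpec-class].
#' @param endErrorSpan,endErrorProb,indelRate,identifiedFraction See
#'   [SyntheticSpec-class].
#' @param refClusterFraction,refDivergence,seed See [SyntheticSpec-class].
#' @return A validated [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(nFamilies = 300L,
                          lengthRange = c(1000L, 1000L),
                          samples = data.frame(
                            sample_id = c("cpA_rep1", "cpA_rep2", "cpB"),
                            species = c("speciesA", "speciesA", "speciesB"),
                            clade = c("cladeI", "cladeI", "cladeI"),
                            stringsAsFactors = FALSE),
                          intraDivergence = 0.005,
                          interMean = 0.14, interSd = 0.02,
                          paralogRate = 0.1, paralogDivergence = 0.10,
                          dropoutRate = 0.2,
                          endErrorRate = 0.02, endErrorSpan = 100L,
                          endErrorProb = 0.15,
                          indelRate = 0,
                          identifiedFraction = 0.75,
                          refClusterFraction = 0.6,
                          refDivergence = c(0.10, 0.15),
                          seed = 1L) {
  new("SyntheticSpec", nFamilies = as.integer(nFamilies),
      lengthRange = as.integer(lengthRange), samples = samples,
      intraDivergence = intraDivergence, interMean = interMean,
      interSd = interSd, paralogRate = paralogRate,
      paralogDivergence = paralogDivergence, dropoutRate = dropoutRate,
      endErrorRate = endErrorRate, endErrorSpan = as.integer(endErrorSpan),
      endErrorProb = endErrorProb, indelRate = indelRate,
      identifiedFraction = identifiedFraction,
      refClusterFraction = refClusterFraction,
      refDivergence = refDivergence, seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

# substitute each site with probability p, always to a different base;
# x is a character vector of single bases
.mutate <- function(x, p) {
  if (p <= 0) return(x)
  hit <- which(runif(length(x)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(x[hit], .BASES)
    x[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  x
}

# apply indels: each site deleted with prob p/2 or followed by a random
# insertion with prob p/2
.indel <- function(x, p) {
  if (p <= 0) return(x)
  u <- runif(length(x))
  del <- u < p / 2
  ins <- u >= p / 2 & u < p
  out <- x[!del]
  if (any(ins)) {
    pos <- which(ins)
    pos <- pos[!del[pos]]
    keepmap <- cumsum(!del)
    for (q in rev(pos)) {
      at <- keepmap[q]
      out <- append(out, sample(.BASES, 1L), after = at)
    }
  }
  out
}

#' Simulate multi-sample transcriptomes with known truth
#'
#' Ancestral gene sequences are drawn uniformly over A/C/G/T; the first
#' species in the sample sheet carries the ancestral state and every other
#' species diverges by i.i.d. substitutions at a per-family rate drawn from
#' `N(interMean, interSd)`. Pre-speciation paralogs duplicate the ancestor
#' at `paralogDivergence` before species divergence, so every sample can
#' carry both copies. Same-species samples each receive
#' `intraDivergence / 2` of additional substitution. Dropout removes each
#' family copy from each sample independently, and terminal error
#' substitutes sites at `endErrorProb` within `endErrorSpan` of an affected
#' terminus. Realized (not nominal) pairwise divergences are recorded in
#' the divergence ledger.
#'
#' @param spec A [SyntheticSpec-class].
#' @param outDir Optional directory; when given, per-sample FASTA files
#'   (60-column), `samples.tsv`, `truth.tsv`, `divergences.tsv` and the
#'   synthetic reference FASTAs are written there.
#' @return List with elements `sequences` (named list of per-sample
#'   [Biostrings::DNAStringSet]), `sampleSheet`, `truth` (one row per
#'   emitted contig: family, copy, paralog and end-damage flags), `dive`
#'   (realized ortholog-pair divergences), `refEuk`, `genomeA`, `genomeB`
#'   (reference sets), `files` (paths, when written) and `spec`.
#' @export
simulateTranscriptomes <- function(spec, outDir = NULL) {
  methods::validObject(spec)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed,
                               envir = globalenv()), add = TRUE)
  set.seed(spec@seed)

  samples <- spec@samples
  species <- unique(samples$species)
  n_id <- round(spec@identifiedFraction * spec@nFamilies)
  n_rc <- round(spec@refClusterFraction * spec@nFamilies)

  seqs <- lapply(samples$sample_id, function(s) character())
  names(seqs) <- samples$sample_id
  truth <- vector("list", spec@nFamilies)
  dive <- vector("list", spec@nFamilies)
  refEuk <- character(); genomeA <- character(); genomeB <- character()

  for (f in seq_len(spec@nFamilies)) {
    fam <- sprintf("F%04d", f)
    L <- if (spec@lengthRange[1] == spec@lengthRange[2])
      spec@lengthRange[1] else
      sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
    anc <- sample(.BASES, L, replace = TRUE)
    n_copies <- 1L + rbinom(1L, 1L, spec@paralogRate)
    copies <- list(anc)
    if (n_copies == 2L) copies[[2]] <- .mutate(anc, spec@paralogDivergence)
    # species-level sequences per copy
    spseq <- list()
    for (sp_i in seq_along(species)) {
      d <- if (sp_i == 1L) 0 else
        min(max(rnorm(1L, spec@interMean, spec@interSd), 0), 0.75)
      spseq[[sp_i]] <- lapply(copies, .mutate, p = d)
    }
    fam_rows <- NULL
    fam_seqs <- list()
    for (si in seq_len(nrow(samples))) {
      sp_i <- match(samples$species[si], species)
      for (cp in seq_len(n_copies)) {
        if (runif(1L) < spec@dropoutRate) next
        x <- .mutate(spseq[[sp_i]][[cp]], spec@intraDivergence / 2)
        x <- .indel(x, spec@indelRate)
        dam5 <- runif(1L) < spec@endErrorRate
        dam3 <- runif(1L) < spec@endErrorRate
        if (dam5) {
          span <- seq_len(min(spec@endErrorSpan, length(x)))
          x[span] <- .mutate(x[span], spec@endErrorProb)
        }
        if (dam3) {
          span <- seq.int(max(1L, length(x) - spec@endErrorSpan + 1L),
                          length(x))
          x[span] <- .mutate(x[span], spec@endErrorProb)
        }
        cid <- sprintf("%s_%sc%d", samples$sample_id[si], fam, cp)
        seqs[[samples$sample_id[si]]][[cid]] <- paste(x, collapse = "")
        fam_seqs[[cid]] <- x
        fam_rows <- rbind(fam_rows, data.frame(
          contig_id = cid, sample_id = samples$sample_id[si],
          species = samples$species[si], family = fam, copy = cp,
          paralog = n_copies == 2L, damaged_5p = dam5, damaged_3p = dam3,
          length = length(x), stringsAsFactors = FALSE))
      }
    }
    truth[[f]] <- fam_rows
    # realized divergences between ortholog (same-copy) pairs
    if (!is.null(fam_rows)) {
      for (cp in unique(fam_rows$copy)) {
        ids <- fam_rows$contig_id[fam_rows$copy == cp]
        if (length(ids) >= 2L) {
          prs <- utils::combn(sort(ids), 2L)
          dd <- apply(prs, 2L, function(pr) {
            a <- fam_seqs[[pr[1]]]; b <- fam_seqs[[pr[2]]]
            n <- min(length(a), length(b))
            mean(a[seq_len(n)] != b[seq_len(n)])
          })
          dive[[f]] <- rbind(dive[[f]], data.frame(
            family = fam, copy = cp, contig1 = prs[1, ], contig2 = prs[2, ],
            divergence = dd, stringsAsFactors = FALSE))
        }
      }
    }
    if (f <= n_id) refEuk[[sprintf("ref_%s", fam)]] <-
      paste(anc, collapse = "")
    if (f <= n_rc) {
      genomeA[[sprintf("gA_%s", fam)]] <-
        paste(.mutate(anc, spec@refDivergence[1]), collapse = "")
      genomeB[[sprintf("gB_%s", fam)]] <-
        paste(.mutate(anc, spec@refDivergence[2]), collapse = "")
    }
  }

  truth <- do.call(rbind, truth)
  dive <- do.call(rbind, dive)
  sequences <- lapply(seqs, function(s) DNAStringSet(unlist(s)))
  sheet <- data.frame(sample_id = samples$sample_id,
                      fasta_path = sprintf("%s.fasta", samples$sample_id),
                      species = samples$species, clade = samples$clade,
                      stringsAsFactors = FALSE)
  out <- list(sequences = sequences, sampleSheet = sheet, truth = truth,
              dive = dive, refEuk = DNAStringSet(refEuk),
              genomeA = DNAStringSet(genomeA),
              genomeB = DNAStringSet(genomeB), files = NULL, spec = spec)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (s in names(sequences)) {
      p <- file.path(outDir, sprintf("%s.fasta", s))
      writeXStringSet(sequences[[s]], p, width = 60L)
      files[s] <- p
    }
    sheet$fasta_path <- unname(files[sheet$sample_id])
    write.table(sheet, file.path(outDir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dive, file.path(outDir, "divergences.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeXStringSet(out$refEuk, file.path(outDir, "ref_eukaryotic.fasta"),
                    width = 60L)
    writeXStringSet(out$genomeA, file.path(outDir, "genomeA.fasta"),
                    width = 60L)
    writeXStringSet(out$genomeB, file.path(outDir, "genomeB.fasta"),
                    width = 60L)
    out$sampleSheet <- sheet
    out$files <- c(files,
                   samples = file.path(outDir, "samples.tsv"),
                   truth = file.path(outDir, "truth.tsv"))
  }
  out
}

#' Contigs of a simulation as a ContigSet
#'
#' @param sim Result of [simulateTranscriptomes()].
#' @return A [ContigSet] covering all samples.
#' @export
simContigSet <- function(sim) {
  sets <- lapply(seq_len(nrow(sim$sampleSheet)), function(i)
    ContigSet(sim$sequences[[sim$sampleSheet$sample_id[i]]],
              sampleId = sim$sampleSheet$sample_id[i],
              species = sim$sampleSheet$species[i],
              clade = sim$sampleSheet$clade[i]))
  do.call(combineContigSets, sets)
}

#' Score pipeline output against simulation truth
#'
#' OSGs are matched to true ortholog families (a family being one copy of
#' one gene family) by majority membership. Reported metrics:
#' * `family_purity`: fraction of multi-member OSGs whose members all come
#'   from one true family;
#' * `ortholog_recall`: fraction of true families whose surviving members
#'   (those not removed by the triplet rule) all landed in a single OSG;
#' * `paralog_split_rate`: among families with both gene copies surviving,
#'   the fraction whose two copies were correctly placed in disjoint OSGs;
#' * `prop_intra_le2` / `prop_inter_le2`: proportion of OSG intraspecific /
#'   interspecific average distances at or below 2%, when summaries are
#'   supplied.
#'
#' @param orthologs An [OrthologSet] from the pipeline run.
#' @param truth Truth table from [simulateTranscriptomes()].
#' @param summaries Optional summary data.frame from [summarizeOsgs()].
#' @return Named list of metrics.
#' @export
evaluateRecovery <- function(orthologs, truth, summaries = NULL) {
  memb <- osgMembership(orthologs)
  unknown <- setdiff(memb$contig_id, truth$contig_id)
  if (length(unknown))
    stop("pipeline output references contigs absent from truth: ",
         paste(head(unknown, 5), collapse = ", "))
  key <- paste(truth$family, truth$copy, sep = ".")
  fam_of <- setNames(key, truth$contig_id)
  memb$fam <- unname(fam_of[memb$contig_id])

  by_osg <- split(memb$fam, memb$osg_id)
  multi <- by_osg[lengths(by_osg) >= 2L]
  purity <- if (length(multi))
    mean(vapply(multi, function(f) length(unique(f)) == 1L, logical(1)))
  else NA_real_

  removed <- removedContigs(orthologs)$contig_id
  surv <- truth[!(truth$contig_id %in% removed), ]
  surv_key <- paste(surv$family, surv$copy, sep = ".")
  by_fam <- split(surv$contig_id, surv_key)
  osg_of <- setNames(memb$osg_id, memb$contig_id)
  recall <- mean(vapply(by_fam, function(ids) {
    o <- unique(osg_of[ids])
    length(o) == 1L && !any(is.na(o))
  }, logical(1)))

  two_copy <- unique(surv$family[surv$copy == 2L])
  split_ok <- vapply(two_copy, function(fm) {
    o1 <- unique(osg_of[surv$contig_id[surv$family == fm & surv$copy == 1L]])
    o2 <- unique(osg_of[surv$contig_id[surv$family == fm & surv$copy == 2L]])
    length(o1) > 0 && length(o2) > 0 && !length(intersect(o1, o2))
  }, logical(1))
  paralog_split_rate <- if (length(two_copy)) mean(split_ok) else NA_real_

  prop_intra <- prop_inter <- NA_real_
  if (!is.null(summaries) && nrow(summaries)) {
    intra <- summaries$davg[summaries$type == "intra"]
    inter <- summaries$davg[summaries$type == "inter"]
    if (length(intra)) prop_intra <- mean(intra <= 2.0)
    if (length(inter)) prop_inter <- mean(inter <= 2.0)
  }
  list(family_purity = purity, ortholog_recall = recall,
       paralog_split_rate = paralog_split_rate,
       prop_intra_le2 = prop_intra, prop_inter_le2 = prop_inter)
}
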