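test_that("a fixed seed reproduces the simulation byte for byte", {
  spec <- syntheticSpec(nFamilies = 15L, lengthRange = c(400L, 600L),
                        seed = 71L)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  s1 <- simulateTranscriptomes(spec, outDir = d1)
  s2 <- simulateTranscriptomes(spec, outDir = d2)
  # samples.tsv records the output paths themselves, so the FASTA and
  # truth/divergence tables are the byte-compared artifacts
  for (f in c("truth.tsv", "divergences.tsv",
              "cpA_rep1.fasta", "cpA_rep2.fasta", "cpB.fasta",
              "ref_eukaryotic.fasta", "genomeA.fasta", "genomeB.fasta")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the data
  s3 <- simulateTranscriptomes(syntheticSpec(nFamilies = 15L,
                                             lengthRange = c(400L, 600L),
                                             seed = 72L))
  expect_false(identical(as.character(s1$sequences[[1]]),
                         as.character(s3$sequences[[1]])))
})

test_that("zero divergence and zero error give identical same-species contigs", {
  spec <- syntheticSpec(nFamilies = 10L, lengthRange = c(300L, 300L),
                        intraDivergence = 0, paralogRate = 0,
                        dropoutRate = 0, endErrorRate = 0, seed = 73L)
  sim <- simulateTranscriptomes(spec)
  for (f in unique(sim$truth$family)) {
    rows <- sim$truth[sim$truth$family == f &
                        sim$truth$species == "speciesA", ]
    seqs <- vapply(seq_len(nrow(rows)), function(i)
      as.character(sim$sequences[[rows$sample_id[i]]][[rows$contig_id[i]]]),
      character(1))
    expect_length(unique(seqs), 1L)
  }
})

test_that("realized interspecific divergence sits at its binomial expectation", {
  spec <- syntheticSpec(nFamilies = 200L, lengthRange = c(1000L, 1000L),
                        intraDivergence = 0, interMean = 0.14, interSd = 0,
                        paralogRate = 0, dropoutRate = 0, endErrorRate = 0,
                        seed = 74L)
  sim <- simulateTranscriptomes(spec)
  # one cross-species ortholog pair per family (rep1 vs the sister species)
  dv <- sim$dive
  cross <- dv[grepl("^cpA_rep1", dv$contig1) & grepl("^cpB", dv$contig2) |
                grepl("^cpB", dv$contig1) & grepl("^cpA_rep1", dv$contig2), ]
  expect_identical(nrow(cross), 200L)
  se <- sqrt(0.14 * 0.86 / 1000 / 200)
  expect_lt(abs(mean(cross$divergence) - 0.14), 3 * se)
})

test_that("dropout removes the binomially expected number of transcripts", {
  spec <- syntheticSpec(nFamilies = 1000L, lengthRange = c(60L, 60L),
                        intraDivergence = 0, paralogRate = 0,
                        dropoutRate = 0.2, endErrorRate = 0, seed = 75L)
  sim <- simulateTranscriptomes(spec)
  sd3 <- 3 * sqrt(1000 * 0.2 * 0.8)
  for (s in spec@samples$sample_id) {
    absent <- 1000L - sum(sim$truth$sample_id == s)
    expect_lt(abs(absent - 200), sd3)
  }
})

test_that("recovery metrics are exact on constructed cases", {
  # perfect recovery on a clean run
  run <- clean_run()
  ev <- evaluateRecovery(run$res@orthologs, run$sim$truth,
                         osgSummaries(run$res))
  expect_equal(ev$family_purity, 1.0)
  expect_equal(ev$ortholog_recall, 1.0)
  expect_equal(ev$prop_inter_le2, 0.0)
  # hand-enumerated 5-family fixture with one deliberately fused OSG
  truth <- data.frame(
    contig_id = sprintf("c%02d", 1:10),
    sample_id = rep(c("s1", "s2"), 5),
    species = rep(c("spA", "spB"), 5),
    family = rep(sprintf("F%d", 1:5), each = 2),
    copy = 1L, paralog = FALSE, damaged_5p = FALSE, damaged_3p = FALSE,
    length = 100L)
  memb <- data.frame(
    osg_id = c("o1", "o1", "o2", "o2", "o3", "o3", "o3", "o3", "o4", "o5"),
    hg_id = "h", contig_id = truth$contig_id,
    sample_id = truth$sample_id, provenance = "single_copy_hg")
  o <- new("OrthologSet", membership = memb,
           removed = data.frame(contig_id = character(),
                                hg_id = character(), reason = character()))
  ev2 <- evaluateRecovery(o, truth)
  # o3 fuses families F3 and F4; o4/o5 split family F5
  expect_equal(ev2$family_purity, 2 / 3)   # o1, o2 pure; o3 fused
  # F1..F4 each sit inside a single OSG (co-clustering does not break
  # recall, purity catches it); the split F5 does
  expect_equal(ev2$ortholog_recall, 4 / 5)
  # pipeline output naming unknown contigs is an input error
  memb_bad <- memb; memb_bad$contig_id[1] <- "nope"
  o_bad <- new("OrthologSet", membership = memb_bad, removed = o@removed)
  expect_error(evaluateRecovery(o_bad, truth), "absent from truth")
})

test_that("a clean pipeline run reproduces the truth families exactly", {
  run <- clean_run()
  memb <- osgMembership(run$res)
  key <- paste(run$sim$truth$family, run$sim$truth$copy)
  fam <- setNames(key, run$sim$truth$contig_id)
  groups <- split(memb$contig_id, memb$osg_id)
  # one OSG per family, each containing exactly the family's contigs
  expect_identical(length(groups), length(unique(key)))
  for (g in groups)
    expect_length(unique(fam[g]), 1L)
})
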