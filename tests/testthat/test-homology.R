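test_that("identical contigs give reciprocal full-identity hits", {
  set.seed(21)
  s <- random_dna(1000)
  seqs <- Biostrings::DNAStringSet(c(a = s, b = s))
  h <- allVsAllHits(seqs, evalueMax = 1e-15)
  expect_identical(sort(h$query_id), c("a", "b"))
  expect_true(all(h$pident == 100))
  expect_true(all(h$length == 1000))
  expect_true(all(h$evalue <= 1e-15))
})

test_that("unrelated random contigs yield no hit at the clustering threshold", {
  set.seed(22)
  seqs <- Biostrings::DNAStringSet(c(a = random_dna(400),
                                     b = random_dna(400)))
  h <- allVsAllHits(seqs, evalueMax = 1e-15)
  expect_identical(nrow(h), 0L)
})

test_that("engine scores on a related trio match the Smith-Waterman oracle", {
  set.seed(23)
  base <- random_dna(300)
  seqs <- c(c1 = base, c2 = mutate_k(base, 10), c3 = mutate_k(base, 30))
  h <- allVsAllHits(Biostrings::DNAStringSet(seqs), evalueMax = 1)
  for (r in seq_len(nrow(h))) {
    expect_equal(h$score[r],
                 sw_oracle(seqs[[h$query_id[r]]], seqs[[h$subject_id[r]]]),
                 info = paste(h$query_id[r], h$subject_id[r]))
  }
  # every unordered pair reported in both orientations with equal score
  expect_identical(nrow(h), 6L)
})

make_contig_table <- function(ids, samples = "s1") {
  data.frame(contig_id = ids, sample_id = rep_len(samples, length(ids)),
             stringsAsFactors = FALSE)
}

fake_hits <- function(from, to, evalue) {
  data.frame(query_id = from, subject_id = to, evalue = evalue,
             stringsAsFactors = FALSE)
}

test_that("clustering uses strict e-value < threshold and transitivity", {
  contigs <- make_contig_table(c("A", "B", "C", "D"))
  # chain A-B, B-C below threshold -> one HG; D isolated
  h <- fake_hits(c("A", "B"), c("B", "C"), c(1e-20, 1e-18))
  g <- buildHomologousGroups(h, contigs, evalueMax = 1e-15)
  m <- hgMembership(g)
  expect_identical(unique(m$hg_id[m$contig_id %in% c("A", "B", "C")]),
                   m$hg_id[m$contig_id == "A"])
  expect_false(m$hg_id[m$contig_id == "D"] %in%
                 m$hg_id[m$contig_id != "D"])
  expect_false(m$comparable[m$contig_id == "D"])
  # an edge at exactly the threshold, or above it, does not cluster
  for (ev in c(1e-15, 1e-14)) {
    g2 <- buildHomologousGroups(fake_hits("A", "B", ev),
                                make_contig_table(c("A", "B")),
                                evalueMax = 1e-15)
    expect_identical(length(unique(hgMembership(g2)$hg_id)), 2L)
  }
  # no hits at all: every contig its own singleton HG
  g3 <- buildHomologousGroups(fake_hits(character(), character(), numeric()),
                              contigs, evalueMax = 1e-15)
  expect_identical(length(unique(hgMembership(g3)$hg_id)), 4L)
  # unknown contig id in the hit list is an input error
  expect_error(buildHomologousGroups(fake_hits("A", "Z", 1e-20), contigs),
               "unknown contig")
})

test_that("copy status flags any sample with two or more members", {
  expect_identical(classifyCopyStatus(c("s1", "s2")), "single")
  expect_identical(classifyCopyStatus(c("s1", "s1", "s2")), "multi")
  expect_identical(classifyCopyStatus("s1"), "single")
  expect_error(classifyCopyStatus(character()), "empty")
})

test_that("HGs partition the contigs and are order/orientation invariant", {
  set.seed(24)
  for (trial in 1:10) {
    n <- sample(5:30, 1)
    ids <- sprintf("c%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    e <- data.frame(query_id = sample(ids, ne, TRUE),
                    subject_id = sample(ids, ne, TRUE),
                    evalue = 10^-sample(10:25, ne, TRUE))
    e <- e[e$query_id != e$subject_id, ]
    contigs <- make_contig_table(ids)
    g <- buildHomologousGroups(e, contigs, evalueMax = 1e-15)
    m <- hgMembership(g)
    # partition: all contigs, each exactly once
    expect_setequal(m$contig_id, ids)
    expect_false(anyDuplicated(m$contig_id) > 0)
    # invariant to row order and query/subject swap
    e2 <- e[sample(nrow(e)), ]
    tmp <- e2$query_id; e2$query_id <- e2$subject_id; e2$subject_id <- tmp
    m2 <- hgMembership(buildHomologousGroups(e2, contigs,
                                             evalueMax = 1e-15))
    expect_identical(m[order(m$contig_id), c("contig_id", "hg_id")],
                     m2[order(m2$contig_id), c("contig_id", "hg_id")])
    # raising the threshold only coarsens: HGs at the stricter threshold
    # stay within single HGs at the looser one
    m3 <- hgMembership(buildHomologousGroups(e, contigs,
                                             evalueMax = 1e-10))
    map <- setNames(m3$hg_id, m3$contig_id)
    for (hg in unique(m$hg_id)) {
      members <- m$contig_id[m$hg_id == hg]
      expect_length(unique(map[members]), 1L)
    }
  }
})

test_that("tabular hit files round-trip through the import adapter", {
  set.seed(25)
  s <- random_dna(500)
  seqs <- Biostrings::DNAStringSet(c(a = s, b = mutate_k(s, 12)))
  h <- allVsAllHits(seqs, evalueMax = 1e-15)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeTabularHits(h, f)
  h2 <- allVsAllHits(seqs, engine = tabularHitsEngine(f),
                     evalueMax = 1e-15)
  expect_equal(h2$qstart, h$qstart)
  expect_equal(h2$send, h$send)
  expect_equal(h2$bitscore, h$bitscore, tolerance = 1e-6)
  g <- buildHomologousGroups(h2, make_contig_table(c("a", "b")))
  expect_identical(length(unique(hgMembership(g)$hg_id)), 1L)
})
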