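# direct per-column occupancy scan, independent of the implementation
trim_oracle <- function(rows, occ_min, window) {
  mat <- do.call(rbind, strsplit(rows, ""))
  ok <- colMeans(mat != "-") >= occ_min
  qual <- which(vapply(seq_len(ncol(mat) - window + 1L), function(s)
    all(ok[s:(s + window - 1L)]), logical(1)))
  if (!length(qual)) return(NULL)
  first <- min(qual)
  last <- max(qual) + window - 1L
  apply(mat[, first:last, drop = FALSE], 1, paste, collapse = "")
}

test_that("end trimming removes low-occupancy terminal columns only", {
  rows <- c(a = "AAAAACGTACGTACGT",
            b = "-----CGTACGTACGT",
            c = "-----CGTACGTACGT")
  out <- trimMsaEnds(rows, occupancyMin = 1.0, window = 5L)
  expect_identical(unname(as.character(out)[1]), "CGTACGTACGT")
  # a fully occupied alignment is unchanged
  full <- c(a = "ACGTACGT", b = "TGCATGCA")
  expect_identical(as.character(trimMsaEnds(full, window = 4L)), full)
  # no qualifying window: unchanged, flagged, with a warning
  ragged <- c(a = "A-A-A-A-", b = "-A-A-A-A")
  expect_warning(res <- trimMsaEnds(ragged, occupancyMin = 1, window = 3L),
                 "untrimmed")
  expect_true(attr(res, "noWindow"))
  expect_identical(as.character(res), ragged)
})

test_that("end trimming matches an exhaustive occupancy-scan oracle", {
  set.seed(51)
  for (k in 1:25) {
    n <- sample(2:5, 1); len <- sample(20:60, 1)
    rows <- vapply(seq_len(n), function(i) {
      core <- random_dna(len)
      lead <- paste(rep("-", sample(0:6, 1)), collapse = "")
      trail <- paste(rep("-", sample(0:6, 1)), collapse = "")
      paste0(lead, core, trail)
    }, character(1))
    w <- max(nchar(rows))
    rows <- vapply(rows, function(r)
      paste0(r, paste(rep("-", w - nchar(r)), collapse = "")), character(1))
    names(rows) <- sprintf("r%d", seq_len(n))
    expected <- trim_oracle(rows, 1.0, 5L)
    if (is.null(expected)) {
      expect_warning(trimMsaEnds(rows, 1.0, 5L))
    } else {
      got <- as.character(trimMsaEnds(rows, 1.0, 5L))
      expect_identical(unname(got), unname(expected), info = paste("case", k))
    }
  }
})

test_that("OSG summaries separate intra and inter species pairs", {
  # two same-species members at 1%: intra only (100 columns, 1 mismatch)
  base <- random_dna(100)
  m2 <- data.frame(contig_id = c("p", "q"), sample_id = c("s1", "s2"),
                   species = c("sp1", "sp1"))
  msa2 <- c(p = base, q = mutate_k(base, 1))
  s2 <- summarizeOsg("osgA", m2, msa2)
  expect_identical(s2$type, "intra")
  expect_equal(s2$davg, 1.0)
  expect_identical(s2$n_pairs, 1L)
  # sp1, sp1, sp2 with d(1a,1b)=0, d(1a,2)=14, d(1b,2)=16 (gaps shrink the
  # compared denominator for 1b): intra avg 0, inter (14, 16, 15)
  r1a <- paste(rep("A", 100), collapse = "")
  r1b <- paste(c(rep("A", 75), rep("-", 25)), collapse = "")
  r2 <- paste(c(rep("C", 12), rep("A", 63), rep("C", 2), rep("A", 23)),
              collapse = "")
  m3 <- data.frame(contig_id = c("x1a", "x1b", "x2"),
                   sample_id = c("sa", "sb", "sc"),
                   species = c("sp1", "sp1", "sp2"))
  s3 <- summarizeOsg("osgB", m3, c(x1a = r1a, x1b = r1b, x2 = r2))
  intra <- s3[s3$type == "intra", ]
  inter <- s3[s3$type == "inter", ]
  expect_equal(intra$davg, 0.0)
  expect_equal(c(inter$dmin, inter$dmax, inter$davg), c(14, 16, 15))
  # members missing a species label are an input error
  m_bad <- data.frame(contig_id = "p", sample_id = "s1",
                      species = NA_character_)
  expect_error(summarizeOsg("osgC", m_bad, msa2), "missing")
})

test_that("random OSG summaries equal brute-force pair enumeration", {
  set.seed(52)
  for (k in 1:10) {
    n <- 6L
    base <- random_dna(120)
    ids <- sprintf("m%d", 1:n)
    sp <- sample(c("sp1", "sp2", "sp3"), n, TRUE)
    rows <- setNames(vapply(1:n, function(i)
      mutate_k(base, sample(0:20, 1)), character(1)), ids)
    m <- data.frame(contig_id = ids, sample_id = sprintf("s%d", 1:n),
                    species = sp)
    got <- summarizeOsg("o", m, rows)
    for (r in seq_len(nrow(got))) {
      if (got$type[r] == "intra") {
        sel <- ids[sp == got$species1[r]]
        prs <- combn(sel, 2)
      } else {
        prs <- as.matrix(expand.grid(ids[sp == got$species1[r]],
                                     ids[sp == got$species2[r]]))
        prs <- t(prs)
      }
      d <- apply(prs, 2, function(pr) pdist_oracle(rows[[pr[1]]],
                                                   rows[[pr[2]]]))
      expect_equal(got$davg[r], mean(d))
      expect_equal(got$dmin[r], min(d))
      expect_equal(got$dmax[r], max(d))
      expect_identical(got$n_pairs[r], length(d))
    }
    expect_true(all(got$dmin <= got$davg & got$davg <= got$dmax))
  }
})

test_that("the three partitions are nested and rule-correct", {
  flags <- data.frame(
    osg_id = c("o1", "o2", "o3", "o4"),
    copy_status = c("single", "multi", "single", "single"),
    identified = c(TRUE, TRUE, FALSE, TRUE),
    reference_cluster_id = c("rc1", "rc2", "rc3", NA))
  p <- partitionSummaries(flags)
  expect_setequal(p$all, flags$osg_id)
  expect_setequal(p$single_copy_eukaryotic, c("o1", "o4"))
  expect_setequal(p$reference_matched, "o1")
  expect_true(all(p$reference_matched %in% p$single_copy_eukaryotic))
  expect_true(all(p$single_copy_eukaryotic %in% p$all))
  # two OSGs claiming one cluster leave neither in reference_matched
  flags$reference_cluster_id[4] <- "rc1"
  p2 <- partitionSummaries(flags)
  expect_length(p2$reference_matched, 0L)
})

test_that("proportion above cutoff counts strictly and errors on no data", {
  s <- data.frame(osg_id = c("a", "b", "c"), type = "intra",
                  species1 = "sp1", species2 = "sp1",
                  dmin = 0, dmax = 0, davg = c(0, 1.5, 3), n_pairs = 1L)
  expect_equal(proportionAboveCutoff(s, "sp1", 2.0), 1 / 3)
  s0 <- s; s0$davg <- 0
  expect_equal(proportionAboveCutoff(s0, "sp1", 2.0), 0)
  expect_error(proportionAboveCutoff(s, "sp9", 2.0), "no data")
  # exactly at the cutoff does not count (strict >)
  s$davg <- c(2, 2, 2)
  expect_equal(proportionAboveCutoff(s, "sp1", 2.0), 0)
  # monotone non-increasing in the cutoff, checked against a recount oracle
  set.seed(53)
  sN <- data.frame(osg_id = sprintf("o%d", 1:500), type = "inter",
                   species1 = "sp1", species2 = "sp2",
                   dmin = 0, dmax = 0, davg = runif(500, 0, 30),
                   n_pairs = 1L)
  cuts <- c(0, 1, 2, 5, 10, 40)
  props <- vapply(cuts, function(ct)
    proportionAboveCutoff(sN, c("sp1", "sp2"), ct), numeric(1))
  expect_true(all(diff(props) <= 0))
  expect_equal(props[3], sum(sN$davg > 2) / 500)
})

test_that("histograms bin half-open and conserve counts", {
  s <- data.frame(osg_id = c("a", "b", "c"), type = "intra",
                  species1 = "sp1", species2 = "sp1",
                  dmin = 0, dmax = 0, davg = c(0, 0.5, 1.2), n_pairs = 1L)
  h <- distanceHistogram(s, "sp1", binWidth = 1)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$bin_lo, c(0, 1))
  expect_error(distanceHistogram(s, "sp1", binWidth = 0), "positive")
  expect_warning(h0 <- distanceHistogram(s, "sp9"), "empty")
  expect_identical(nrow(h0), 0L)
  set.seed(54)
  sN <- data.frame(osg_id = sprintf("o%d", 1:2000), type = "intra",
                   species1 = "sp1", species2 = "sp1",
                   dmin = 0, dmax = 0, davg = runif(2000, 0, 25),
                   n_pairs = 1L)
  h2 <- distanceHistogram(sN, "sp1", binWidth = 0.5)
  expect_identical(sum(h2$count), 2000L)
})
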