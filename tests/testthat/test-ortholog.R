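dm_from <- function(labels, ...) {
  D <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  vals <- list(...)
  for (nm in names(vals)) {
    pair <- strsplit(nm, "_", fixed = TRUE)[[1]]
    D[pair[1], pair[2]] <- D[pair[2], pair[1]] <- vals[[nm]]
  }
  D
}

test_that("within-sample subdivision chains at the 2% cutoff", {
  m <- data.frame(contig_id = c("a", "b", "c"), sample_id = "s1")
  D <- dm_from(c("a", "b", "c"), a_b = 1.0, b_c = 1.5, a_c = 2.5)
  sg <- subdivideWithinSample(m, D, cutoff = 2.0)
  expect_length(unique(sg$subgroup_id), 1L)  # chained despite a_c > 2
  D2 <- dm_from(c("a", "b", "c"), a_b = 3, b_c = 4, a_c = 5)
  sg2 <- subdivideWithinSample(m, D2, cutoff = 2.0)
  expect_length(unique(sg2$subgroup_id), 3L)
  one <- subdivideWithinSample(data.frame(contig_id = "a",
                                          sample_id = "s1"),
                               dm_from("a"), cutoff = 2.0)
  expect_identical(nrow(one), 1L)
  # samples are subdivided independently
  m3 <- data.frame(contig_id = c("a", "b", "x", "y"),
                   sample_id = c("s1", "s1", "s2", "s2"))
  D3 <- dm_from(c("a", "b", "x", "y"), a_b = 1, x_y = 9,
                a_x = 1, a_y = 1, b_x = 1, b_y = 1)
  sg3 <- subdivideWithinSample(m3, D3, cutoff = 2.0)
  expect_length(unique(sg3$subgroup_id[sg3$sample_id == "s1"]), 1L)
  expect_length(unique(sg3$subgroup_id[sg3$sample_id == "s2"]), 2L)
})

test_that("neighbor joining recovers additive topologies", {
  # additive 4-taxon matrix with ((A,B),(C,D)) structure; the oracle is the
  # four-point condition: the pairing with the smallest sum is the split
  D <- dm_from(c("A", "B", "C", "D"),
               A_B = 2, A_C = 10, A_D = 11, B_C = 11, B_D = 12, C_D = 3)
  sums <- c(AB_CD = D["A", "B"] + D["C", "D"],
            AC_BD = D["A", "C"] + D["B", "D"],
            AD_BC = D["A", "D"] + D["B", "C"])
  expect_identical(names(which.min(sums)), "AB_CD")
  tr <- buildGeneTree(D)
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # identical sequences: star-like tree with zero branch lengths
  tr0 <- buildGeneTree(dm_from(c("A", "B", "C", "D")))
  expect_true(all(tr0$edge.length == 0))
  expect_error(buildGeneTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # random additive matrices: NJ reconstructs the generating tree
  set.seed(41)
  for (k in 1:20) {
    gen <- ape::rtree(5, br = function(n) runif(n, 1, 5))
    D5 <- ape::cophenetic.phylo(gen)
    tr5 <- buildGeneTree(D5)
    expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(gen)), 0,
                 ignore_attr = TRUE, info = paste("trial", k))
  }
})

test_that("subgroup matching minimizes average cross distance per sample", {
  sg <- data.frame(subgroup_id = c("x.1", "x.2", "y.1", "y.2"),
                   contig_id = c("x1", "x2", "y1", "y2"),
                   sample_id = c("sx", "sx", "sy", "sy"))
  D <- dm_from(c("x1", "x2", "y1", "y2"),
               x1_x2 = 20, y1_y2 = 20,
               x1_y1 = 1.0, x2_y2 = 1.2, x1_y2 = 15, x2_y1 = 14)
  res <- matchSubgroupsToOsgs(sg, D)
  grp <- split(res$contig_id, res$osg_index)
  expect_true(list(c("x1", "y1")) %in% grp)
  expect_true(list(c("x2", "y2")) %in% grp)
  # brute-force oracle over the two sample-respecting perfect pairings
  tot1 <- D["x1", "y1"] + D["x2", "y2"]
  tot2 <- D["x1", "y2"] + D["x2", "y1"]
  expect_lt(tot1, tot2)
  # one sample only: every subgroup its own OSG
  sg1 <- data.frame(subgroup_id = c("x.1", "x.2"),
                    contig_id = c("x1", "x2"), sample_id = "sx")
  res1 <- matchSubgroupsToOsgs(sg1, dm_from(c("x1", "x2"), x1_x2 = 20))
  expect_length(unique(res1$osg_index), 2L)
  # three samples, one subgroup each, mutually close: one OSG
  sg3 <- data.frame(subgroup_id = c("a.1", "b.1", "c.1"),
                    contig_id = c("a1", "b1", "c1"),
                    sample_id = c("sa", "sb", "sc"))
  res3 <- matchSubgroupsToOsgs(sg3, dm_from(c("a1", "b1", "c1"),
                                            a1_b1 = 1, a1_c1 = 1.5,
                                            b1_c1 = 1.2))
  expect_length(unique(res3$osg_index), 1L)
})

test_that("triplet rule keeps the closer paralog, deterministically on ties", {
  m <- data.frame(contig_id = c("a1", "a2", "b"),
                  sample_id = c("sa", "sa", "sb"))
  D <- dm_from(c("a1", "a2", "b"), a1_a2 = 10, a1_b = 1, a2_b = 5)
  tri <- resolveTriplet(m, D)
  expect_identical(tri$kept, c("a1", "b"))
  expect_identical(tri$removed, "a2")
  # reversed distances
  D2 <- dm_from(c("a1", "a2", "b"), a1_a2 = 10, a1_b = 5, a2_b = 1)
  expect_identical(resolveTriplet(m, D2)$removed, "a1")
  # tie: keep the lexicographically smaller paralog
  D3 <- dm_from(c("a1", "a2", "b"), a1_a2 = 10, a1_b = 3, a2_b = 3)
  expect_identical(resolveTriplet(m, D3)$kept, c("a1", "b"))
  expect_error(resolveTriplet(data.frame(contig_id = c("a", "b", "c"),
                                         sample_id = c("s1", "s2", "s3")),
                              dm_from(c("a", "b", "c"))),
               "two sequences from one sample")
})

test_that("every contig lands in exactly one OSG or the removal ledger", {
  run <- study_condition_run()
  memb <- osgMembership(run$res)
  removed <- removedContigs(run$res)
  all_ids <- contigData(run$res@contigs)$contig_id
  expect_setequal(c(memb$contig_id, removed$contig_id), all_ids)
  expect_false(anyDuplicated(c(memb$contig_id, removed$contig_id)) > 0)
  # removals only ever come from the triplet rule
  if (nrow(removed))
    expect_true(all(removed$reason == "triplet_rule"))
})

test_that("ortholog resolution is invariant to contig input order", {
  small <- clean_run(seed = 6L, nFamilies = 12L)
  cs <- simContigSet(small$sim)
  set.seed(42)
  perm <- cs[sample(length(cs))]
  res2 <- runComparison(perm, useCds = FALSE, verbose = FALSE)
  canon <- function(r) {
    m <- osgMembership(r)
    unname(sort(vapply(split(m$contig_id, m$osg_id),
                       function(x) paste(sort(x), collapse = "+"),
                       character(1))))
  }
  expect_identical(canon(res2), canon(small$res))
})
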