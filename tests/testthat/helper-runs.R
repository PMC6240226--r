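# Shared simulation runs, computed once per test session.

.run_cache <- new.env(parent = emptyenv())

# Full study-condition run: the generator defaults (300 families, 1 kb,
# two same-species samples at 0.5% divergence, one sister species at mean
# 14%, 10% paralogs, 20% dropout, end errors on 2% of termini), with
# classification against the synthetic eukaryotic reference set and
# matching to the synthetic single-copy genome clusters.
study_condition_run <- function(seed = 1L) {
  key <- paste0("study", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sim <- simulateTranscriptomes(syntheticSpec(seed = seed))
  res <- runComparison(simContigSet(sim), useCds = FALSE,
                       classifyRefsets = list(eukaryotic = sim$refEuk),
                       refClusters = list(genesA = sim$genomeA,
                                          genesB = sim$genomeB),
                       verbose = FALSE)
  .run_cache[[key]] <- list(sim = sim, res = res)
  .run_cache[[key]]
}

# Small clean run (no paralogs/dropout/error) for exact-recovery checks.
clean_run <- function(seed = 5L, nFamilies = 25L) {
  key <- paste0("clean", seed, "_", nFamilies)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  spec <- syntheticSpec(nFamilies = nFamilies,
                        lengthRange = c(600L, 600L),
                        paralogRate = 0, dropoutRate = 0,
                        endErrorRate = 0, seed = seed)
  sim <- simulateTranscriptomes(spec)
  res <- runComparison(simContigSet(sim), useCds = FALSE, verbose = FALSE)
  .run_cache[[key]] <- list(sim = sim, res = res)
  .run_cache[[key]]
}
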