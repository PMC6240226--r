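---
title: "Resolving cryptic species with transcriptome-wide p-distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving cryptic species with transcriptome-wide p-distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiverge)
```

# The problem

DNA barcoding of microbial eukaryotes leans on one or two markers (COI,
SSU rDNA), and in several amoebozoan genera those markers fail: isolates
with drastically different morphologies can be identical in every barcode,
while morphologically indistinguishable isolates can be deeply divergent.
Transcriptomes offer thousands of markers at once — if contigs assembled
from different samples can be matched into groups that are truly
orthologous, so that the distances measured between species are not
inflated by hidden paralogy.

`orthodiverge` implements that comparison end to end:

1. contigs are length-filtered (≥ 300 bp), classified against reference
   sets, and reduced to coding regions;
2. an all-vs-all similarity search links contigs with E-value < 1e-15 into
   **homologous groups** (HGs) by single linkage;
3. within each multi-copy HG, same-sample sequences are subdivided at a
   **2% uncorrected p-distance** cutoff and the subgroups matched across
   samples — guided by a neighbor-joining gene tree — into **orthologous
   subgroups** (OSGs), with a special three-sequence rule for 2+1 groups;
4. every OSG is re-aligned, end-trimmed, and summarized by the minimum,
   maximum and average intra- and inter-species p-distance;
5. OSGs are partitioned three ways (all; single-copy with an identified
   eukaryotic member; additionally matched to a single-copy two-genome
   reference cluster) and the proportion of groups above the 2% barcode
   gap is tabulated per partition;
6. single-copy, cluster-matched OSGs with all designated intraspecific
   averages below 2% and presence in at least two clades become candidate
   barcode markers.

The 2% threshold is the approximate barcode gap observed for COI in
*Cochliopodium* (maximum intraspecific ~0.9%, minimum interspecific
~2.8%), and is used both to sort paralogs within a sample and as the
reporting cutoff between partitions.

# The statistic

All distances are **uncorrected p-distances in percent** under pairwise
deletion:

$$ d_{ij} \;=\; 100 \cdot \frac{\#\{\text{columns where } i \neq j\}}
  {\#\{\text{columns with a non-gap, non-N character in both}\}} $$

No multiple-hit correction is applied: at intraspecific (< 2%) and
moderate interspecific (~14–20%) divergences the correction is small, and
the raw proportion is what the barcode-gap threshold is calibrated
against. `N` is excluded from the comparison (but counts as a mismatch in
alignment *scoring*, a deliberately conservative choice).

# Parameters that matter

| parameter | default | role |
|---|---|---|
| `minLen` | 300 bp | contig length filter before any comparison |
| `evalueMax` | 1e-15 (strict `<`) | edge threshold for HG clustering |
| `classifyEvalue` | 1e-10 | classification hit threshold (see below) |
| `cutoff` | 2.0 % | within-sample subdivision; the barcode gap |
| `minOrfLen` | 300 nt | minimum ORF for CDS extraction |
| `occupancyMin`, `window` | 1.0, 10 | alignment end-trimming rule |
| `binWidth` | 1 % | histogram granularity |

The classification E-value is a package choice: the clustering threshold
(1e-15) is prescribed by the method, but no threshold is prescribed for
the contaminant-classification step, so a conventional 1e-10 is the
default and is exposed as `classifyEvalue`.

# Design choices where the method is underdetermined

Several steps of the published procedure leave the exact rule open; the
package fixes each one explicitly:

* **Clustering is single linkage** (connected components of the
  thresholded hit graph). The permissive chaining behavior is intentional:
  contigs with very little mutual overlap should still be grouped when
  they come from the same gene. The same convention is used for the 2%
  within-sample subdivision, so `d(a,b) = 1`, `d(b,c) = 1.5`,
  `d(a,c) = 2.5` yields one subgroup.
* **Gene trees are neighbor-joining on the p-distance matrix**, not
  maximum likelihood. The tree is used only to keep paralog clusters apart
  during matching, a task for which distance trees are sufficient at this
  scale; `resolveOrthologs(treeFun =)` is the seam for an external tree
  tool. Negative NJ branch lengths are clamped to zero.
* **Subgroup matching is greedy**: candidate subgroup pairs from different
  samples merge in increasing order of average inter-subgroup p-distance,
  subject to at most one subgroup per sample per OSG and to tree
  consistency (the path between the two subgroups may not run through the
  spanning subtree of a third, already-merged cluster). Ties break on the
  lexicographically smaller id pair, making runs reproducible.
* **There is no distance ceiling on cross-sample matching.** An orphaned
  paralog whose true ortholog dropped out will be matched to whatever is
  left in its HG, sometimes at large distance. This is intended: it
  reproduces the high-distance "tail" that motivates the single-copy
  partitions, and the tail's reduction across partitions is itself part of
  the expected output pattern.
* **CDS extraction is a longest-ORF rule** (six frames, ATG to the next
  in-frame stop, stop codon excluded, open at the 3' end when no stop
  occurs; ties resolved by frame order `+1,+2,+3,-1,-2,-3`, then leftmost
  start). It is a coding-region trimmer, not a coding-potential model,
  and the pipeline accepts `useCds = FALSE` for inputs that are already
  coding-region-level sequences.
* **Reference clusters are reciprocal best hits** between two genomes'
  gene sets with in-genome duplicates excluded, replacing an online
  clustering service with an offline, reproducible equivalent of its
  "single-copy genes shared between two genomes" semantics. The OSG
  representative for cluster matching is the longest member.
* **Every final OSG is re-aligned before distance reporting**, including
  those reduced by the triplet rule, so reported distances never depend on
  an alignment computed over since-removed sequences.
* **Internal coordinates are 0-based half-open**; tabular hit files import
  and export 1-based inclusive coordinates.

# The built-in search and alignment engines

For desk-scale and fully offline runs, the package carries its own search
engine (k-mer seeding, banded Smith–Waterman around the modal seed
diagonal, ungapped Karlin–Altschul E-values
$E = K m n e^{-\lambda S}$ with $K = 0.13$, $\lambda = 0.318$) and its own
progressive aligner (guide order from Needleman–Wunsch scores against the
longest sequence; match +1, mismatch −1, gap open −4, gap extend −1,
"once a gap, always a gap"). Both are pluggable: `tabularHitsEngine()`
imports 12-column tabular hits from an external search tool, and
`externalAligner()` shells out to a command-line multiple aligner. All
internal kernels are validated against brute-force dynamic-programming
oracles in the test suite.

# What the simulator emulates — and what it does not

`syntheticSpec()` / `simulateTranscriptomes()` generate multi-sample
transcriptomes with known truth. The defaults are the package's reference
study conditions and are not tuned per run:

* 300 families, 1 kb genes, uniform random ancestors;
* two same-species samples at 0.5% mutual divergence
  (`intraDivergence = 0.005`, split evenly over the two sample branches)
  and one sister species at `N(0.14, 0.02)` per-site divergence — inside
  vs. far outside the 2% gap, as in real congeneric comparisons;
* pre-speciation paralogs in 10% of families at 10% divergence — far
  enough to be separable at the 2% cutoff, close enough to share an HG;
* 20% transcript dropout per family copy per sample, the main source of
  orphaned paralogs and hence of mismatched high-distance groups;
* elevated terminal error (each terminus affected with probability 0.02;
  within a 100 nt span sites substitute at 0.15), emulating the
  observation that sequencing error concentrates at contig ends. An
  affected terminus shifts a pairwise distance by roughly +1.5%, so
  single-hit pairs land near the 2% boundary and double hits clearly
  beyond it — producing a small intraspecific tail of a few percent of
  groups, comparable to real data;
* the synthetic eukaryotic reference set contains the ancestors of 75% of
  families (the rest remain "unidentified"), and two synthetic reference
  genomes carry single-copy genes for 60% of families at 10% and 15%
  divergence from the ancestor. These divergences are chosen so a
  DNA-level search can still detect the genes; real genome pairs at this
  taxonomic depth would be compared at the protein level, which is out of
  scope, so the synthetic genomes stand in for the *vouching role* of
  single-copy reference clusters rather than for realistic genome
  divergence. The generator labels all such outputs synthetic.

The simulator uses i.i.d. substitutions (always to a different base), no
rate heterogeneity across sites, no codon structure, and no indels unless
`indelRate > 0` is requested. Realized — not nominal — pairwise
divergences are recorded in the divergence ledger, so binomial sampling
and coincident substitutions are accounted for when checking the
generator. Consequences for interpretation: passing end-to-end tests show
that the *pipeline logic* (clustering, subdivision, matching, partitions)
recovers a known structure under realistic divergences, dropout and end
error; they do not exercise expression-level coverage variation,
chimeric misassembly, codon-aware alignment, or contamination, all of
which affect real transcriptomes.

Because the simulated contigs are already coding-region-level sequences
(uniform random DNA carries no ORF structure), simulated runs use
`runComparison(useCds = FALSE)`; the longest-ORF extractor is exercised by
its own unit tests on constructed sequences.

# Numerical conventions and degenerate inputs

* Strict inequalities follow the method's wording: clustering requires
  `evalue < 1e-15`; the tabulated tail counts groups with average distance
  strictly `> 2%`.
* A p-distance over zero comparable columns returns 0 with a warning and
  a `noOverlap` flag rather than `NaN`, and the pair is flagged in the
  distance-matrix attribute.
* Contigs with no qualifying hit become singleton HGs flagged
  non-comparable, so copy-status accounting covers every contig.
* End-trimming with no qualifying full-occupancy window returns the
  alignment unchanged with a `noWindow` flag.
* `proportionAboveCutoff()` distinguishes "comparison defined nowhere"
  (an error) from a genuine 0.
* All group ids (`HG…`, `OSG…`, subgroup and cluster ids) are assigned by
  sorting on the smallest member id, so identical inputs give
  byte-identical outputs; the determinism test re-runs the pipeline and
  compares files by checksum.

# Problem sizes used in validation

The test-suite and acceptance runs use the reference study conditions
above (about 800 contigs across three samples, ~300 HGs, ~330 OSGs),
plus smaller clean runs (no paralogs/dropout/error) for exact-recovery
checks and fixtures of tens of sequences for the oracle comparisons.
These sizes are the package's validation choices; the pipeline itself has
no hard-coded scale and accepts external search engines and aligners for
larger inputs.

# Known limitations

* Single-linkage chaining can, by design, link distant paralogs through
  intermediates; the single-copy and reference-matched partitions exist
  precisely to quantify and contain this.
* The greedy matcher is not globally optimal; the 2×2 case is verified
  against brute force, but adversarial HGs with many near-tied subgroups
  could be matched suboptimally.
* The built-in engine's banded alignment assumes the optimal alignment
  stays near the best seed diagonal; sequences with large internal
  rearrangements need an external search tool via the tabular adapter.
* DNA-level reference matching limits the usable divergence of reference
  genomes; deeply diverged genome pairs require protein-level comparison,
  which is a non-goal here.
* Distances are uncorrected by construction; they understate divergence
  beyond ~20% and should not feed distance-based dating.
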