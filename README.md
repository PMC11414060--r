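# clipmod

Single-nucleotide analysis of iCLIP and miCLIP libraries: crosslink-induced
truncation site (CITS) calling, m6A/m6Am site classification, and the
profiling statistics that go with them.

## Who this is for and what it does

iCLIP-seq reads truncate at the protein–RNA crosslink, so the position one
nucleotide 5' of a read start marks a binding site; with an anti-m6A
antibody (miCLIP) the same signal marks methylated adenosines. `clipmod`
takes aligned CLIP reads (BAM or BED6) plus a genome (FASTA) and transcript
annotation (GTF) and provides, as composable Bioconductor-style functions:

- **Truncation extraction** — `extractTruncations()` converts reads to
  per-nucleotide truncation counts (`TruncationTrack`).
- **CITS calling** — `callCits()` tests each position with ≥ 2 events
  against a per-transcript uniform null: with *n* events on a pre-mRNA
  span of length *L*, a position with *k* events gets
  *p* = P(X ≥ *k*), X ~ Binomial(*n*, 1/*L*), with genome-wide
  Benjamini–Hochberg correction and an FDR ≤ 0.01 decision rule.
  `filterAgainstControl()` removes GFP-control peaks;
  `mergeReplicatePeaks()` merges replicates.
- **m6A/m6Am classification** — `classifySites()` merges two miCLIP
  replicate CITS lists at a maximum gap of 1 bp, extends peaks ±2 bp,
  designates the central A of each DRACH motif (D∈{A,G,U}, R∈{A,G}, A, C,
  H∈{A,C,U}) as an m6A site, and reports the 5'-most A of each A-run that
  falls within the first quarter of an annotated 5'UTR — and does not
  coincide with an m6A site — as m6Am.
- **Profiles** — `metageneProfile()` (length-standardized 5'UTR/CDS/3'UTR
  bins, average crosslinks per million per transcript),
  `featureDistribution()` (raw percent and peaks per Kb per region),
  `anchorProfile()` (strand-aware density around a site set with a
  matched random-site null and a ±100 nt Wilcoxon rank-sum
  quantification), `overlapPeaks()` (≥ 1 nt intersection after 50 nt
  extension), `normalizeToInput()` (iCLIP/SMI CPM ratios).
- **Counts and groups** — `countSites()` (sites × samples matrix with
  median-of-ratios size factors), `compareGroups()` (Mann–Whitney or
  ANOVA + Tukey HSD), `targetVsNontargetFoldchange()`, and `ddct()`
  (RQ = 2^−ΔΔCT).
- **Synthetic data with planted truth** — `simulateReference()` and
  `simulateClipLibrary()` generate a genome, spliced transcripts, and
  multi-condition libraries (wildtype, knockdown, miCLIP, size-matched
  input, GFP control) in which every planted crosslink/m6A/m6Am site is
  known, so the entire pipeline is testable end to end without external
  data.
- **Orchestration** — `runPipeline()` binds the modules into subcommands
  (`simulate`, `cits`, `classify`, `metagene`, `anchor`, `overlap`,
  `counts`, `groups`) with YAML configuration, validation and JSON run
  manifests; `inst/scripts/clipmod.R` is a thin command-line wrapper.

## Worked example

Simulate a reference with planted truth, build two miCLIP replicates, call
CITS and classify methylation sites:

```r
library(clipmod)

spec <- simulationSpec(seed = 42)
sim <- simulateReference(spec)
sim
#> ClipSimulation: 69264 bp genome, 30 transcripts
#>   truth m6a: 50 sites
#>   truth m6am: 30 sites
#>   truth crosslink: 60 sites
#>   truth gfp_artifact: 3 sites

idx <- annotationIndex(sim)
lib1 <- simulateClipLibrary(sim, "miclip", 1, seed = 101)
lib2 <- simulateClipLibrary(sim, "miclip", 2, seed = 102)
lib1$track
#> TruncationTrack 'miclip_rep1': 20561 positions, 26,753 truncation events

p1 <- callCits(lib1$track, idx)   # 76 significant CITS at FDR <= 0.01
p2 <- callCits(lib2$track, idx)   # 76
cls <- classifySites(p1, p2, idx)
length(cls$m6a); length(cls$m6am)
#> [1] 50
#> [1] 29
head(cls$m6a, 3)
#> GRanges object with 3 ranges and 5 metadata columns:
#>       seqnames    ranges strand |       klass       motif   support
#>          <Rle> <IRanges>  <Rle> | <character> <character> <numeric>
#>   [1]    chrS1      1194      + |         m6A       TGACC        18
#>   [2]    chrS1      1424      + |         m6A       AAACC        18
#>   [3]    chrS1      1827      + |         m6A       TGACT        21
```

All 50 planted m6A sites are recovered (sensitivity 1.0 at 20-fold
enrichment over a 0.5 events/nt background), 29 of 30 planted m6Am sites
survive the first-quarter-of-5'UTR filter, and the two coordinate sets are
disjoint by construction of the procedure. Each reported m6A carries its
sense-strand DRACH context (`motif`), the summed replicate truncation
support, and the merged peak it derived from.

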