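---
title: "Methods: truncation-site calling and m6A/m6Am classification with clipmod"
author: "clipmod maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: truncation-site calling and m6A/m6Am classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmod)
library(GenomicRanges)
```

# The problem

iCLIP-style experiments read out protein–RNA contacts at single-nucleotide
resolution: reverse transcription stalls at the crosslinked nucleotide, so
the genomic position immediately 5' of a read start (in read orientation)
marks the contact. Performed with an anti-m6A antibody (miCLIP), the same
truncation signal marks methylated adenosines. `clipmod` implements the
downstream computational path from aligned reads to biology:
per-nucleotide truncation counts, statistically significant
crosslink-induced truncation sites (CITS), classification of miCLIP peaks
into internal m6A sites and cap-proximal m6Am sites, standardized metagene
and anchored-density profiles with matched random-site null models,
peak-overlap statistics, and site-level count comparisons — plus a fully
seeded synthetic-data generator so that every stage is testable against
planted truth without any external data.

# The CITS model

Upstream callers for this assay are typically used as black boxes; here the
statistical model is stated explicitly so it can be tested. For a
transcript whose genomic span (exons plus introns, i.e. the pre-mRNA) has
length $L$ and carries $n$ truncation events in a library, the null
hypothesis for a single position is that events land uniformly on the
span. A position carrying $k$ events receives the binomial tail
probability

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, 1/L),$$

and p-values are Benjamini–Hochberg corrected across all tested positions
genome-wide (a single experiment-wide FDR, the simplest defensible reading
of an "FDR $\le$ 0.01" decision rule). Design choices:

* **Pre-mRNA background.** The span rather than the mature mRNA is the
  background unit because intronic binding is a prominent feature of this
  class of data; an exon-only null would misstate the intronic signal.
* **Representative transcript.** A genomic position covered by several
  transcript models is tested once, under the transcript with the longest
  mRNA (ties broken alphabetically). This avoids double-counting positions
  in overlapping isoforms; the rule is exposed through
  `assignTranscripts()` and documented wherever it is used.
* **`minCount = 2`.** Singleton truncations carry no testable signal under
  any per-position null; testing them would only inflate the correction
  burden. Configurable via `citsParams()`.
* Replicate CITS lists are merged with `mergeReplicatePeaks()`; GFP-only
  control peaks are removed by exact-coordinate set difference
  (`filterAgainstControl()`), with an optional windowed match because the
  appropriate stringency is assay-dependent.

The FDR behaviour is verified empirically: on simulated uniform-background
libraries with no planted sites, the average of $V/\max(R,1)$ over 50
replicates stays below 0.02 (see `tests/testthat/test-acceptance.R`).

# m6A/m6Am classification

The classifier follows the published procedure step by step, with each
step its own testable function:

1. **Merge** single-nucleotide miCLIP CITS from two replicates at a
   maximum gap of 1 bp (`mergeMiclipCits()`). "Gap" counts intervening
   bases: sites at positions 100 and 102 merge; 100 and 103 do not.
2. **Extend** each merged peak 2 bp up- and downstream (`extendPeaks()`),
   floored at the chromosome origin and capped at its end.
3. **m6A**: scan the sense-strand sequence of each extended peak (padded
   2 nt per side so a motif may straddle the boundary) for DRACH 5-mers —
   D $\in$ {A,G,U}, R $\in$ {A,G}, then A, C, H $\in$ {A,C,U}; T replaces
   U on the DNA alphabet and N matches nothing. The coordinate of the
   motif's central A becomes the m6A site (`callM6A()`). Every DRACH in a
   peak yields a site; peaks without a motif contribute nothing.
4. **m6Am**: within each extended peak, maximal runs of sense-strand
   adenosines are collapsed and each run is represented by its 5'-most A
   in transcript sense (`callM6Am()`). m6Am is the first transcribed
   nucleotide adjacent to the cap, so when a run must be reduced to one
   coordinate the 5'-most A is the biologically coherent representative;
   this was a genuinely open choice and is recorded here as ours.
   Candidates survive only if they fall within the first
   $\lfloor 0.25 \times \text{5'UTR length} \rfloor$ nt of the 5'UTR of at
   least one annotated transcript (any transcript qualifies a candidate —
   the permissive reading; a representative-only variant is a one-line
   configuration change), and candidates that coincide with an m6A
   coordinate are excluded regardless of position.

`classifySites()` composes the four steps and is deterministic given its
inputs; on genomes of the scale used in the tests it is checked against an
independent brute-force implementation that enumerates every 5-mer and
every A-run.

# Profiles and null models

**Metagene profiles** (`metageneProfile()`) rescale each transcript region
(5'UTR, CDS, 3'UTR) to a fixed number of bins — defaults 50/100/70,
echoing typical UTR:CDS length ratios; no published bin setting exists for
the figure style being reproduced, so the values are configurable — and
average per-transcript binned CPM profiles unweighted over all transcripts
that possess all three regions. Events on transcripts lacking a region are
excluded and counted rather than silently misassigned. Bins are computed
as $\lfloor \text{offset} \times \text{bins} / \text{length} \rfloor$ with
the multiplication performed first, because dividing first places exact
bin-boundary offsets on the wrong side of the boundary through floating
point error.

**Anchored profiles** (`anchorProfile()`) average CPM density at
strand-aware offsets around a site set ("upstream" is negative in
transcript sense), summarize each site by its summed density within ±100
nt (configurable), and compare these sums against an equal number of
matched random sites by a two-sided Wilcoxon rank-sum test with continuity
correction and mid-ranked ties. The construction of "random sites" is
never specified in the figure legends this mirrors; we therefore ship two
explicit constructions and record which was used: *stratified* (each
anchor replaced by a uniform draw from the same chromosome and
feature-region type, avoiding trivially confounded nulls) and *uniform*
(uniform over transcribed space). Calibration is verified: with a track
independent of the anchors, rejection at $\alpha = 0.001$ stays below
0.005 over 200 seeded repetitions and the p-value distribution passes a
Kolmogorov–Smirnov test against U(0,1).

**Peak overlap** (`overlapPeaks()`) extends both peak sets 50 nt per side
and counts a query peak as overlapping when it shares at least one
nucleotide with any extended subject peak, strand-aware by default.

# Counts and group comparisons

`countSites()` builds a sites × samples matrix of truncation counts within
±2 nt of each site (the same window the classifier uses) as a
`SummarizedExperiment`, with per-sample size factors by the
median-of-ratios method; with fewer than 10 all-positive rows the factors
fall back to library-size ratios. `compareGroups()` applies a two-sided
Mann–Whitney test for two groups or one-way ANOVA with Tukey HSD for
three or more, on size-factor-normalized values (rank tests are invariant
to the log transform used for display). A negative-binomial differential
model is deliberately out of scope: the published analysis used an
external package for that step, and this package does not re-derive it.
`ddct()` implements qPCR relative quantification,
$RQ = 2^{-\Delta\Delta CT}$, exactly invertible by $-\log_2$.

# The synthetic-data generator

`simulateReference()` and `simulateClipLibrary()` define the study
conditions under which everything above is validated:

* A random-base genome carries spliced transcripts (defaults: 30
  transcripts, 5'UTRs 150–300 nt, CDS 300–900 nt, 3'UTRs 200–500 nt, 1–3
  introns of 100–400 nt, alternating strands, one gene per transcript).
* Planted **m6A** sites are written into the genome as a DRACH 5-mer
  flanked by `CC…CC`, a context chosen so that exactly one DRACH is
  centered at the planted coordinate; **m6Am** sites are written as an
  isolated adenosine (`CCACC`) within the first quarter of a 5'UTR;
  **crosslink** and GFP-artifact sites need no sequence context. All
  planted contexts lie within a single exon (so genomic and spliced
  sequence agree) and all sites are at least 15 nt apart.
* Libraries draw truncation events per transcribed nucleotide from
  Poisson(0.5) — the background rate is the expected number of events per
  nucleotide, i.e. the per-nt rate at the nominal one-million-event
  library scale — multiplied by 20 at the planted sites of the library's
  condition: wildtype and knockdown libraries are enriched at crosslink,
  m6A and m6Am sites; miCLIP libraries at m6A/m6Am only; size-matched
  input nowhere; the GFP control at its own artifact sites (5% of the
  crosslink count, disjoint coordinates, so control filtering is exercised
  meaningfully). Knockdown multiplies the enrichment by 0.3. Each event
  becomes one read starting 1 nt 3' of the event, making
  `extractTruncations()` the exact inverse of the emission — a property
  tested byte-for-byte.

What the generator does **not** emulate: sequencing errors, PCR
duplicates, fragment-length and crosslinking-efficiency biases,
non-uniform background (e.g. expression-correlated coverage), overlapping
gene models, and alternative isoforms. Passing tests therefore demonstrate
that the statistical machinery is correct under its stated model, not that
the model captures every artifact of real libraries; on real data the
uniform-background assumption is conservative where coverage is locally
smooth and can be anticonservative at sharp coverage steps (e.g.
exon–intron boundaries of partially processed transcripts).

# Numerical and interface conventions

* Intervals are 1-based closed `GRanges` internally; BED and bedGraph I/O
  go through `rtracklayer`, which converts at the boundary, and GTF is
  1-based natively. All single-nucleotide sites have width 1.
* The stop codon is treated as part of the CDS exactly as annotated; no
  adjustment is attempted.
* Merging ties (equal summed counts in a cluster) resolve to the 5'-most
  position in transcript sense; `gap = 0` collapses identical coordinates
  only, while `gap = g >= 1` allows up to `g` intervening bases.
* Every randomized operation takes an explicit seed and restores the
  caller's RNG state; there is no hidden entropy, which is what makes the
  simulate→call→classify→profile pipeline byte-reproducible.
* Problem sizes in the test suite (a ~70 kb genome with 30 transcripts for
  most properties; ~450 kb with 105 transcripts and 300 methylation sites
  for the knockdown contrast; 50 background libraries for FDR control; 200
  repetitions for null calibration; 1000 randomized trials per oracle)
  were chosen as the smallest regimes in which the tested properties are
  statistically meaningful.

# Known limitations

* The binomial null ignores local coverage structure; a two-sided or
  position-specific background (as mixture models in dedicated callers
  use) is out of scope.
* m6Am calling is restricted to annotated 5'UTRs; sites at unannotated
  transcription start sites are not recoverable by construction.
* No crosslink-induced mutation (CIMS) analysis, no stoichiometry
  estimation, and no negative-binomial differential methylation.

# A worked example

```{r example, eval = FALSE}
spec <- simulationSpec(seed = 42)
sim <- simulateReference(spec)
idx <- annotationIndex(sim)
lib1 <- simulateClipLibrary(sim, "miclip", 1, seed = 101)
lib2 <- simulateClipLibrary(sim, "miclip", 2, seed = 102)
p1 <- callCits(lib1$track, idx)
p2 <- callCits(lib2$track, idx)
cls <- classifySites(p1, p2, idx)
length(cls$m6a)    # recovered m6A sites
length(cls$m6am)   # recovered m6Am sites
```

The README shows this example with the output it prints.
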