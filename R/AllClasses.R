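#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom Biostrings DNAStringSet
NULL

#' Strand-aware transcript annotation index
#'
#' Container binding a genome sequence to strand-aware transcript feature
#' models. For every coding transcript the exonic space is partitioned into
#' 5'UTR, CDS and 3'UTR blocks; the gaps between consecutive exons are the
#' introns. Non-coding transcripts carry exon and intron features only. The
#' index also stores a transcript-span table used for fast position-to-
#' transcript lookup, and designates a representative transcript (the one
#' with the longest mRNA) wherever a single transcript must stand for a
#' position covered by several models.
#'
#' @slot transcripts [GRangesList] exons per transcript, genomic order.
#' @slot features [GRanges] unlisted feature table: one row per feature
#'   interval with metadata columns `tx`, `region` (one of `utr5`, `cds`,
#'   `utr3`, `intron`), `region_length` (total sense length of that region in
#'   that transcript) and `cum_before` (sense-strand length of the region
#'   preceding the interval within its transcript).
#' @slot txdata [DataFrame] one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `span_start`, `span_end`, `mrna_length`,
#'   `utr5_length`, `coding`.
#' @slot spans [GRanges] genomic span (first exon start to last exon end) of
#'   each transcript, same order as `txdata`.
#' @slot genome [DNAStringSet] chromosome sequences, uppercase.
#'
#' @seealso [loadAnnotation()], [transcriptSequence()], [genomicToMeta()]
#' @export
setClass("AnnotationIndex",
    representation(
        transcripts = "GRangesList",
        features    = "GRanges",
        txdata      = "DataFrame",
        spans       = "GRanges",
        genome      = "DNAStringSet"
    )
)

setValidity("AnnotationIndex", function(object) {
    msg <- character()
    if (length(object@spans) != nrow(object@txdata))
        msg <- c(msg, "spans and txdata must have one entry per transcript")
    if (!all(c("transcript_id", "gene_id", "mrna_length", "utr5_length",
               "coding") %in% colnames(object@txdata)))
        msg <- c(msg, "txdata lacks required columns")
    if (length(msg)) msg else TRUE
})

#' Per-nucleotide truncation counts for one CLIP library
#'
#' Sparse track of crosslink-induced truncation events: width-1 genomic
#' positions with a positive integer `count` metadata column. The library
#' size is the total number of truncation events, so counts-per-million
#' scaling is always defined relative to usable events.
#'
#' @slot sampleId single sample identifier.
#' @slot sites [GRanges] width-1, sorted, metadata column `count` (positive
#'   integers).
#' @slot librarySize total truncation events (`sum(count)`).
#' @slot dropped named integer vector of skipped-record counters
#'   (`negative_coordinate`, `off_chromosome`, `unstranded`, `unmapped`).
#'
#' @seealso [extractTruncations()], [callCits()]
#' @export
setClass("TruncationTrack",
    representation(
        sampleId    = "character",
        sites       = "GRanges",
        librarySize = "numeric",
        dropped     = "integer"
    )
)

setValidity("TruncationTrack", function(object) {
    msg <- character()
    if (length(object@sites)) {
        if (is.null(object@sites$count))
            return("sites must carry a 'count' metadata column")
        if (any(object@sites$count < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(width(object@sites) != 1L))
            msg <- c(msg, "sites must have width 1")
        if (!isTRUE(all.equal(object@librarySize, sum(object@sites$count))))
            msg <- c(msg, "librarySize must equal sum of counts")
    } else if (object@librarySize != 0) {
        msg <- c(msg, "empty track must have librarySize 0")
    }
    if (length(msg)) msg else TRUE
})

#' Parameters for CITS calling
#'
#' @slot fdrThreshold BH-adjusted FDR cutoff for significant truncation
#'   sites (default 0.01).
#' @slot minCount minimum per-position truncation count to test (default 2).
#' @slot mergeGap maximum number of intervening bases when merging replicate
#'   peak lists (default 0: identical positions only).
#'
#' @export
setClass("CitsParams",
    representation(
        fdrThreshold = "numeric",
        minCount     = "integer",
        mergeGap     = "integer"
    ),
    prototype(fdrThreshold = 0.01, minCount = 2L, mergeGap = 0L)
)

setValidity("CitsParams", function(object) {
    msg <- character()
    if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
        msg <- c(msg, "fdrThreshold must lie in (0, 1)")
    if (object@minCount < 1L)
        msg <- c(msg, "minCount must be >= 1")
    if (object@mergeGap < 0L)
        msg <- c(msg, "mergeGap must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Parameters for m6A/m6Am site classification
#'
#' Defaults are the published procedure: replicate truncation sites merged
#' at a maximum gap of 1 bp, peaks extended 2 bp each side, DRACH-anchored
#' m6A designation, and the m6Am first-quarter-of-5'UTR rule.
#'
#' @slot mergeGap maximum intervening bases when merging replicate miCLIP
#'   sites (default 1).
#' @slot extend symmetric peak extension in nt (default 2).
#' @slot utr5Fraction leading fraction of the 5'UTR in which m6Am candidates
#'   may lie (default 0.25).
#' @slot drachPattern IUPAC DNA pattern for the methylation consensus
#'   (default `"DRACH"`).
#'
#' @export
setClass("ClassifyParams",
    representation(
        mergeGap     = "integer",
        extend       = "integer",
        utr5Fraction = "numeric",
        drachPattern = "character"
    ),
    prototype(mergeGap = 1L, extend = 2L, utr5Fraction = 0.25,
              drachPattern = "DRACH")
)

setValidity("ClassifyParams", function(object) {
    msg <- character()
    if (object@utr5Fraction <= 0 || object@utr5Fraction > 1)
        msg <- c(msg, "utr5Fraction must lie in (0, 1]")
    if (object@extend < 0L) msg <- c(msg, "extend must be >= 0")
    if (object@mergeGap < 0L) msg <- c(msg, "mergeGap must be >= 0")
    if (nchar(object@drachPattern) != 5L)
        msg <- c(msg, "drachPattern must be a 5-mer")
    if (length(msg)) msg else TRUE
})

#' Anchored signal-density profile with matched random null
#'
#' Mean signal density (counts per million) at strand-aware offsets around a
#' set of anchor sites, together with the same computation on an equally
#' sized set of matched random sites, per-site summed densities within a
#' quantification window, and a two-sided Wilcoxon rank-sum comparison of
#' the two sets of per-site sums.
#'
#' @slot offsets integer offsets, -W..W, upstream negative in transcript
#'   sense.
#' @slot mean,sem per-offset mean and standard error over anchors (CPM).
#' @slot nullMean,nullSem the same over the matched random sites.
#' @slot siteSums,nullSums per-site summed density within the +/-Q window.
#' @slot statistic,pValue Wilcoxon rank-sum test of siteSums vs nullSums.
#' @slot window,quantWindow W and Q in nt.
#' @slot nAnchors number of anchors profiled.
#' @slot truncated number of anchors whose window ran off a chromosome end.
#'
#' @seealso [anchorProfile()]
#' @export
setClass("AnchorProfile",
    representation(
        offsets     = "integer",
        mean        = "numeric",
        sem         = "numeric",
        nullMean    = "numeric",
        nullSem     = "numeric",
        siteSums    = "numeric",
        nullSums    = "numeric",
        statistic   = "numeric",
        pValue      = "numeric",
        window      = "integer",
        quantWindow = "integer",
        nAnchors    = "integer",
        truncated   = "integer"
    )
)

setValidity("AnchorProfile", function(object) {
    msg <- character()
    if (length(object@mean) != length(object@offsets))
        msg <- c(msg, "mean must align with offsets")
    if (length(object@siteSums) != length(object@nullSums))
        msg <- c(msg, "matched null must have as many sites as anchors")
    if (length(msg)) msg else TRUE
})

#' Length-standardized metagene profile
#'
#' Average signal over transcripts after rescaling each transcript region
#' (5'UTR, CDS, 3'UTR) to a fixed number of bins. Densities are average
#' crosslinks per million per transcript, so the profile is independent of
#' absolute transcript lengths and of library depth.
#'
#' @slot bins data.frame with columns `region` and `bin_index` (0-based
#'   within region), one row per profile bin in 5'->3' order.
#' @slot density,sem per-bin mean and standard error over transcripts
#'   (CPM).
#' @slot nTranscripts number of transcripts averaged (all three regions
#'   present).
#' @slot binCounts named bins-per-region vector.
#' @slot nEvents events that fell in profiled regions (conservation
#'   bookkeeping); `nExcluded` events on transcripts lacking a region.
#' @slot nExcluded see above.
#'
#' @seealso [metageneProfile()]
#' @export
setClass("MetageneProfile",
    representation(
        bins         = "data.frame",
        density      = "numeric",
        sem          = "numeric",
        nTranscripts = "integer",
        binCounts    = "integer",
        nEvents      = "numeric",
        nExcluded    = "numeric"
    )
)

#' Per-site read-count matrix across samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `counts` assay
#' (sites x samples truncation counts within the site window) and a
#' per-sample `sizeFactor` column in `colData` computed by the
#' median-of-ratios method (library-size ratios when fewer than 10 usable
#' rows are available).
#'
#' @seealso [countSites()], [compareGroups()]
#' @export
setClass("SiteCountMatrix", contains = "SummarizedExperiment")

#' Result of a rank-based or ANOVA group comparison
#'
#' @slot method `"wilcoxon"` (two groups, Mann-Whitney U) or
#'   `"anova_tukey"` (>= 3 groups, one-way ANOVA with Tukey HSD).
#' @slot statistic U (two groups) or F (>= 3 groups).
#' @slot pValue overall two-sided p-value.
#' @slot groupMeans named per-group means of the compared values.
#' @slot groupSizes named per-group numbers of values.
#' @slot pairwise data.frame of Tukey HSD contrasts (`contrast`, `diff`,
#'   `p_adj`); empty for the two-group test.
#'
#' @seealso [compareGroups()]
#' @export
setClass("GroupComparison",
    representation(
        method     = "character",
        statistic  = "numeric",
        pValue     = "numeric",
        groupMeans = "numeric",
        groupSizes = "integer",
        pairwise   = "data.frame"
    )
)

#' Specification of a synthetic CLIP/miCLIP study
#'
#' Defines the synthetic genome, transcript architecture, planted site
#' classes and library regimes used by [simulateReference()] and
#' [simulateClipLibrary()]. Defaults describe a compact but realistic
#' regime: truncation events at 20-fold the background rate over a
#' 0.5-events-per-nucleotide Poisson exonic/intronic background, two
#' replicates per condition, and a knockdown condition in which planted
#' enrichment is attenuated to 30%.
#'
#' @slot seed master seed for the reference genome.
#' @slot nTranscripts number of transcripts (one per gene).
#' @slot utr5Range,cdsRange,utr3Range,intronRange length ranges (nt).
#' @slot nIntronsRange range of introns per transcript.
#' @slot nCrosslinkSites,nM6aSites,nM6amSites planted site counts.
#' @slot enrichment fold increase of truncation rate at planted sites.
#' @slot backgroundRate expected truncation events per transcribed nt.
#' @slot replicates libraries per condition.
#' @slot knockdownAttenuation multiplicative reduction of the enrichment
#'   factor in the knockdown condition (default 0.3, so 20x becomes 6x).
#' @slot gfpArtifactFraction GFP-control artifact sites as a fraction of
#'   planted crosslink sites (default 0.05, minimum 1).
#' @slot readLength emitted read length (nt).
#'
#' @export
setClass("SimulationSpec",
    representation(
        seed                 = "integer",
        nTranscripts         = "integer",
        utr5Range            = "integer",
        cdsRange             = "integer",
        utr3Range            = "integer",
        intronRange          = "integer",
        nIntronsRange        = "integer",
        nCrosslinkSites      = "integer",
        nM6aSites            = "integer",
        nM6amSites           = "integer",
        enrichment           = "numeric",
        backgroundRate       = "numeric",
        replicates           = "integer",
        knockdownAttenuation = "numeric",
        gfpArtifactFraction  = "numeric",
        readLength           = "integer"
    )
)

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@enrichment <= 1) msg <- c(msg, "enrichment must exceed 1")
    if (object@backgroundRate <= 0)
        msg <- c(msg, "backgroundRate must be positive")
    if (any(c(object@nCrosslinkSites, object@nM6aSites,
              object@nM6amSites) < 0))
        msg <- c(msg, "site counts must be >= 0")
    if (object@knockdownAttenuation <= 0 || object@knockdownAttenuation > 1)
        msg <- c(msg, "knockdownAttenuation must lie in (0, 1]")
    for (nm in c("utr5Range", "cdsRange", "utr3Range", "intronRange",
                 "nIntronsRange")) {
        r <- slot(object, nm)
        if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
            msg <- c(msg, sprintf("%s must be an ordered length-2 range", nm))
    }
    if (length(msg)) msg else TRUE
})

#' A generated synthetic reference with planted truth
#'
#' @slot genome [DNAStringSet] synthetic chromosomes.
#' @slot index [AnnotationIndex] built from the generated models.
#' @slot truth named list of truth [GRanges]: `crosslink`, `m6a`, `m6am`,
#'   `gfp_artifact`; each width-1 with metadata (`tx`, and `motif` for m6a).
#' @slot spec the [SimulationSpec] that produced it.
#'
#' @seealso [simulateReference()]
#' @export
setClass("ClipSimulation",
    representation(
        genome = "DNAStringSet",
        index  = "AnnotationIndex",
        truth  = "list",
        spec   = "SimulationSpec"
    )
)
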