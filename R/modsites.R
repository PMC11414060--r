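#' @include AllClasses.R annotation.R truncations.R
NULL

#' Merge miCLIP CITS replicates into candidate peaks
#'
#' Clusters single-nucleotide anti-m6A truncation sites from two (or more)
#' replicates: sites on the same chromosome and strand separated by at most
#' `gap` intervening bases fall into one cluster, reported as the interval
#' spanning its members. At the published `gap = 1`, replicate sites at
#' positions 100 and 102 merge into one peak covering 100-102; sites at 100
#' and 103 do not.
#'
#' @param rep1,rep2 width-1 peak [GRanges] from two replicates.
#' @param gap maximum intervening bases (default 1).
#' @param ... further replicate [GRanges] (pooled, then clustered).
#' @return [GRanges] of merged intervals with metadata `support` (summed
#'   member counts, from `k`/`count` columns when present) and `n_members`.
#' @export
mergeMiclipCits <- function(rep1, rep2, gap = 1L, ...) {
    if (missing(rep2))
        stop("the classification procedure is defined on >= 2 replicates")
    reps <- c(list(rep1, rep2), list(...))
    gap <- as.integer(gap)
    all <- do.call(c, unname(lapply(reps, function(g) {
        out <- GRanges(seqnames(g), IRanges::ranges(g), strand = strand(g))
        out$support <-
            if (!is.null(g$k)) as.numeric(g$k)
            else if (!is.null(g$count)) as.numeric(g$count)
            else rep(1, length(g))
        out
    })))
    if (!length(all)) return(GRanges())
    all <- sort(all, ignore.strand = TRUE)
    red <- GenomicRanges::reduce(all,
                                 min.gapwidth = .clusterGapwidth(gap),
                                 with.revmap = TRUE)
    red$support <- vapply(red$revmap, function(ix) sum(all$support[ix]),
                          numeric(1))
    red$n_members <- lengths(red$revmap)
    red$revmap <- NULL
    sort(red, ignore.strand = TRUE)
}

#' Symmetrically extend peak intervals
#'
#' Extends each interval by `extend` nt on both sides, floored at the
#' chromosome origin and capped at the chromosome end when the index (and
#' hence sequence lengths) is supplied.
#'
#' @param peaks [GRanges].
#' @param extend nt per side (default 2).
#' @param index optional [AnnotationIndex-class] supplying chromosome
#'   lengths.
#' @return extended [GRanges] (metadata preserved).
#' @export
extendPeaks <- function(peaks, extend = 2L, index = NULL) {
    extend <- as.integer(extend)
    out <- peaks
    start(out) <- pmax(1L, start(peaks) - extend)
    newEnd <- end(peaks) + extend
    if (!is.null(index)) {
        lim <- Biostrings::width(index@genome)[match(as.character(seqnames(peaks)), names(index@genome))]
        newEnd <- pmin(newEnd, as.integer(lim))
    }
    end(out) <- newEnd
    out
}

## Sense-strand sequence of [s, e] on chrom; minus strand reverse-complements.
.senseSeq <- function(genome, chrom, s, e, strand) {
    x <- Biostrings::subseq(genome[[chrom]], s, e)
    if (strand == "-") x <- Biostrings::reverseComplement(x)
    x
}

#' Designate m6A sites inside extended miCLIP peaks
#'
#' Scans the sense-strand sequence of each extended peak, padded by 2 nt on
#' each side so the 5-mer may straddle the boundary, for DRACH matches
#' (`D = A/G/T, R = A/G, A, C, H = A/C/T` on the DNA alphabet; `N` matches
#' nothing) whose central A lies inside the extended peak. Each qualifying
#' A becomes one m6A site; peaks with no match contribute nothing;
#' duplicate coordinates are reported once.
#'
#' @param extended [GRanges] of extended peaks (see [extendPeaks()]),
#'   optionally with a `support` metadata column.
#' @param index an [AnnotationIndex-class] (for the genome sequence).
#' @param params a [ClassifyParams-class].
#' @return width-1 [GRanges] with metadata `klass = "m6A"`, `motif` (the
#'   sense 5-mer), `support`, `source_start`, `source_end`.
#' @export
callM6A <- function(extended, index, params = classifyParams()) {
    pat <- Biostrings::DNAString(params@drachPattern)
    arm <- (length(pat) - 1L) %/% 2L
    res <- list()
    for (i in seq_along(extended)) {
        g <- extended[i]
        chrom <- as.character(seqnames(g))
        std <- as.character(strand(g))
        lim <- length(index@genome[[chrom]])
        s <- max(1L, start(g) - arm)
        e <- min(lim, end(g) + arm)
        seq <- .senseSeq(index@genome, chrom, s, e, std)
        m <- Biostrings::matchPattern(pat, seq, fixed = "subject")
        if (!length(m)) next
        centerSense <- start(m) + arm
        ## sense coordinate -> genomic coordinate
        gpos <- if (std == "+") s + centerSense - 1L else e - centerSense + 1L
        inside <- gpos >= start(g) & gpos <= end(g)
        if (!any(inside)) next
        gpos <- gpos[inside]
        motifs <- as.character(m)[inside]
        res[[length(res) + 1L]] <- GRanges(
            factor(chrom, names(index@genome)),
            IRanges(gpos, width = 1L), strand = std,
            klass = "m6A", motif = motifs,
            support = if (!is.null(g$support)) g$support else NA_real_,
            source_start = start(g), source_end = end(g))
    }
    if (!length(res)) return(GRanges())
    out <- do.call(c, res)
    key <- paste(seqnames(out), strand(out), start(out))
    out <- out[!duplicated(key)]
    sort(out, ignore.strand = TRUE)
}

#' Designate m6Am candidate sites inside extended miCLIP peaks
#'
#' Within each extended peak, maximal runs of sense-strand adenosines are
#' collapsed and each run yields one candidate at its 5'-most A (in
#' transcript sense). Candidates are kept only when they fall within the
#' first `floor(utr5Fraction * utr5_length)` nt of the 5'UTR of at least
#' one annotated transcript (transcript-sense offset), and candidates whose
#' coordinate equals an m6A site are excluded regardless of position.
#'
#' @param extended [GRanges] of extended peaks.
#' @param m6aSites width-1 [GRanges] of already-called m6A sites.
#' @param index an [AnnotationIndex-class].
#' @param params a [ClassifyParams-class].
#' @return width-1 [GRanges] with metadata `klass = "m6Am"`, `motif` (A-run
#'   descriptor, e.g. `"A3"`), `support`, `source_start`, `source_end`.
#' @export
callM6Am <- function(extended, m6aSites, index, params = classifyParams()) {
    cand <- list()
    for (i in seq_along(extended)) {
        g <- extended[i]
        chrom <- as.character(seqnames(g))
        std <- as.character(strand(g))
        seq <- as.character(.senseSeq(index@genome, chrom, start(g), end(g),
                                      std))
        runs <- gregexpr("A+", seq)[[1]]
        if (runs[1] == -1L) next
        runLen <- attr(runs, "match.length")
        sensePos <- as.integer(runs)      # 5'-most A of each run
        gpos <- if (std == "+") start(g) + sensePos - 1L
                else end(g) - sensePos + 1L
        cand[[length(cand) + 1L]] <- GRanges(
            factor(chrom, names(index@genome)),
            IRanges(gpos, width = 1L), strand = std,
            klass = "m6Am", motif = sprintf("A%d", runLen),
            support = if (!is.null(g$support)) g$support else NA_real_,
            source_start = start(g), source_end = end(g))
    }
    if (!length(cand)) return(GRanges())
    out <- do.call(c, cand)
    ## keep candidates within the first quarter of >= 1 annotated 5'UTR
    u5 <- index@features[index@features$region == "utr5"]
    hits <- GenomicRanges::findOverlaps(out, u5, ignore.strand = FALSE)
    ok <- logical(length(out))
    if (length(hits)) {
        qi <- queryHits(hits); si <- subjectHits(hits)
        f <- u5[si]
        minus <- as.character(strand(f)) == "-"
        off <- ifelse(minus, f$cum_before + (end(f) - start(out)[qi]),
                      f$cum_before + (start(out)[qi] - start(f)))
        lim <- floor(params@utr5Fraction * f$region_length)
        good <- off < lim
        ok[unique(qi[good])] <- TRUE
    }
    out <- out[ok]
    if (length(out) && length(m6aSites)) {
        keyA <- paste(seqnames(m6aSites), strand(m6aSites), start(m6aSites))
        key <- paste(seqnames(out), strand(out), start(out))
        out <- out[!key %in% keyA]
    }
    key <- paste(seqnames(out), strand(out), start(out))
    out <- out[!duplicated(key)]
    sort(out, ignore.strand = TRUE)
}

#' Classify miCLIP truncation peaks into m6A and m6Am sites
#'
#' The full published procedure: replicate single-nucleotide CITS are
#' merged at a maximum gap of 1 bp, each merged peak is extended 2 bp up-
#' and downstream, peaks containing a DRACH motif yield m6A sites at the
#' motif's A, and peaks containing sense-strand adenosines yield m6Am
#' candidates (consecutive As merged, 5'-most A recorded) that are kept
#' when they fall within the first quarter of an annotated 5'UTR and do not
#' coincide with any m6A site. Deterministic given its inputs.
#'
#' @param rep1,rep2 width-1 miCLIP CITS [GRanges] from two replicates.
#' @param index an [AnnotationIndex-class].
#' @param params a [ClassifyParams-class] (defaults are the published
#'   values).
#' @return named list with elements `m6a` and `m6am` (width-1 [GRanges],
#'   see [callM6A()] and [callM6Am()]), plus `peaks` (the merged extended
#'   intervals).
#' @export
classifySites <- function(rep1, rep2, index, params = classifyParams()) {
    merged <- mergeMiclipCits(rep1, rep2, gap = params@mergeGap)
    ext <- extendPeaks(merged, extend = params@extend, index = index)
    m6a <- callM6A(ext, index, params)
    m6am <- callM6Am(ext, m6a, index, params)
    list(m6a = m6a, m6am = m6am, peaks = ext)
}

#' Write methylation sites as BED6
#'
#' `name = klass:motif`, `score = support` capped at 1000.
#'
#' @param sites width-1 site [GRanges] from [callM6A()]/[callM6Am()].
#' @param path output BED path.
#' @export
exportSitesBed <- function(sites, path) {
    out <- GRanges(seqnames(sites), IRanges::ranges(sites),
                   strand = strand(sites))
    out$name <- paste(sites$klass, sites$motif, sep = ":")
    sup <- sites$support
    sup[is.na(sup)] <- 0
    out$score <- pmin(1000L, as.integer(round(sup)))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write CITS peaks as BED6 and a companion statistics TSV
#'
#' BED name is the sample id and the score is `round(-10 * log10(q))`
#' capped at 1000; the TSV carries `k`, `n`, `L`, `p`, `q` per site.
#'
#' @param cits CITS [GRanges] from [callCits()].
#' @param bedPath output BED path.
#' @param tsvPath optional output TSV path.
#' @export
exportCitsBed <- function(cits, bedPath, tsvPath = NULL) {
    out <- GRanges(seqnames(cits), IRanges::ranges(cits),
                   strand = strand(cits))
    out$name <- if (length(cits)) cits$sample_id else character(0)
    q <- if (length(cits)) cits$q_value else numeric(0)
    out$score <- pmin(1000L, as.integer(round(-10 * log10(pmax(q, 1e-100)))))
    rtracklayer::export(out, bedPath, format = "BED")
    if (!is.null(tsvPath)) {
        df <- data.frame(chrom = as.character(seqnames(cits)),
                         start0 = start(cits) - 1L, end = end(cits),
                         strand = as.character(strand(cits)),
                         k = cits$k, n = cits$n, L = cits$L,
                         p = cits$p_value, q = cits$q_value)
        utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(bedPath)
}
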