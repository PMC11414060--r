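#' @include AllClasses.R annotation.R
NULL

#' Per-nucleotide truncation counts from aligned CLIP reads
#'
#' iCLIP-style libraries truncate at the crosslinked nucleotide during cDNA
#' preparation, so each read marks the genomic position immediately 5' of
#' its start in read orientation: one base before the leftmost aligned base
#' for plus-strand reads, one base after the rightmost aligned base for
#' minus-strand reads. Events falling before position 1 (or past the
#' chromosome end, when sequence lengths are known) are dropped and
#' counted, as are unstranded records. Reads are assumed deduplicated
#' upstream.
#'
#' @param reads aligned reads: a [GRanges], a BED6 file path, or a BAM file
#'   path (mapped primary records are used).
#' @param sampleId sample identifier stored in the track.
#' @param seqlengths optional named integer vector of chromosome lengths
#'   used to drop off-chromosome events; taken from `reads` seqinfo when
#'   available.
#' @return a [TruncationTrack-class].
#' @examples
#' r <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 101), c(135, 135)), strand = c("+", "-"))
#' truncationSites(extractTruncations(r, "demo"))  # positions 100 and 136
#' @export
extractTruncations <- function(reads, sampleId, seqlengths = NULL) {
    if (is.character(reads)) {
        reads <- if (grepl("\\.bam$", reads, ignore.case = TRUE)) {
            GenomicRanges::granges(GenomicAlignments::readGAlignments(
                reads,
                param = Rsamtools::ScanBamParam(
                    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                                  isSecondaryAlignment = FALSE))))
        } else {
            rtracklayer::import(reads, format = "BED")
        }
    }
    dropped <- c(negative_coordinate = 0L, off_chromosome = 0L,
                 unstranded = 0L, unmapped = 0L)
    if (is.null(seqlengths)) {
        sl <- GenomeInfoDb::seqlengths(reads)
        if (length(sl) && !all(is.na(sl))) seqlengths <- sl
    }
    std <- as.character(strand(reads))
    bad <- std == "*"
    dropped["unstranded"] <- sum(bad)
    reads <- reads[!bad]
    std <- std[!bad]
    pos <- ifelse(std == "+", start(reads) - 1L, end(reads) + 1L)
    neg <- pos < 1L
    dropped["negative_coordinate"] <- sum(neg)
    chrom <- as.character(seqnames(reads))
    if (!is.null(seqlengths)) {
        lim <- seqlengths[chrom]
        off <- !is.na(lim) & pos > lim
        dropped["off_chromosome"] <- sum(off)
        keep <- !neg & !off
    } else keep <- !neg
    chrom <- chrom[keep]; pos <- pos[keep]; std <- std[keep]
    if (!length(pos)) {
        return(new("TruncationTrack", sampleId = sampleId, sites = GRanges(),
                   librarySize = 0, dropped = dropped))
    }
    key <- paste(chrom, std, pos)
    agg <- rowsum(rep(1L, length(key)), key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    sites <- GRanges(vapply(parts, `[`, "", 1L),
                     IRanges(as.integer(vapply(parts, `[`, "", 3L)),
                             width = 1L),
                     strand = vapply(parts, `[`, "", 2L))
    sites$count <- as.integer(agg[, 1])
    sites <- sort(sites, ignore.strand = TRUE)
    new("TruncationTrack", sampleId = sampleId, sites = sites,
        librarySize = as.numeric(sum(sites$count)), dropped = dropped)
}

#' Construct a truncation track directly from positions and counts
#'
#' @param sites width-1 [GRanges] with a `count` metadata column.
#' @param sampleId sample identifier.
#' @return a [TruncationTrack-class].
#' @export
truncationTrack <- function(sites, sampleId) {
    sites <- sort(sites, ignore.strand = TRUE)
    new("TruncationTrack", sampleId = sampleId, sites = sites,
        librarySize = if (length(sites)) as.numeric(sum(sites$count)) else 0,
        dropped = c(negative_coordinate = 0L, off_chromosome = 0L,
                    unstranded = 0L, unmapped = 0L))
}

#' Call significant crosslink-induced truncation sites (CITS)
#'
#' Tests every position with at least `minCount` truncation events against
#' a per-transcript uniform null: with `n` total events on a transcript
#' whose genomic span (exons plus introns, i.e. pre-mRNA) has length `L`, a
#' position carrying `k` events receives the binomial tail probability
#' `P(X >= k)`, `X ~ Binomial(n, 1/L)`. p-values are Benjamini-Hochberg
#' corrected across all tested positions genome-wide, and positions with
#' `q <= fdrThreshold` are returned sorted by coordinate. Positions covered
#' by several transcript models are tested once, under the representative
#' (longest-mRNA) transcript. Positions outside all transcript spans are
#' not tested; their count is attached as attribute `outside`.
#'
#' @param track a [TruncationTrack-class].
#' @param index an [AnnotationIndex-class].
#' @param params a [CitsParams-class] (default `citsParams()`).
#' @return [GRanges] of width-1 peaks with metadata columns `k`, `n`, `L`,
#'   `p_value`, `q_value`, `sample_id`, `tx`.
#' @export
callCits <- function(track, index, params = citsParams()) {
    stopifnot(is(track, "TruncationTrack"), is(index, "AnnotationIndex"))
    sites <- track@sites
    if (!length(sites)) stop("cannot call CITS on an empty track")
    tx <- assignTranscripts(index, sites)
    outside <- sum(is.na(tx))
    keep <- !is.na(tx)
    sites <- sites[keep]; tx <- tx[keep]
    ## per-transcript totals over ALL assigned events (incl. untested ones)
    nPerTx <- rowsum(as.numeric(sites$count), tx)
    row <- match(tx, index@txdata$transcript_id)
    L <- index@txdata$span_end[row] - index@txdata$span_start[row] + 1L
    n <- nPerTx[tx, 1]
    test <- sites$count >= params@minCount
    out <- GRanges()
    if (any(test)) {
        k <- sites$count[test]
        nT <- n[test]; LT <- L[test]
        p <- stats::pbinom(k - 1, nT, 1 / LT, lower.tail = FALSE)
        q <- stats::p.adjust(p, method = "BH")
        sig <- q <= params@fdrThreshold
        if (any(sig)) {
            out <- sites[test][sig]
            mcols(out) <- DataFrame(
                k = k[sig], n = as.integer(nT[sig]), L = as.integer(LT[sig]),
                p_value = p[sig], q_value = q[sig],
                sample_id = track@sampleId, tx = tx[test][sig])
            out <- sort(out, ignore.strand = TRUE)
        }
    }
    attr(out, "outside") <- outside
    attr(out, "n_tested") <- sum(test)
    out
}

#' Remove CITS present in a control library
#'
#' Drops peaks whose single-nucleotide site coincides with any control peak
#' at the same chromosome, strand and position (the default), or lies
#' within `window` nt of one when `window > 0`.
#'
#' @param cits,controlCits width-1 peak [GRanges].
#' @param window matching half-window in nt (0 = exact position).
#' @return the filtered `cits`.
#' @export
filterAgainstControl <- function(cits, controlCits, window = 0L) {
    if (!length(controlCits) || !length(cits)) return(cits)
    ctl <- GenomicRanges::resize(controlCits, 1L + 2L * as.integer(window),
                                 fix = "center")
    hit <- GenomicRanges::countOverlaps(cits, ctl, ignore.strand = FALSE) > 0
    cits[!hit]
}

## cluster width-1 sites: gap = max intervening bases for gap >= 1;
## gap 0 collapses identical positions only.
.clusterGapwidth <- function(gap) if (gap == 0L) 0L else gap + 1L

#' Merge CITS peak lists across replicates
#'
#' Takes the union of single-nucleotide peaks from two or more replicate
#' lists. Sites on the same chromosome and strand are collapsed into one
#' cluster when separated by at most `gap` intervening bases (positions 100
#' and 102 merge at `gap = 1`; `gap = 0` collapses identical positions
#' only). Each cluster is reported as the member position with the highest
#' summed count, ties resolved 5'-most in transcript sense.
#'
#' @param peakLists list of width-1 peak [GRanges]; counts are taken from a
#'   `k` (or `count`) metadata column, defaulting to 1.
#' @param gap maximum intervening bases (default 0).
#' @return width-1 [GRanges] with metadata `k` (summed count at the
#'   reported position), `cluster_total` and `n_members`.
#' @export
mergeReplicatePeaks <- function(peakLists, gap = 0L) {
    stopifnot(is.list(peakLists), length(peakLists) >= 1L)
    gap <- as.integer(gap)
    getK <- function(g) {
        if (!is.null(g$k)) as.numeric(g$k)
        else if (!is.null(g$count)) as.numeric(g$count)
        else rep(1, length(g))
    }
    all <- do.call(c, unname(lapply(peakLists, function(g) {
        out <- GRanges(seqnames(g), IRanges::ranges(g), strand = strand(g))
        out$k <- getK(g)
        out
    })))
    if (!length(all)) return(GRanges())
    ## sum counts at identical positions first
    key <- paste(seqnames(all), strand(all), start(all))
    ksum <- rowsum(all$k, key)
    uniq <- all[!duplicated(key)]
    uniq$k <- unname(ksum[paste(seqnames(uniq), strand(uniq), start(uniq)), 1])
    uniq <- sort(uniq, ignore.strand = TRUE)
    red <- GenomicRanges::reduce(uniq,
                                 min.gapwidth = .clusterGapwidth(gap),
                                 with.revmap = TRUE)
    pick <- vapply(red$revmap, function(ix) {
        members <- uniq[ix]
        best <- which(members$k == max(members$k))
        if (length(best) > 1L) {
            ## 5'-most in transcript sense
            best <- if (as.character(strand(members))[1] == "-")
                best[which.max(start(members)[best])]
            else best[which.min(start(members)[best])]
        }
        ix[best]
    }, integer(1))
    out <- uniq[pick]
    out$cluster_total <- vapply(red$revmap,
                                function(ix) sum(uniq$k[ix]), numeric(1))
    out$n_members <- lengths(red$revmap)
    sort(out, ignore.strand = TRUE)
}

#' Normalize a CLIP track to size-matched input in genomic bins
#'
#' Per-bin binding density as the ratio of counts-per-million values,
#' `(clip CPM + eps) / (smi CPM + eps)`, over fixed-width bins. Bins
#' occupied by neither library are omitted.
#'
#' @param clip,smi [TruncationTrack-class] objects from the same genome
#'   build.
#' @param binSize bin width in nt (default 50).
#' @param pseudocount `eps`, in CPM (default 0.5).
#' @return [GRanges] of bins with metadata `clip_cpm`, `smi_cpm`, `ratio`.
#' @export
normalizeToInput <- function(clip, smi, binSize = 50L, pseudocount = 0.5) {
    if (smi@librarySize == 0)
        stop("size-matched input library is empty; use un-normalized ",
             "density instead")
    if (clip@librarySize == 0) stop("CLIP library is empty")
    binOf <- function(track) {
        s <- track@sites
        data.frame(chrom = as.character(seqnames(s)),
                   strand = as.character(strand(s)),
                   bin = (start(s) - 1L) %/% binSize,
                   cpm = s$count / track@librarySize * 1e6)
    }
    a <- binOf(clip); b <- binOf(smi)
    keyA <- paste(a$chrom, a$strand, a$bin)
    keyB <- paste(b$chrom, b$strand, b$bin)
    cpmA <- rowsum(a$cpm, keyA); cpmB <- rowsum(b$cpm, keyB)
    keys <- sort(union(rownames(cpmA), rownames(cpmB)))
    va <- vb <- numeric(length(keys))
    va[match(rownames(cpmA), keys)] <- cpmA[, 1]
    vb[match(rownames(cpmB), keys)] <- cpmB[, 1]
    parts <- strsplit(keys, " ", fixed = TRUE)
    bin <- as.integer(vapply(parts, `[`, "", 3L))
    out <- GRanges(vapply(parts, `[`, "", 1L),
                   IRanges(bin * binSize + 1L, width = binSize),
                   strand = vapply(parts, `[`, "", 2L))
    out$clip_cpm <- va
    out$smi_cpm <- vb
    out$ratio <- (va + pseudocount) / (vb + pseudocount)
    sort(out, ignore.strand = TRUE)
}
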