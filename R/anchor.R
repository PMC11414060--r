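#' @include AllClasses.R annotation.R truncations.R
NULL

## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## random state afterwards.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Draw matched random sites for a null model
#'
#' Samples as many random positions as there are anchors, uniformly from
#' transcribed space. In the default stratified mode each anchor is
#' replaced by a position drawn from the same chromosome and feature-region
#' type (utr5/cds/utr3/intron, noncoding exon), so the null matches the
#' anchors' region and chromosome composition; a stratum with no available
#' positions falls back to unstratified sampling with a warning. Fully
#' reproducible from `seed`, which is mandatory.
#'
#' @param anchors width-1 [GRanges].
#' @param index an [AnnotationIndex-class].
#' @param match `"stratified"` (default) or `"uniform"`.
#' @param seed integer seed.
#' @return width-1 [GRanges], `length(anchors)` sites, strand taken from
#'   the sampled feature interval.
#' @export
sampleRandomSites <- function(anchors, index,
                              match = c("stratified", "uniform"), seed) {
    match <- match.arg(match)
    if (missing(seed)) stop("a seed is required")
    f <- index@features
    freg <- f$region
    freg[freg == "exon"] <- "noncoding"
    drawFrom <- function(pool, n) {
        ## pool: GRanges intervals; position uniform over their bases
        w <- width(pool)
        iv <- sample.int(length(pool), n, replace = TRUE, prob = w)
        pos <- start(pool)[iv] +
            floor(stats::runif(n) * w[iv])
        GRanges(seqnames(pool)[iv], IRanges(pos, width = 1L),
                strand = strand(pool)[iv])
    }
    .withSeed(seed, {
        if (match == "uniform") {
            pool <- GenomicRanges::reduce(index@spans)
            out <- drawFrom(pool, length(anchors))
        } else {
            tx <- assignTranscripts(index, anchors)
            reg <- rep("any", length(anchors))
            has <- !is.na(tx)
            if (any(has)) {
                meta <- genomicToMeta(index, tx[has], start(anchors)[has])
                r <- meta$region
                r[r == "exon"] <- "noncoding"
                r[r == "none"] <- "any"
                reg[has] <- r
            }
            chrom <- as.character(seqnames(anchors))
            stratum <- paste(chrom, reg)
            pieces <- vector("list", length(anchors))
            for (st in unique(stratum)) {
                ix <- which(stratum == st)
                ch <- chrom[ix[1]]; rg <- reg[ix[1]]
                pool <- if (rg == "any") {
                    GenomicRanges::reduce(
                        index@spans[as.character(seqnames(index@spans)) == ch])
                } else {
                    GenomicRanges::reduce(
                        f[freg == rg & as.character(seqnames(f)) == ch])
                }
                if (!length(pool)) {
                    warning("no available positions for stratum '", st,
                            "'; falling back to unstratified sampling")
                    pool <- GenomicRanges::reduce(index@spans)
                }
                drawn <- drawFrom(pool, length(ix))
                for (j in seq_along(ix)) pieces[[ix[j]]] <- drawn[j]
            }
            out <- do.call(c, pieces)
        }
        out
    })
}

#' Anchored signal-density profile with a matched random null
#'
#' Computes, for each anchor site, the CPM-scaled truncation density of a
#' track at strand-aware offsets `-W..W` (upstream negative in transcript
#' sense), averages over anchors (mean and SEM per offset), performs the
#' same computation on an equally sized set of matched random sites, and
#' compares the per-site summed densities within `+/-Q` nt by a two-sided
#' Wilcoxon rank-sum (Mann-Whitney) test with continuity correction.
#' Windows running off a chromosome end are truncated and flagged.
#' Deterministic under a fixed `seed`.
#'
#' @param track a [TruncationTrack-class].
#' @param anchors width-1 [GRanges] anchor sites.
#' @param index an [AnnotationIndex-class].
#' @param W plot half-window in nt (default 500).
#' @param Q quantification half-window in nt (default 100).
#' @param nullMatch `"stratified"` or `"uniform"` random-site construction.
#' @param seed integer seed for the random sites.
#' @param nullSites optional pre-drawn random sites (overrides sampling;
#'   must have `length(anchors)` elements).
#' @return an [AnchorProfile-class].
#' @export
anchorProfile <- function(track, anchors, index, W = 500L, Q = 100L,
                          nullMatch = c("stratified", "uniform"), seed,
                          nullSites = NULL) {
    stopifnot(is(track, "TruncationTrack"))
    if (!length(anchors)) stop("anchors must be non-empty")
    if (!length(track@sites)) stop("track must be non-empty")
    nullMatch <- match.arg(nullMatch)
    W <- as.integer(W); Q <- as.integer(Q)
    if (is.null(nullSites)) {
        if (missing(seed)) stop("a seed is required for the random null")
        nullSites <- sampleRandomSites(anchors, index, match = nullMatch,
                                       seed = seed)
    }
    if (length(nullSites) != length(anchors))
        stop("number of random anchors must equal number of real anchors")
    real <- .offsetMatrix(track, anchors, W, index)
    null <- .offsetMatrix(track, nullSites, W, index)
    qcols <- which(abs(seq(-W, W)) <= Q)
    siteSums <- rowSums(real$mat[, qcols, drop = FALSE])
    nullSums <- rowSums(null$mat[, qcols, drop = FALSE])
    wt <- stats::wilcox.test(siteSums, nullSums, alternative = "two.sided",
                             correct = TRUE, exact = FALSE)
    nA <- length(anchors)
    semOf <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
    new("AnchorProfile",
        offsets = seq(-W, W), mean = colMeans(real$mat),
        sem = semOf(real$mat), nullMean = colMeans(null$mat),
        nullSem = semOf(null$mat), siteSums = siteSums,
        nullSums = nullSums, statistic = unname(wt$statistic),
        pValue = wt$p.value, window = W, quantWindow = Q,
        nAnchors = nA, truncated = real$truncated)
}

## anchors x offsets CPM matrix; strand-aware offset orientation.
.offsetMatrix <- function(track, anchors, W, index) {
    nA <- length(anchors)
    mat <- matrix(0, nrow = nA, ncol = 2L * W + 1L)
    pos <- start(anchors)
    win <- GRanges(seqnames(anchors),
                   IRanges(pmax(1L, pos - W), pos + W),
                   strand = strand(anchors))
    lim <- Biostrings::width(index@genome)[match(as.character(seqnames(anchors)), names(index@genome))]
    truncated <- sum(pos - W < 1L | pos + W > lim)
    hits <- GenomicRanges::findOverlaps(track@sites, win,
                                        ignore.strand = FALSE)
    if (length(hits)) {
        si <- queryHits(hits); ai <- subjectHits(hits)
        off <- start(track@sites)[si] - pos[ai]
        minus <- as.character(strand(anchors))[ai] == "-"
        off[minus] <- -off[minus]
        cpm <- track@sites$count[si] / track@librarySize * 1e6
        ix <- cbind(ai, off + W + 1L)
        keep <- ix[, 2] >= 1L & ix[, 2] <= 2L * W + 1L
        incr <- rowsum(cpm[keep],
                       paste(ix[keep, 1], ix[keep, 2]))
        parts <- strsplit(rownames(incr), " ", fixed = TRUE)
        mat[cbind(as.integer(vapply(parts, `[`, "", 1L)),
                  as.integer(vapply(parts, `[`, "", 2L)))] <- incr[, 1]
    }
    list(mat = mat, truncated = as.integer(truncated))
}

#' Overlap two peak sets after symmetric extension
#'
#' Both sets are extended by `extendNt` per side; a peak of `a` counts as
#' overlapping when it shares at least one nucleotide with any extended
#' peak of `b`. Strand-aware by default.
#'
#' @param a,b peak [GRanges].
#' @param extendNt extension per side in nt (default 50).
#' @param ignoreStrand ignore strand when intersecting (default FALSE).
#' @return list with `extended_nt`, `n_a`, `n_b`, `n_overlapping_a`,
#'   `fraction` (`n_overlapping_a / n_a`).
#' @export
overlapPeaks <- function(a, b, extendNt = 50L, ignoreStrand = FALSE) {
    extendNt <- as.integer(extendNt)
    ea <- extendPeaks(a, extendNt)
    eb <- extendPeaks(b, extendNt)
    nOv <- sum(GenomicRanges::countOverlaps(
        ea, eb, minoverlap = 1L, ignore.strand = ignoreStrand) > 0)
    list(extended_nt = extendNt, n_a = length(a), n_b = length(b),
         n_overlapping_a = nOv,
         fraction = if (length(a)) nOv / length(a) else NA_real_)
}

#' Write an anchor profile as TSV plus a JSON statistics block
#'
#' @param profile an [AnchorProfile-class].
#' @param tsvPath profile table output path.
#' @param jsonPath optional statistics JSON path (W, Q, n, U, p).
#' @export
exportAnchorProfile <- function(profile, tsvPath, jsonPath = NULL) {
    utils::write.table(profileTable(profile), tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(jsonPath)) {
        jsonlite::write_json(
            list(W = profile@window, Q = profile@quantWindow,
                 n = profile@nAnchors, U = profile@statistic,
                 p = profile@pValue),
            jsonPath, auto_unbox = TRUE, digits = NA)
    }
    invisible(tsvPath)
}
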