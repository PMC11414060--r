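#' @include AllClasses.R annotation.R truncations.R
NULL

.DEFAULT_BINS <- c(utr5 = 50L, cds = 100L, utr3 = 70L)

#' Length-standardized metagene density profile
#'
#' Maps every truncation event (or site) into transcript feature space via
#' the representative transcript, rescales each region to a fixed number of
#' bins (`floor(offset / region_length * bins)`), converts counts to events
#' per million library events, and averages the per-transcript binned
#' profiles unweighted over all transcripts that possess all three regions.
#' The resulting density is therefore independent of absolute transcript
#' lengths and of library depth. Events on transcripts lacking a 5'UTR or
#' 3'UTR (or outside any transcript) are excluded from averaging and
#' counted.
#'
#' @param x a [TruncationTrack-class], or a width-1 [GRanges] of sites
#'   (optional `count` column, default 1 per site).
#' @param index an [AnnotationIndex-class].
#' @param binCounts named integer vector of bins per region (default
#'   `c(utr5 = 50, cds = 100, utr3 = 70)`).
#' @param normalize `"cpm"` (default) or `"input-ratio"`; the latter
#'   divides the profile bin-wise by an identically computed profile of
#'   `smi`, with pseudocount `eps` on both sides.
#' @param smi size-matched-input [TruncationTrack-class] (required for
#'   `"input-ratio"`).
#' @param eps pseudocount for the ratio mode (default 0.01 CPM).
#' @return a [MetageneProfile-class].
#' @export
metageneProfile <- function(x, index, binCounts = .DEFAULT_BINS,
                            normalize = c("cpm", "input-ratio"),
                            smi = NULL, eps = 0.01) {
    normalize <- match.arg(normalize)
    binCounts <- binCounts[c("utr5", "cds", "utr3")]
    storage.mode(binCounts) <- "integer"
    if (anyNA(binCounts)) stop("binCounts must name utr5, cds and utr3")
    base <- .metageneOne(x, index, binCounts)
    if (normalize == "input-ratio") {
        if (is.null(smi)) stop("input-ratio mode requires an smi track")
        ref <- .metageneOne(smi, index, binCounts)
        base@density <- (base@density + eps) / (ref@density + eps)
        base@sem <- rep(NA_real_, length(base@sem))
    }
    base
}

.eventSites <- function(x) {
    if (is(x, "TruncationTrack")) {
        s <- x@sites
        list(sites = s, lib = x@librarySize)
    } else {
        s <- x
        if (is.null(s$count)) s$count <- rep(1L, length(s))
        list(sites = s, lib = sum(s$count))
    }
}

.metageneOne <- function(x, index, binCounts) {
    ev <- .eventSites(x)
    sites <- ev$sites
    if (!length(sites)) stop("no events to profile")
    td <- index@txdata
    ## transcripts owning all three regions
    regLen <- function(region) {
        f <- index@features[index@features$region == region]
        len <- structure(rep(0L, nrow(td)), names = td$transcript_id)
        s <- rowsum(width(f), f$tx)
        len[rownames(s)] <- s[, 1]
        len
    }
    l5 <- regLen("utr5"); lc <- regLen("cds"); l3 <- regLen("utr3")
    eligible <- td$transcript_id[l5 > 0 & lc > 0 & l3 > 0]
    if (!length(eligible))
        stop("no transcript has all of utr5, cds and utr3")
    tx <- assignTranscripts(index, sites)
    meta <- genomicToMeta(index, ifelse(is.na(tx), td$transcript_id[1], tx),
                          start(sites))
    usable <- !is.na(tx) & tx %in% eligible &
        meta$region %in% names(binCounts)
    excluded <- as.numeric(sum(sites$count[!usable]))
    sites <- sites[usable]; tx <- tx[usable]; meta <- meta[usable, ]
    nBins <- sum(binCounts)
    offsets <- cumsum(c(0L, binCounts))[seq_along(binCounts)]
    names(offsets) <- names(binCounts)
    ## multiply before dividing: integer products are exact in doubles,
    ## so floor() cannot fall on the wrong side of a bin boundary
    binIn <- pmin(floor(as.numeric(meta$offset) * binCounts[meta$region] /
                        meta$region_length),
                  binCounts[meta$region] - 1L)
    bin <- offsets[meta$region] + binIn + 1L      # 1..nBins
    cpm <- sites$count / ev$lib * 1e6
    ## per (transcript, bin) sums; mean and sem across eligible transcripts
    keyTx <- factor(tx, levels = eligible)
    keyBin <- factor(bin, levels = seq_len(nBins))
    sums <- rowsum(cpm, paste(as.integer(keyTx), as.integer(keyBin)))
    parts <- strsplit(rownames(sums), " ", fixed = TRUE)
    b <- as.integer(vapply(parts, `[`, "", 2L))
    v <- sums[, 1]
    nTx <- length(eligible)
    tot <- tot2 <- numeric(nBins)
    agg <- rowsum(cbind(v, v^2), b)
    bi <- as.integer(rownames(agg))
    tot[bi] <- agg[, 1]; tot2[bi] <- agg[, 2]
    dens <- tot / nTx
    varb <- (tot2 - nTx * dens^2) / max(1L, nTx - 1L)
    varb[varb < 0] <- 0
    sem <- sqrt(varb / nTx)
    bins <- data.frame(
        region = rep(names(binCounts), binCounts),
        bin_index = unlist(lapply(binCounts, seq_len), use.names = FALSE) - 1L,
        stringsAsFactors = FALSE)
    new("MetageneProfile", bins = bins, density = unname(dens),
        sem = unname(sem), nTranscripts = nTx, binCounts = binCounts,
        nEvents = as.numeric(sum(sites$count)),
        nExcluded = as.numeric(excluded))
}

setMethod("show", "MetageneProfile", function(object) {
    cat("MetageneProfile: ", length(object@density), " bins (",
        paste(names(object@binCounts), object@binCounts, sep = "=",
              collapse = ", "), "), ", object@nTranscripts,
        " transcripts averaged\n", sep = "")
    cat("  ", object@nEvents, " events profiled, ", object@nExcluded,
        " excluded\n", sep = "")
})

#' Tabulate a metagene profile
#'
#' @param profile a [MetageneProfile-class].
#' @return data.frame with `region`, `bin_index`, `density`, `sem`.
#' @export
metageneTable <- function(profile) {
    cbind(profile@bins, density = profile@density, sem = profile@sem)
}

#' Distribution of peaks across transcript feature regions
#'
#' Assigns each peak to a region of its representative transcript and
#' reports either the raw percentage of peaks per region (over `utr5`,
#' `cds`, `utr3`, `intron` and `noncoding` exonic space) or, in
#' length-normalized mode, peaks per kilobase of summed region length
#' across all transcripts in the index. Peaks outside every transcript
#' span are bucketed `intergenic` and excluded from percentages and per-Kb
#' denominators.
#'
#' @param peaks width-1 peak [GRanges].
#' @param index an [AnnotationIndex-class].
#' @param ignoreStrand assign peaks irrespective of strand (default FALSE).
#' @return data.frame with columns `region`, `count`, `percent`,
#'   `length_kb`, `peaks_per_kb`.
#' @export
featureDistribution <- function(peaks, index, ignoreStrand = FALSE) {
    regions <- c("utr5", "cds", "utr3", "intron", "noncoding")
    tx <- assignTranscripts(index, peaks, ignoreStrand = ignoreStrand)
    reg <- rep("intergenic", length(peaks))
    has <- !is.na(tx)
    if (any(has)) {
        meta <- genomicToMeta(index, tx[has], start(peaks)[has])
        r <- meta$region
        r[r == "exon"] <- "noncoding"
        r[r == "none"] <- "intergenic"
        reg[has] <- r
    }
    counts <- vapply(regions, function(r) sum(reg == r), integer(1))
    ## summed region lengths over the whole index, in Kb
    f <- index@features
    fr <- f$region
    fr[fr == "exon"] <- "noncoding"
    lenNt <- vapply(regions, function(r) sum(width(f)[fr == r]), numeric(1))
    lengthKb <- lenNt / 1000
    inTx <- sum(counts)
    out <- data.frame(
        region = regions, count = counts,
        percent = if (inTx > 0) 100 * counts / inTx else rep(NA_real_, 5L),
        length_kb = lengthKb,
        peaks_per_kb = ifelse(lengthKb > 0, counts / lengthKb, NA_real_),
        stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "intergenic") <- sum(reg == "intergenic")
    out
}

#' Write a metagene profile as TSV
#'
#' @param profile a [MetageneProfile-class].
#' @param path output TSV path.
#' @export
exportMetageneTsv <- function(profile, path) {
    utils::write.table(metageneTable(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
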