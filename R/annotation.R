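#' @include AllClasses.R
NULL

## Region labels in transcript (5'->3') order for coding transcripts.
.REGIONS <- c("utr5", "cds", "utr3")

#' Load genome and transcript annotation into an index
#'
#' Reads a GTF (exon and CDS records carrying `transcript_id` and `gene_id`
#' attributes) and a FASTA genome, and derives strand-aware 5'UTR / CDS /
#' 3'UTR / intron feature models for every coding transcript. Non-coding
#' transcripts (no CDS records) carry exon and intron features only.
#' Transcripts whose CDS records are not contained in their exons are
#' skipped with a warning.
#'
#' @param gtfPath path to a GTF file.
#' @param fastaPath path to a FASTA genome (an `.fai` index is created if
#'   missing and the file is uncompressed).
#' @return an [AnnotationIndex-class].
#' @export
loadAnnotation <- function(gtfPath, fastaPath) {
    .checkGtfLines(gtfPath)
    gr <- rtracklayer::import(gtfPath, format = "gtf")
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome <- DNAStringSet(toupper(genome))
    ex <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    if (!length(ex)) stop("GTF contains no exon records")
    if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
        stop("exon records must carry a transcript_id attribute")
    buildAnnotationIndex(
        exons = GenomicRanges::split(ex, ex$transcript_id),
        cds = if (length(cds))
                  GenomicRanges::split(cds, cds$transcript_id)
              else GRangesList(),
        geneIds = vapply(split(as.character(ex$gene_id), ex$transcript_id),
                         `[`, character(1), 1L),
        genome = genome)
}

## Cheap structural scan so a malformed line is reported by number before
## rtracklayer's parser sees it.
.checkGtfLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- which(body)[nf < 8L]
    if (length(bad))
        stop("malformed GTF line ", bad[1], " in ", path,
             ": expected >= 8 tab-separated fields")
    invisible(TRUE)
}

#' Build an annotation index from in-memory transcript models
#'
#' Lower-level constructor used both by [loadAnnotation()] and by the
#' synthetic-data generator.
#'
#' @param exons [GRangesList] of exon intervals per transcript.
#' @param cds [GRangesList] of CDS intervals per transcript (may be empty
#'   or lack entries for non-coding transcripts).
#' @param geneIds named character vector transcript_id -> gene_id.
#' @param genome [DNAStringSet] of chromosome sequences.
#' @return an [AnnotationIndex-class].
#' @export
buildAnnotationIndex <- function(exons, cds, geneIds, genome) {
    txIds <- names(exons)
    featList <- vector("list", length(txIds))
    keep <- logical(length(txIds))
    txrows <- vector("list", length(txIds))
    for (i in seq_along(txIds)) {
        tx <- txIds[i]
        ex <- sort(exons[[tx]])
        strand <- as.character(strand(ex))[1]
        if (!strand %in% c("+", "-")) {
            warning("transcript ", tx, " has no strand; skipped")
            next
        }
        chrom <- as.character(seqnames(ex))[1]
        exr <- IRanges::ranges(ex)
        if (length(exr) > 1L &&
            any(start(exr)[-1] <= end(exr)[-length(exr)])) {
            warning("transcript ", tx, " has overlapping exons; skipped")
            next
        }
        cdsr <- if (tx %in% names(cds)) IRanges::ranges(sort(cds[[tx]]))
                else IRanges()
        coding <- length(cdsr) > 0L
        if (coding &&
            sum(width(IRanges::intersect(cdsr, exr))) != sum(width(cdsr))) {
            warning("CDS of transcript ", tx,
                    " is not contained in its exons; transcript skipped")
            next
        }
        feat <- .deriveFeatures(exr, cdsr, chrom, strand, tx,
                                names(genome))
        featList[[i]] <- feat
        mrna <- sum(width(exr))
        u5 <- if (length(feat)) sum(width(feat)[feat$region == "utr5"]) else 0L
        txrows[[i]] <- data.frame(
            transcript_id = tx, gene_id = unname(geneIds[tx]),
            chrom = chrom, strand = strand,
            span_start = min(start(exr)), span_end = max(end(exr)),
            mrna_length = mrna, utr5_length = u5, coding = coding,
            stringsAsFactors = FALSE)
        keep[i] <- TRUE
    }
    txdata <- do.call(rbind, txrows[keep])
    if (is.null(txdata)) stop("no usable transcripts in annotation")
    feats <- do.call(c, featList[keep])
    spans <- GRanges(factor(txdata$chrom, names(genome)),
                     IRanges(txdata$span_start, txdata$span_end),
                     strand = txdata$strand)
    new("AnnotationIndex",
        transcripts = exons[txdata$transcript_id],
        features = feats, txdata = DataFrame(txdata), spans = spans,
        genome = genome)
}

## Partition one transcript's exonic space into utr5/cds/utr3 (coding) or
## leave it as exons (non-coding), and add introns; annotate each interval
## with region length and cumulative sense-strand offset.
.deriveFeatures <- function(exr, cdsr, chrom, strand, tx, seqLevels) {
    pieces <- list()
    if (length(cdsr)) {
        cs <- min(start(cdsr)); ce <- max(end(cdsr))
        lo <- IRanges::intersect(exr, IRanges(1L, cs - 1L))
        mid <- IRanges::intersect(exr, IRanges(cs, ce))
        hi <- if (ce < max(end(exr)))
                  IRanges::intersect(exr, IRanges(ce + 1L, max(end(exr))))
              else IRanges()
        if (strand == "+") {
            pieces$utr5 <- lo; pieces$cds <- mid; pieces$utr3 <- hi
        } else {
            pieces$utr5 <- hi; pieces$cds <- mid; pieces$utr3 <- lo
        }
    } else {
        pieces$exon <- exr
    }
    pieces$intron <- IRanges::setdiff(
        IRanges(min(start(exr)), max(end(exr))), exr)
    out <- list()
    for (region in names(pieces)) {
        r <- pieces[[region]]
        if (!length(r)) next
        ## transcript-sense order: ascending for +, descending for -
        ord <- if (strand == "+") order(start(r)) else order(-start(r))
        r <- r[ord]
        cumBefore <- cumsum(c(0L, width(r)))[seq_along(r)]
        gr <- GRanges(factor(chrom, seqLevels), r, strand = strand)
        mcols(gr) <- DataFrame(tx = tx, region = region,
                               region_length = sum(width(r)),
                               cum_before = cumBefore)
        out[[region]] <- gr
    }
    res <- do.call(c, unname(out))
    sort(res)
}

#' Sense-strand mRNA sequence of a transcript
#'
#' Concatenates the exon sequences in transcript order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param index an [AnnotationIndex-class].
#' @param transcriptId transcript identifier.
#' @return a character scalar (A/C/G/T/N).
#' @export
transcriptSequence <- function(index, transcriptId) {
    if (!transcriptId %in% index@txdata$transcript_id)
        stop("unknown transcript '", transcriptId, "'")
    ex <- sort(index@transcripts[[transcriptId]])
    chrom <- as.character(seqnames(ex))[1]
    seqs <- Biostrings::extractAt(index@genome[[chrom]], IRanges::ranges(ex))
    s <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
    if (as.character(strand(ex))[1] == "-")
        s <- Biostrings::reverseComplement(s)
    as.character(s)
}

#' Map genomic positions into transcript feature space
#'
#' For each (position, transcript) pair, reports the feature region
#' (`utr5`, `cds`, `utr3`, `intron`, or `exon` for non-coding transcripts),
#' the 0-based offset of the position within that region measured 5'->3' in
#' mRNA sense, and the total region length. Positions outside the
#' transcript span yield region `"none"` with `NA` offsets.
#'
#' @param index an [AnnotationIndex-class].
#' @param transcriptId character vector of transcript ids (recycled to the
#'   length of `position`).
#' @param position integer vector of 1-based genomic positions.
#' @return data.frame with columns `region`, `offset`, `region_length`.
#' @export
genomicToMeta <- function(index, transcriptId, position) {
    n <- max(length(position), length(transcriptId))
    transcriptId <- rep_len(transcriptId, n)
    position <- rep_len(as.integer(position), n)
    chrom <- index@txdata$chrom[match(transcriptId,
                                      index@txdata$transcript_id)]
    if (anyNA(chrom)) stop("unknown transcript id(s)")
    q <- GRanges(chrom, IRanges(position, width = 1L))
    hits <- GenomicRanges::findOverlaps(q, index@features,
                                        ignore.strand = TRUE)
    ok <- index@features$tx[subjectHits(hits)] ==
        transcriptId[queryHits(hits)]
    hits <- hits[ok]
    out <- data.frame(region = rep("none", n),
                      offset = rep(NA_integer_, n),
                      region_length = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
    if (length(hits)) {
        qi <- queryHits(hits); si <- subjectHits(hits)
        f <- index@features[si]
        minus <- as.character(strand(f)) == "-"
        off <- ifelse(minus,
                      f$cum_before + (end(f) - position[qi]),
                      f$cum_before + (position[qi] - start(f)))
        out$region[qi] <- f$region
        out$offset[qi] <- as.integer(off)
        out$region_length[qi] <- f$region_length
    }
    out
}

#' Assign positions to representative transcripts
#'
#' A genomic position may fall within several transcript spans; operations
#' that need a single model take the transcript with the longest mRNA
#' (ties broken by transcript id). Strand-aware.
#'
#' @param index an [AnnotationIndex-class].
#' @param gr [GRanges] of positions (any width; span overlap decides).
#' @param ignoreStrand match irrespective of strand (default FALSE).
#' @return character vector of transcript ids, `NA` where no span matches.
#' @export
assignTranscripts <- function(index, gr, ignoreStrand = FALSE) {
    hits <- GenomicRanges::findOverlaps(gr, index@spans,
                                        ignore.strand = ignoreStrand)
    out <- rep(NA_character_, length(gr))
    if (!length(hits)) return(out)
    qi <- queryHits(hits); si <- subjectHits(hits)
    ord <- order(qi, -index@txdata$mrna_length[si],
                 index@txdata$transcript_id[si])
    qi <- qi[ord]; si <- si[ord]
    first <- !duplicated(qi)
    out[qi[first]] <- index@txdata$transcript_id[si[first]]
    out
}

#' Write transcript feature intervals as BED6
#'
#' One record per feature interval, `name = transcript:region`, score 0.
#'
#' @param index an [AnnotationIndex-class].
#' @param path output BED path.
#' @export
exportFeatureBed <- function(index, path) {
    f <- index@features
    out <- GRanges(seqnames(f), IRanges::ranges(f), strand = strand(f))
    out$name <- paste(f$tx, f$region, sep = ":")
    out$score <- 0L
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write an annotation index back to GTF
#'
#' Emits exon records for every transcript and CDS records for coding
#' transcripts; [loadAnnotation()] on the result reproduces the feature
#' tables.
#'
#' @param index an [AnnotationIndex-class].
#' @param path output GTF path.
#' @export
exportGtf <- function(index, path) {
    recs <- list()
    td <- index@txdata
    for (i in seq_len(nrow(td))) {
        tx <- td$transcript_id[i]
        ex <- sort(index@transcripts[[tx]])
        e <- GRanges(seqnames(ex), IRanges::ranges(ex), strand = strand(ex))
        e$type <- "exon"
        e$transcript_id <- tx
        e$gene_id <- td$gene_id[i]
        recs[[length(recs) + 1L]] <- e
        if (td$coding[i]) {
            f <- txFeatures(index, tx)
            cd <- f[f$region == "cds"]
            c2 <- GRanges(seqnames(cd), IRanges::ranges(cd),
                          strand = strand(cd))
            c2$type <- "CDS"
            ## reading-frame phase in transcript-sense order
            ord <- if (td$strand[i] == "+") order(start(c2))
                   else order(-start(c2))
            cum <- cumsum(c(0L, width(c2)[ord]))[seq_along(c2)]
            ph <- integer(length(c2))
            ph[ord] <- (3L - cum %% 3L) %% 3L
            c2$phase <- ph
            c2$transcript_id <- tx
            c2$gene_id <- td$gene_id[i]
            recs[[length(recs) + 1L]] <- c2
        }
    }
    all <- sort(do.call(c, recs), ignore.strand = TRUE)
    all$source <- "clipmod"
    rtracklayer::export(all, path, format = "gtf")
    invisible(path)
}
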