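#' @include AllClasses.R annotation.R truncations.R
NULL

#' Constructor for a synthetic-study specification
#'
#' Defaults describe the study conditions emulated throughout the test
#' suite: a compact multi-transcript genome, planted crosslink / m6A /
#' m6Am sites at 20-fold enrichment over a Poisson background of 0.5
#' truncation events per transcribed nucleotide, two replicates per
#' condition, and a knockdown condition with enrichment attenuated to 30%.
#'
#' @param seed master seed for the reference.
#' @param nTranscripts transcripts (one gene each; default 30).
#' @param utr5Range,cdsRange,utr3Range,intronRange feature length ranges
#'   in nt.
#' @param nIntronsRange introns per transcript (range).
#' @param nCrosslinkSites,nM6aSites,nM6amSites planted site counts.
#' @param enrichment fold increase of the truncation rate at planted sites
#'   (default 20).
#' @param backgroundRate expected truncation events per transcribed nt
#'   (default 0.5).
#' @param replicates libraries per condition (default 2).
#' @param knockdownAttenuation multiplier on enrichment under knockdown
#'   (default 0.3).
#' @param gfpArtifactFraction GFP-control artifact sites as a fraction of
#'   crosslink sites (default 0.05).
#' @param readLength emitted read length in nt (default 35).
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(seed = 1L, nTranscripts = 30L,
                           utr5Range = c(150L, 300L),
                           cdsRange = c(300L, 900L),
                           utr3Range = c(200L, 500L),
                           intronRange = c(100L, 400L),
                           nIntronsRange = c(1L, 3L),
                           nCrosslinkSites = 60L, nM6aSites = 50L,
                           nM6amSites = 30L, enrichment = 20,
                           backgroundRate = 0.5, replicates = 2L,
                           knockdownAttenuation = 0.3,
                           gfpArtifactFraction = 0.05,
                           readLength = 35L) {
    new("SimulationSpec", seed = as.integer(seed),
        nTranscripts = as.integer(nTranscripts),
        utr5Range = as.integer(utr5Range), cdsRange = as.integer(cdsRange),
        utr3Range = as.integer(utr3Range),
        intronRange = as.integer(intronRange),
        nIntronsRange = as.integer(nIntronsRange),
        nCrosslinkSites = as.integer(nCrosslinkSites),
        nM6aSites = as.integer(nM6aSites),
        nM6amSites = as.integer(nM6amSites),
        enrichment = as.numeric(enrichment),
        backgroundRate = as.numeric(backgroundRate),
        replicates = as.integer(replicates),
        knockdownAttenuation = as.numeric(knockdownAttenuation),
        gfpArtifactFraction = as.numeric(gfpArtifactFraction),
        readLength = as.integer(readLength))
}

## The 18 DRACH 5-mers on the DNA alphabet.
.drachVariants <- function() {
    v <- expand.grid(D = c("A", "G", "T"), R = c("A", "G"),
                     A = "A", C = "C", H = c("A", "C", "T"),
                     stringsAsFactors = FALSE)
    apply(v, 1, paste, collapse = "")
}

#' Generate a synthetic reference genome with planted truth
#'
#' Builds a random-base genome, lays out spliced transcripts with the
#' spec'd 5'UTR/CDS/3'UTR/intron architecture (alternating strands, one
#' gene per transcript), and plants three classes of ground-truth sites by
#' writing their sequence context into the genome: m6A sites receive a
#' DRACH 5-mer (flanked by Cs so exactly one DRACH is centered at the
#' site), m6Am sites an isolated adenosine within the first quarter of
#' their 5'UTR, and crosslink plus GFP-artifact sites need no context.
#' Planted contexts always fall within a single exon so the genomic and
#' spliced sequence agree, and all planted sites are mutually separated by
#' at least 15 nt. Deterministic under the spec seed.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [ClipSimulation-class].
#' @export
simulateReference <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    .withSeed(spec@seed, .simulateReferenceImpl(spec))
}

.simulateReferenceImpl <- function(spec) {
    nTx <- spec@nTranscripts
    perChrom <- 15L
    nChrom <- ceiling(nTx / perChrom)
    spacer <- 500L
    rint <- function(r) if (r[1] == r[2]) r[1]
                        else sample(seq(r[1], r[2]), 1L)
    txs <- vector("list", nTx)
    cursor <- rep(spacer + 1L, nChrom)
    for (i in seq_len(nTx)) {
        chrom <- ((i - 1L) %/% perChrom) + 1L
        strand <- if (i %% 2L == 1L) "+" else "-"
        u5 <- rint(spec@utr5Range); cd <- rint(spec@cdsRange)
        u3 <- rint(spec@utr3Range)
        mrna <- u5 + cd + u3
        nInt <- rint(spec@nIntronsRange)
        intLens <- vapply(seq_len(nInt), function(j) rint(spec@intronRange),
                          integer(1))
        repeat {  # exons at least 30 nt so planted contexts have room
            breaks <- sort(sample(seq(30L, mrna - 30L), nInt))
            if (nInt < 2L || min(diff(breaks)) >= 30L) break
        }
        segStarts <- c(1L, breaks)           # sense mRNA starts of exons
        segEnds <- c(breaks - 1L, mrna)
        exLens <- segEnds - segStarts + 1L
        ## genomic layout: sense exon order for +, reversed for -
        ord <- if (strand == "+") seq_along(exLens) else rev(seq_along(exLens))
        gStart <- integer(length(exLens)); gEnd <- integer(length(exLens))
        pos <- cursor[chrom]
        for (j in seq_along(ord)) {
            e <- ord[j]
            gStart[e] <- pos
            gEnd[e] <- pos + exLens[e] - 1L
            pos <- gEnd[e] + 1L
            if (j < length(ord)) {
                intIdx <- if (strand == "+") e else e - 1L
                pos <- pos + intLens[intIdx]
            }
        }
        cursor[chrom] <- pos + spacer
        txs[[i]] <- list(id = sprintf("TX%04d", i),
                         gene = sprintf("G%04d", i),
                         chrom = paste0("chrS", chrom), strand = strand,
                         u5 = u5, cd = cd, u3 = u3, mrna = mrna,
                         segStarts = segStarts, segEnds = segEnds,
                         gStart = gStart, gEnd = gEnd)
    }
    chromLens <- as.integer(cursor + spacer)
    names(chromLens) <- paste0("chrS", seq_len(nChrom))
    genomeChars <- lapply(chromLens, function(n)
        sample(c("A", "C", "G", "T"), n, replace = TRUE))

    senseToGenomic <- function(tx, m) {
        ## m: 1-based sense mRNA position -> genomic position
        e <- findInterval(m, tx$segStarts)
        off <- m - tx$segStarts[e]
        if (tx$strand == "+") tx$gStart[e] + off else tx$gEnd[e] - off
    }
    sameExonWindow <- function(tx, m, arm) {
        e1 <- findInterval(m - arm, tx$segStarts)
        e2 <- findInterval(m + arm, tx$segStarts)
        m - arm >= 1L && m + arm <= tx$mrna && e1 == e2
    }
    used <- lapply(chromLens, function(n) integer(0))
    farEnough <- function(chrom, p, minDist = 15L) {
        !length(used[[chrom]]) || min(abs(used[[chrom]] - p)) >= minDist
    }
    claim <- function(chrom, p) used[[chrom]][length(used[[chrom]]) + 1L] <<- p
    writeSense <- function(tx, gpos, senseStr) {
        ## write a sense-strand context centered at gpos into the genome
        s <- strsplit(senseStr, "")[[1]]
        if (tx$strand == "-")
            s <- rev(chartr("ACGT", "TGCA", s))
        arm <- (length(s) - 1L) %/% 2L
        genomeChars[[tx$chrom]][(gpos - arm):(gpos + arm)] <<- s
    }

    drach <- .drachVariants()
    plant <- function(n, klass) {
        if (n == 0L)
            return(GRanges())
        out <- vector("list", n)
        tries <- 0L
        k <- 1L
        while (k <= n) {
            tries <- tries + 1L
            if (tries > 200L * n)
                stop("infeasible spec: could not place ", n, " ", klass,
                     " sites (constraint: spacing/region too tight)")
            tx <- txs[[sample.int(nTx, 1L)]]
            if (klass == "m6am") {
                lim <- floor(tx$u5 / 4)
                if (lim < 10L) next
                m <- sample(seq(3L, lim - 2L), 1L) # sense offset+1 (1-based)
                if (!sameExonWindow(tx, m, 2L)) next
                gpos <- senseToGenomic(tx, m)
                if (!farEnough(tx$chrom, gpos)) next
                writeSense(tx, gpos, "CCACC")
                motif <- "A1"
            } else if (klass == "m6a") {
                lo <- tx$u5 + 6L; hi <- tx$mrna - 6L
                m <- sample(seq(lo, hi), 1L)
                if (!sameExonWindow(tx, m, 4L)) next
                gpos <- senseToGenomic(tx, m)
                if (!farEnough(tx$chrom, gpos)) next
                motif <- drach[sample.int(length(drach), 1L)]
                writeSense(tx, gpos, paste0("CC", motif, "CC"))
            } else { # crosslink / gfp artifact: anywhere in the span
                span <- range(c(tx$gStart, tx$gEnd))
                gpos <- sample(seq(span[1] + 5L, span[2] - 5L), 1L)
                if (!farEnough(tx$chrom, gpos)) next
                motif <- NA_character_
                m <- NA_integer_
            }
            claim(tx$chrom, gpos)
            out[[k]] <- GRanges(factor(tx$chrom, names(chromLens)),
                                IRanges(gpos, width = 1L),
                                strand = tx$strand, tx = tx$id,
                                motif = motif,
                                sense_pos = if (klass %in% c("m6a", "m6am"))
                                    m else NA_integer_)
            k <- k + 1L
        }
        sort(do.call(c, out), ignore.strand = TRUE)
    }
    truth <- list(
        m6a = plant(spec@nM6aSites, "m6a"),
        m6am = plant(spec@nM6amSites, "m6am"),
        crosslink = plant(spec@nCrosslinkSites, "crosslink"),
        gfp_artifact = plant(max(if (spec@nCrosslinkSites > 0) 1L else 0L,
                                 round(spec@gfpArtifactFraction *
                                       spec@nCrosslinkSites)),
                             "gfp"))

    genome <- DNAStringSet(vapply(genomeChars, paste, "", collapse = ""))
    names(genome) <- names(chromLens)
    exons <- GRangesList(lapply(txs, function(tx)
        GRanges(tx$chrom, IRanges(sort(tx$gStart), sort(tx$gEnd)),
                strand = tx$strand)))
    names(exons) <- vapply(txs, `[[`, "", "id")
    ## CDS genomic intervals: sense mRNA window [u5+1, u5+cd]
    cdsList <- lapply(txs, function(tx) {
        a <- tx$u5 + 1L; b <- tx$u5 + tx$cd
        ivs <- list()
        for (e in seq_along(tx$segStarts)) {
            lo <- max(a, tx$segStarts[e]); hi <- min(b, tx$segEnds[e])
            if (lo > hi) next
            g1 <- senseToGenomic(tx, lo); g2 <- senseToGenomic(tx, hi)
            ivs[[length(ivs) + 1L]] <-
                IRanges(min(g1, g2), max(g1, g2))
        }
        GRanges(tx$chrom, do.call(c, ivs), strand = tx$strand)
    })
    names(cdsList) <- names(exons)
    geneIds <- structure(vapply(txs, `[[`, "", "gene"), names = names(exons))
    index <- buildAnnotationIndex(exons, GRangesList(cdsList), geneIds,
                                  genome)
    ## truth-consistency assertions (contexts verifiable from sequence)
    if (length(truth$m6a)) {
        ctx <- .truthContexts(genome, truth$m6a, 2L)
        stopifnot(all(substr(ctx, 3L, 3L) == "A"),
                  all(grepl("^[AGT][AG]AC[ACT]$", ctx)))
    }
    if (length(truth$m6am)) {
        ctx <- .truthContexts(genome, truth$m6am, 0L)
        stopifnot(all(ctx == "A"))
    }
    new("ClipSimulation", genome = genome, index = index, truth = truth,
        spec = spec)
}

## sense-strand (2*arm+1)-mers centered on width-1 sites
.truthContexts <- function(genome, sites, arm) {
    vapply(seq_along(sites), function(i) {
        chrom <- as.character(seqnames(sites))[i]
        p <- start(sites)[i]
        as.character(.senseSeq(genome, chrom, p - arm, p + arm,
                               as.character(strand(sites))[i]))
    }, character(1))
}

## Planted-site set and enrichment factor per library condition.
.conditionSites <- function(sim, condition) {
    E <- sim@spec@enrichment
    switch(condition,
        wildtype = list(sites = c(sim@truth$crosslink, sim@truth$m6a,
                                  sim@truth$m6am), factor = E),
        knockdown = list(sites = c(sim@truth$crosslink, sim@truth$m6a,
                                   sim@truth$m6am),
                         factor = E * sim@spec@knockdownAttenuation),
        miclip = list(sites = c(sim@truth$m6a, sim@truth$m6am), factor = E),
        miclip_knockdown = list(sites = c(sim@truth$m6a, sim@truth$m6am),
                                factor = E * sim@spec@knockdownAttenuation),
        smi = list(sites = GRanges(), factor = 1),
        gfp = list(sites = sim@truth$gfp_artifact, factor = E),
        stop("unknown condition '", condition, "'"))
}

#' Simulate one CLIP/miCLIP library as aligned read records
#'
#' Draws truncation events per transcribed nucleotide from a Poisson
#' distribution at the spec's background rate, multiplied by the
#' enrichment factor at the planted sites of the chosen condition
#' (`wildtype` and `knockdown` libraries are enriched at crosslink, m6A
#' and m6Am sites; `miclip` and `miclip_knockdown` at m6A/m6Am sites only;
#' `smi` nowhere; `gfp` at its own artifact sites). Knockdown conditions
#' multiply the enrichment by the spec's attenuation. Each event at
#' position p is emitted as one read starting 1 nt 3' of p in read
#' orientation, so [extractTruncations()] inverts the construction
#' exactly. Deterministic under `seed`.
#'
#' @param sim a [ClipSimulation-class] from [simulateReference()].
#' @param condition one of `"wildtype"`, `"knockdown"`, `"miclip"`,
#'   `"miclip_knockdown"`, `"smi"`, `"gfp"`.
#' @param replicate replicate number (recorded in the sample id).
#' @param seed integer seed for this library.
#' @return list with `reads` ([GRanges] of read alignments), `track`
#'   (the matching [TruncationTrack-class]), `sampleId`, `condition`,
#'   `replicate`, and `rates` (width-1 [GRanges] of enriched positions
#'   with their expected per-nt event rate).
#' @export
simulateClipLibrary <- function(sim, condition = "wildtype",
                                replicate = 1L, seed) {
    stopifnot(is(sim, "ClipSimulation"))
    if (missing(seed)) stop("a seed is required")
    cs <- .conditionSites(sim, condition)
    spec <- sim@spec
    sampleIdStr <- sprintf("%s_rep%d", condition, replicate)
    .withSeed(seed, {
        spans <- sim@index@spans
        std <- as.character(strand(spans))
        events <- vector("list", length(spans))
        enr <- cs$sites
        for (i in seq_along(spans)) {
            s <- start(spans)[i]; e <- end(spans)[i]
            lam <- rep(spec@backgroundRate, e - s + 1L)
            if (length(enr)) {
                here <- as.character(seqnames(enr)) ==
                        as.character(seqnames(spans))[i] &
                        as.character(strand(enr)) == std[i] &
                        start(enr) >= s & start(enr) <= e
                lam[start(enr)[here] - s + 1L] <-
                    spec@backgroundRate * cs$factor
            }
            cnt <- stats::rpois(length(lam), lam)
            nz <- which(cnt > 0L)
            if (!length(nz)) next
            events[[i]] <- GRanges(
                factor(as.character(seqnames(spans))[i], names(sim@genome)),
                IRanges(s + nz - 1L, width = 1L),
                strand = std[i], count = cnt[nz])
        }
        ev <- do.call(c, events[!vapply(events, is.null, TRUE)])
        if (is.null(ev)) ev <- GRanges()
        reads <- .eventsToReads(ev, spec@readLength, structure(Biostrings::width(sim@genome), names = names(sim@genome)))
        track <- truncationTrack(ev, sampleIdStr)
        rates <- cs$sites
        if (length(rates))
            rates$expected_rate <- spec@backgroundRate * cs$factor
        list(reads = reads, track = track, sampleId = sampleIdStr,
             condition = condition, replicate = replicate, rates = rates)
    })
}

## one read per event, starting 1 nt 3' of the truncation position
.eventsToReads <- function(ev, readLength, chromLens) {
    if (!length(ev)) return(GRanges())
    idx <- rep(seq_along(ev), ev$count)
    pos <- start(ev)[idx]
    chrom <- as.character(seqnames(ev))[idx]
    std <- as.character(strand(ev))[idx]
    lim <- chromLens[chrom]
    rs <- ifelse(std == "+", pos + 1L, pmax(1L, pos - readLength))
    re <- ifelse(std == "+", pmin(pos + readLength, lim), pos - 1L)
    ok <- rs >= 1L & re <= lim & rs <= re
    out <- GRanges(factor(chrom[ok], names(chromLens)),
                   IRanges(rs[ok], re[ok]), strand = std[ok])
    out$name <- sprintf("read%07d", seq_along(out))
    out$score <- 0L
    out
}

#' Simulate per-gene log2 fold changes with a planted target shift
#'
#' Non-target genes draw log2 fold changes from Normal(0, sd); target
#' genes from Normal(-effect, sd). Genes carrying planted crosslink sites
#' are always targets; additional synthetic genes pad the universe to
#' `nGenes` and are labelled targets until `targetFraction` is reached.
#'
#' @param sim a [ClipSimulation-class].
#' @param effect mean downward log2 fold-change shift of targets
#'   (default 0.3).
#' @param nGenes total genes in the universe (default 2000).
#' @param targetFraction fraction of targets (default 0.15).
#' @param sd noise standard deviation (default 0.5).
#' @param seed integer seed.
#' @return data.frame with `gene_id`, `log2fc`, `is_target`.
#' @export
simulateGeneFoldchanges <- function(sim, effect = 0.3, nGenes = 2000L,
                                    targetFraction = 0.15, sd = 0.5, seed) {
    if (missing(seed)) stop("a seed is required")
    .withSeed(seed, {
        td <- sim@index@txdata
        truthGenes <- unique(td$gene_id[match(sim@truth$crosslink$tx,
                                              td$transcript_id)])
        extra <- max(0L, as.integer(nGenes) - nrow(td))
        ids <- c(td$gene_id, sprintf("SG%05d", seq_len(extra)))
        nTarget <- max(length(truthGenes),
                       round(targetFraction * length(ids)))
        others <- setdiff(ids, truthGenes)
        targets <- c(truthGenes,
                     sample(others, max(0L, nTarget - length(truthGenes))))
        isT <- ids %in% targets
        lfc <- stats::rnorm(length(ids), mean = ifelse(isT, -effect, 0),
                            sd = sd)
        data.frame(gene_id = ids, log2fc = lfc, is_target = isT,
                   stringsAsFactors = FALSE)
    })
}

#' Write a simulation (and optional libraries) to disk
#'
#' Emits `genome.fa` (with `.fai` index), `annotation.gtf`, per-class
#' truth TSVs, one BED6 read file per supplied library, and a
#' `samples.tsv` sample sheet (`sample_id`, `path`, `group`).
#'
#' @param sim a [ClipSimulation-class].
#' @param libs optional list of libraries from [simulateClipLibrary()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, libs = list(), dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim@genome, fa)
    Rsamtools::indexFa(fa)
    exportGtf(sim@index, file.path(dir, "annotation.gtf"))
    for (nm in names(sim@truth)) {
        t <- sim@truth[[nm]]
        df <- data.frame(chrom = as.character(seqnames(t)),
                         position = start(t),
                         strand = as.character(strand(t)),
                         tx = if (length(t)) t$tx else character(0),
                         motif = if (length(t)) t$motif else character(0))
        utils::write.table(df, file.path(dir, paste0("truth_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(libs)) {
        rows <- lapply(libs, function(lib) {
            bed <- file.path(dir, paste0(lib$sampleId, ".reads.bed"))
            rtracklayer::export(lib$reads, bed, format = "BED")
            data.frame(sample_id = lib$sampleId, path = bed,
                       group = lib$condition)
        })
        utils::write.table(do.call(rbind, rows),
                           file.path(dir, "samples.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

#' Round-trip a simulation spec through YAML
#'
#' @param spec a [SimulationSpec-class].
#' @param path YAML path.
#' @export
writeSimulationSpec <- function(spec, path) {
    slots <- slotNames(spec)
    vals <- lapply(slots, function(s) slot(spec, s))
    names(vals) <- slots
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' @rdname writeSimulationSpec
#' @return [SimulationSpec-class] for `readSimulationSpec`.
#' @export
readSimulationSpec <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(simulationSpec, vals)
}
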