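suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

## chrom/strand/position key for width-1 site sets
siteKey <- function(g) paste(seqnames(g), strand(g), start(g))

## Two-transcript index matching the canonical worked example:
## exons [1,100] and [201,300] (1-based), CDS spanning [51,250]; TXP on +,
## TXM the same structure on -. Genome is a fixed random 600 bp sequence.
twoTxIndex <- function(seed = 5) {
    genome <- DNAStringSet(c(
        chrA = paste(sample2(c("A", "C", "G", "T"), 600, seed = seed),
                     collapse = ""),
        chrB = paste(sample2(c("A", "C", "G", "T"), 600, seed = seed + 1),
                     collapse = "")))
    exons <- GRangesList(
        TXP = GRanges("chrA", IRanges(c(1, 201), c(100, 300)),
                      strand = "+"),
        TXM = GRanges("chrB", IRanges(c(1, 201), c(100, 300)),
                      strand = "-"))
    cds <- GRangesList(
        TXP = GRanges("chrA", IRanges(c(51, 201), c(100, 250)),
                      strand = "+"),
        TXM = GRanges("chrB", IRanges(c(51, 201), c(100, 250)),
                      strand = "-"))
    buildAnnotationIndex(exons, cds,
                         c(TXP = "GP", TXM = "GM"), genome)
}

## deterministic sampling without touching the global RNG state
sample2 <- function(x, n, seed, replace = TRUE) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(x, n, replace = replace)
}

## memoized default simulation so several test files can share it
.fixtureCache <- new.env(parent = emptyenv())
cachedSim <- function(key = "default", maker = function()
                          simulateReference(simulationSpec(seed = 42))) {
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- maker()
    .fixtureCache[[key]]
}

## ---- independent brute-force oracles -------------------------------------

## all DRACH 5-mer centers in a genomic window, by direct enumeration of the
## 18 consensus variants over per-base extracted sense sequence
oracleDrachCenters <- function(genomeChar, s, e, strandChar) {
    variants <- apply(expand.grid(c("A", "G", "T"), c("A", "G"), "A", "C",
                                  c("A", "C", "T"),
                                  stringsAsFactors = FALSE),
                      1, paste, collapse = "")
    hits <- integer(0)
    for (p in s:e) {
        if (p - 2 < 1 || p + 2 > nchar(genomeChar)) next
        win <- substr(genomeChar, p - 2, p + 2)
        if (strandChar == "-") {
            win <- chartr("ACGT", "TGCA", win)
            win <- paste(rev(strsplit(win, "")[[1]]), collapse = "")
        }
        if (win %in% variants) hits <- c(hits, p)
    }
    sort(hits)
}

## maximal sense-strand A-runs in [s, e]; returns genomic position of the
## 5'-most A of each run
oracleAruns <- function(genomeChar, s, e, strandChar) {
    bases <- strsplit(substr(genomeChar, s, e), "")[[1]]
    pos <- s:e
    if (strandChar == "-") {
        bases <- rev(strsplit(chartr("ACGT", "TGCA",
                                     paste(bases, collapse = "")),
                              "")[[1]])
        pos <- rev(pos)
    }
    isA <- bases == "A"
    out <- integer(0)
    i <- 1
    while (i <= length(isA)) {
        if (isA[i]) {
            out <- c(out, pos[i])          # 5'-most A of the run
            while (i <= length(isA) && isA[i]) i <- i + 1
        } else i <- i + 1
    }
    sort(out)
}

## single-linkage clustering of integer positions: same cluster when
## consecutive sorted positions differ by <= maxDiff
oracleClusters <- function(positions, maxDiff) {
    p <- sort(unique(positions))
    if (!length(p)) return(list())
    cl <- cumsum(c(1L, as.integer(diff(p) > maxDiff)))
    split(p, cl)
}

## exact binomial upper tail by direct summation
oracleBinomTail <- function(k, n, prob) {
    sum(vapply(k:n, function(i)
        choose(n, i) * prob^i * (1 - prob)^(n - i), numeric(1)))
}

## O(n*m) interval overlap after symmetric extension
oracleOverlapFraction <- function(aStart, aEnd, bStart, bEnd, ext) {
    as <- aStart - ext; ae <- aEnd + ext
    bs <- bStart - ext; be <- bEnd + ext
    hit <- vapply(seq_along(as), function(i)
        any(as[i] <= be & ae[i] >= bs), logical(1))
    mean(hit)
}

## exact two-sided Mann-Whitney by full enumeration of group assignments
oracleMannWhitney <- function(x, y) {
    n <- length(x); m <- length(y)
    all <- c(x, y)
    r <- rank(all)
    uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    us <- apply(combos, 2, function(ix)
        sum(rank(all)[ix]) - n * (n + 1) / 2)
    center <- n * m / 2
    pv <- mean(abs(us - center) >= abs(uObs - center))
    list(U = uObs, p = pv)
}
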