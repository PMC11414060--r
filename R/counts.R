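#' @include AllClasses.R truncations.R
NULL

#' Per-site truncation-count matrix across samples
#'
#' For every site and sample, sums truncation counts within the site window
#' `[site - flank, site + flank]` (strand-aware). Per-sample size factors
#' are computed by the median-of-ratios method over rows with no zero
#' count; when fewer than 10 such rows exist the factors fall back to
#' library-size ratios (each library size divided by the geometric mean of
#' library sizes). Sites on a chromosome absent from a track score 0 with a
#' warning.
#'
#' @param sites width-1 site [GRanges] (e.g. m6A sites or CITS).
#' @param tracks named list of [TruncationTrack-class] objects; names are
#'   sample ids (defaults to each track's `sampleId`).
#' @param flank half-window in nt (default 2, mirroring the classification
#'   window).
#' @return a [SiteCountMatrix-class].
#' @export
countSites <- function(sites, tracks, flank = 2L) {
    stopifnot(length(sites) > 0, length(tracks) > 0)
    if (is.null(names(tracks)))
        names(tracks) <- vapply(tracks, sampleId, character(1))
    flank <- as.integer(flank)
    win <- GenomicRanges::resize(sites, 2L * flank + 1L, fix = "center")
    win <- GenomicRanges::trim(win)
    mat <- matrix(0L, nrow = length(sites), ncol = length(tracks),
                  dimnames = list(NULL, names(tracks)))
    for (j in seq_along(tracks)) {
        tr <- tracks[[j]]@sites
        missing <- setdiff(unique(as.character(seqnames(sites))),
                           unique(as.character(seqnames(tr))))
        if (length(missing))
            warning("sample '", names(tracks)[j],
                    "' has no events on: ", paste(missing, collapse = ", "))
        hits <- GenomicRanges::findOverlaps(win, tr, ignore.strand = FALSE)
        if (length(hits)) {
            s <- rowsum(tr$count[subjectHits(hits)], queryHits(hits))
            mat[as.integer(rownames(s)), j] <- as.integer(s[, 1])
        }
    }
    rownames(mat) <- paste0(seqnames(sites), ":", start(sites), ":",
                            strand(sites))
    libSizes <- vapply(tracks, librarySize, numeric(1))
    sf <- .medianOfRatios(mat, libSizes)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat),
        rowRanges = sites,
        colData = DataFrame(sample_id = names(tracks),
                            library_size = libSizes,
                            sizeFactor = sf,
                            row.names = names(tracks)))
    new("SiteCountMatrix", se)
}

## DESeq-style median-of-ratios; library-size fallback below 10 usable rows.
.medianOfRatios <- function(mat, libSizes) {
    logGeo <- rowMeans(log(mat))
    usable <- is.finite(logGeo)
    if (sum(usable) >= 10L) {
        apply(mat[usable, , drop = FALSE], 2, function(col)
            exp(stats::median(log(col) - logGeo[usable])))
    } else {
        libSizes / exp(mean(log(libSizes)))
    }
}

#' @rdname SiteCountMatrix-class
#' @param object a `SiteCountMatrix`.
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "SiteCountMatrix", function(object, ...)
    structure(object$sizeFactor, names = colnames(object)))

#' Size-factor-normalized counts
#'
#' @param x a [SiteCountMatrix-class].
#' @return numeric matrix of counts divided column-wise by size factors.
#' @export
normalizedCounts <- function(x) {
    m <- SummarizedExperiment::assay(x, "counts")
    t(t(m) / sizeFactors(x))
}

#' Compare groups of values by rank test or ANOVA with Tukey HSD
#'
#' Two groups are compared by a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test; three or more groups by one-way ANOVA with Tukey HSD post hoc
#' contrasts. For a [SiteCountMatrix-class], values are size-factor
#' normalized counts pooled per column group across sites; for a numeric
#' vector (e.g. per-gene log2 fold changes), values are used as-is.
#'
#' @param x numeric vector or [SiteCountMatrix-class].
#' @param groups factor of group labels: one per value (vector input) or
#'   one per sample column (matrix input). All groups must be non-empty.
#' @return a [GroupComparison-class].
#' @export
setGeneric("compareGroups", function(x, groups)
    standardGeneric("compareGroups"))

#' @rdname compareGroups
#' @export
setMethod("compareGroups", "numeric", function(x, groups) {
    groups <- droplevels(as.factor(groups))
    if (length(groups) != length(x))
        stop("groups must have one label per value")
    if (nlevels(groups) < 2L) stop("need at least two groups")
    if (any(table(groups) == 0L)) stop("every group must be non-empty")
    means <- tapply(x, groups, mean)
    sizes <- as.integer(table(groups))
    names(sizes) <- levels(groups)
    if (nlevels(groups) == 2L) {
        wt <- stats::wilcox.test(x[groups == levels(groups)[1]],
                                 x[groups == levels(groups)[2]],
                                 alternative = "two.sided",
                                 correct = TRUE, exact = FALSE)
        new("GroupComparison", method = "wilcoxon",
            statistic = unname(wt$statistic), pValue = wt$p.value,
            groupMeans = structure(as.numeric(means),
                                   names = names(means)),
            groupSizes = sizes,
            pairwise = data.frame(contrast = character(0),
                                  diff = numeric(0), p_adj = numeric(0)))
    } else {
        fit <- stats::aov(x ~ groups)
        an <- summary(fit)[[1]]
        tk <- stats::TukeyHSD(fit)$groups
        new("GroupComparison", method = "anova_tukey",
            statistic = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
            groupMeans = structure(as.numeric(means),
                                   names = names(means)),
            groupSizes = sizes,
            pairwise = data.frame(contrast = rownames(tk),
                                  diff = tk[, "diff"],
                                  p_adj = tk[, "p adj"],
                                  row.names = NULL))
    }
})

#' @rdname compareGroups
#' @export
setMethod("compareGroups", "SiteCountMatrix", function(x, groups) {
    groups <- droplevels(as.factor(groups))
    if (length(groups) != ncol(x))
        stop("groups must have one label per sample column")
    norm <- normalizedCounts(x)
    vals <- as.vector(norm)
    lab <- factor(rep(as.character(groups), each = nrow(norm)),
                  levels = levels(groups))
    compareGroups(vals, lab)
})

#' Relative quantification by the delta-delta-CT method
#'
#' `RQ = 2 ^ -((ctTarget - ctRef) - (ctTarget0 - ctRef0))`: threshold
#' cycles of the target normalized to a reference gene and to the baseline
#' time point. Exactly invertible: `-log2(RQ)` recovers the delta-delta-CT.
#'
#' @param ctTarget,ctRef threshold cycles of target and reference gene at
#'   the measured time point.
#' @param ctTarget0,ctRef0 threshold cycles at the baseline time point.
#' @return relative quantity (vectorized).
#' @examples
#' ddct(21, 11, 20, 10)   # ddCT = 0 -> 1
#' ddct(22, 11, 20, 10)   # ddCT = 1 -> 0.5
#' @export
ddct <- function(ctTarget, ctRef, ctTarget0, ctRef0) {
    stopifnot(all(is.finite(c(ctTarget, ctRef, ctTarget0, ctRef0))))
    2^-((ctTarget - ctRef) - (ctTarget0 - ctRef0))
}

#' Compare fold changes of target and non-target genes
#'
#' Partitions per-gene log2 fold changes into targets (e.g. genes with
#' binding sites, or m6A-containing genes) and non-targets, and compares
#' the two distributions via [compareGroups()].
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param targetGenes character vector of target gene ids.
#' @return a [GroupComparison-class] with groups `target` / `non_target`.
#' @export
targetVsNontargetFoldchange <- function(log2fc, targetGenes) {
    if (is.null(names(log2fc)))
        stop("log2fc must be named by gene id")
    inTarget <- names(log2fc) %in% targetGenes
    if (!any(inTarget))
        stop("no overlap between gene ids of log2fc and targetGenes")
    if (all(inTarget))
        stop("every gene is a target; the non-target group is empty")
    groups <- factor(ifelse(inTarget, "target", "non_target"),
                     levels = c("target", "non_target"))
    compareGroups(unname(log2fc), groups)
}
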