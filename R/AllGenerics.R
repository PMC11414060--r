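#' @include AllClasses.R
NULL

#' Constructor for CITS-calling parameters
#'
#' @param fdrThreshold BH FDR cutoff (default 0.01).
#' @param minCount minimum truncation count to test a position (default 2).
#' @param mergeGap maximum intervening bases for replicate merging
#'   (default 0).
#' @return a [CitsParams-class] object.
#' @examples
#' citsParams()
#' citsParams(fdrThreshold = 0.05)
#' @export
citsParams <- function(fdrThreshold = 0.01, minCount = 2L, mergeGap = 0L) {
    new("CitsParams", fdrThreshold = as.numeric(fdrThreshold),
        minCount = as.integer(minCount), mergeGap = as.integer(mergeGap))
}

#' Constructor for m6A/m6Am classification parameters
#'
#' @param mergeGap maximum intervening bases for miCLIP replicate merging
#'   (default 1).
#' @param extend symmetric peak extension in nt (default 2).
#' @param utr5Fraction leading fraction of the 5'UTR qualifying m6Am
#'   candidates (default 0.25).
#' @param drachPattern IUPAC DNA pattern for the m6A consensus
#'   (default "DRACH").
#' @return a [ClassifyParams-class] object.
#' @export
classifyParams <- function(mergeGap = 1L, extend = 2L, utr5Fraction = 0.25,
                           drachPattern = "DRACH") {
    new("ClassifyParams", mergeGap = as.integer(mergeGap),
        extend = as.integer(extend), utr5Fraction = as.numeric(utr5Fraction),
        drachPattern = toupper(drachPattern))
}

#' @rdname TruncationTrack-class
#' @param object,x a `TruncationTrack`.
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname TruncationTrack-class
#' @export
setMethod("librarySize", "TruncationTrack", function(x) x@librarySize)

#' @rdname TruncationTrack-class
#' @export
setGeneric("truncationSites", function(x) standardGeneric("truncationSites"))

#' @rdname TruncationTrack-class
#' @export
setMethod("truncationSites", "TruncationTrack", function(x) x@sites)

#' @rdname TruncationTrack-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname TruncationTrack-class
#' @export
setMethod("sampleId", "TruncationTrack", function(x) x@sampleId)

setMethod("show", "TruncationTrack", function(object) {
    cat("TruncationTrack '", object@sampleId, "': ",
        length(object@sites), " positions, ",
        format(object@librarySize, big.mark = ","),
        " truncation events\n", sep = "")
    if (any(object@dropped > 0L)) {
        d <- object@dropped[object@dropped > 0L]
        cat("  dropped records:",
            paste(names(d), d, sep = "=", collapse = ", "), "\n")
    }
})

#' @rdname AnnotationIndex-class
#' @param x an `AnnotationIndex`.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname AnnotationIndex-class
#' @export
setMethod("transcriptIds", "AnnotationIndex",
          function(x) x@txdata$transcript_id)

#' @rdname AnnotationIndex-class
#' @export
setGeneric("txFeatures", function(x, ...) standardGeneric("txFeatures"))

#' Feature intervals of one transcript (or all)
#'
#' @rdname AnnotationIndex-class
#' @param ... for `txFeatures`: `transcript` (optional id).
#' @param transcript optional transcript id; all features if omitted.
#' @export
setMethod("txFeatures", "AnnotationIndex", function(x, transcript = NULL) {
    if (is.null(transcript)) return(x@features)
    x@features[x@features$tx == transcript]
})

setMethod("show", "AnnotationIndex", function(object) {
    n <- nrow(object@txdata)
    cat("AnnotationIndex:", n, "transcripts (",
        sum(object@txdata$coding), "coding ) on",
        length(object@genome), "sequence(s)\n")
})

setMethod("show", "AnchorProfile", function(object) {
    cat("AnchorProfile: ", object@nAnchors, " anchors, window +/-",
        object@window, " nt, quantified +/-", object@quantWindow, " nt\n",
        sep = "")
    cat(sprintf("  Wilcoxon rank-sum vs matched random sites: U = %.1f, p = %.3g\n",
                object@statistic, object@pValue))
})

#' @rdname AnchorProfile-class
#' @param x an `AnchorProfile`.
#' @export
setGeneric("perSiteSums", function(x) standardGeneric("perSiteSums"))

#' Per-site summed densities (+/-Q window) for anchors and matched null
#' @rdname AnchorProfile-class
#' @export
setMethod("perSiteSums", "AnchorProfile", function(x)
    list(anchors = x@siteSums, random = x@nullSums))

#' Profile table (offset, mean, sem, null_mean, null_sem)
#' @rdname AnchorProfile-class
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname AnchorProfile-class
#' @export
setMethod("profileTable", "AnchorProfile", function(x)
    data.frame(offset = x@offsets, mean = x@mean, sem = x@sem,
               null_mean = x@nullMean, null_sem = x@nullSem))

setMethod("show", "GroupComparison", function(object) {
    cat("GroupComparison (", object@method, "): ", sep = "")
    cat(sprintf("statistic = %.4g, p = %.3g\n", object@statistic,
                object@pValue))
    cat("  group means:",
        paste(names(object@groupMeans),
              sprintf("%.4g", object@groupMeans), sep = "=",
              collapse = ", "), "\n")
    if (nrow(object@pairwise))
        cat("  ", nrow(object@pairwise), "Tukey HSD contrasts\n")
})

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec: ", object@nTranscripts, " transcripts; planted ",
        object@nCrosslinkSites, " crosslink / ", object@nM6aSites,
        " m6A / ", object@nM6amSites, " m6Am sites; enrichment ",
        object@enrichment, "x over ", object@backgroundRate,
        " events/nt background\n", sep = "")
})

setMethod("show", "ClipSimulation", function(object) {
    cat("ClipSimulation:", sum(Biostrings::width(object@genome)), "bp genome,",
        nrow(object@index@txdata), "transcripts\n")
    for (nm in names(object@truth))
        cat("  truth ", nm, ": ", length(object@truth[[nm]]), " sites\n",
            sep = "")
})

#' @rdname ClipSimulation-class
#' @param x a `ClipSimulation`.
#' @export
setGeneric("truthSites", function(x, ...) standardGeneric("truthSites"))

#' Planted truth sites of one class
#' @rdname ClipSimulation-class
#' @param ... for `truthSites`: `what`, one of `"crosslink"`, `"m6a"`,
#'   `"m6am"`, `"gfp_artifact"`.
#' @param what truth class name.
#' @export
setMethod("truthSites", "ClipSimulation", function(x, what = "m6a") {
    if (!what %in% names(x@truth))
        stop("unknown truth class '", what, "'")
    x@truth[[what]]
})

#' @rdname ClipSimulation-class
#' @export
setGeneric("annotationIndex", function(x) standardGeneric("annotationIndex"))

#' @rdname ClipSimulation-class
#' @export
setMethod("annotationIndex", "ClipSimulation", function(x) x@index)
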