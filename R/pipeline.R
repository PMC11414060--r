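#' @include AllClasses.R annotation.R truncations.R modsites.R metagene.R
#' @include anchor.R counts.R simulate.R
NULL

#' Default pipeline configuration
#'
#' Every numeric default equals the published value where one exists: CITS
#' FDR 0.01, miCLIP merge gap 1 bp, peak extension 2 bp, 5'UTR fraction
#' 0.25, overlap extension 50 nt, anchor quantification window 100 nt.
#'
#' @param fasta,gtf,samples input paths (may be NULL for `simulate`).
#' @param seed integer seed used by every randomized step.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(fasta = NULL, gtf = NULL, samples = NULL,
                           seed = 1L) {
    list(
        paths = list(fasta = fasta, gtf = gtf, samples = samples),
        cits = list(fdr_threshold = 0.01, min_count = 2, merge_gap = 0),
        classify = list(merge_gap = 1, extend = 2, utr5_fraction = 0.25,
                        drach_pattern = "DRACH"),
        metagene = list(bins_utr5 = 50, bins_cds = 100, bins_utr3 = 70),
        anchor = list(window = 500, quant_window = 100,
                      null_match = "stratified"),
        overlap = list(extend_nt = 50),
        counts = list(flank = 2),
        seed = as.integer(seed))
}

#' Validate a pipeline configuration
#'
#' Checks field types and ranges; stops with a message naming the first
#' offending field.
#'
#' @param config configuration list (see [pipelineConfig()]).
#' @return `TRUE`, invisibly.
#' @export
validatePipelineConfig <- function(config) {
    need <- function(cond, field, why) {
        if (!isTRUE(cond))
            stop("invalid config field '", field, "': ", why, call. = FALSE)
    }
    f <- config$cits$fdr_threshold
    need(is.numeric(f) && length(f) == 1 && f > 0 && f < 1,
         "cits.fdr_threshold", "must be a number in (0, 1)")
    need(config$cits$min_count >= 1, "cits.min_count", "must be >= 1")
    need(config$cits$merge_gap >= 0, "cits.merge_gap", "must be >= 0")
    need(config$classify$merge_gap >= 0, "classify.merge_gap",
         "must be >= 0")
    need(config$classify$extend >= 0, "classify.extend", "must be >= 0")
    u <- config$classify$utr5_fraction
    need(is.numeric(u) && u > 0 && u <= 1, "classify.utr5_fraction",
         "must lie in (0, 1]")
    need(config$anchor$window >= 1, "anchor.window", "must be >= 1")
    need(config$anchor$quant_window >= 1, "anchor.quant_window",
         "must be >= 1")
    need(config$overlap$extend_nt >= 0, "overlap.extend_nt",
         "must be >= 0")
    need(config$counts$flank >= 0, "counts.flank", "must be >= 0")
    need(is.numeric(config$seed) && length(config$seed) == 1,
         "seed", "must be a single integer")
    invisible(TRUE)
}

.logMsg <- function(level, ...) {
    message(format(Sys.time(), "[%H:%M:%S] "), level, ": ", ...)
}

.writeManifest <- function(outDir, subcommand, config, inputs, outputs) {
    manifest <- list(
        subcommand = subcommand,
        parameters = config[setdiff(names(config), "paths")],
        inputs = inputs,
        outputs = outputs,
        seed = config$seed,
        software = list(package = "clipmod",
                        version = as.character(utils::packageVersion("clipmod"))),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline subcommand
#'
#' Orchestrates the package's modules into the analysis flows:
#' `simulate` (reference + libraries + sample sheet), `cits` (truncation
#' extraction, CITS calling, GFP filtering, replicate merging), `classify`
#' (m6A/m6Am from two miCLIP replicates), `metagene`, `anchor`, `overlap`,
#' `counts` and `groups`. Each run validates the configuration, writes its
#' artifacts plus a JSON manifest (inputs, parameters, seed, software
#' version) into `outDir`, and never mutates its inputs.
#'
#' @param subcommand one of `"simulate"`, `"cits"`, `"classify"`,
#'   `"metagene"`, `"anchor"`, `"overlap"`, `"counts"`, `"groups"`.
#' @param config configuration list from [pipelineConfig()] or a YAML path.
#' @param outDir output directory.
#' @param ... subcommand-specific inputs: `spec` (simulate);
#'   `anchors` / `peaksA` / `peaksB` BED paths (anchor, overlap);
#'   `sites` BED path and `groups` sample-sheet column (counts, groups);
#'   `log2fc` / `targets` TSV paths (groups).
#' @return named list of written artifact paths, invisibly.
#' @export
runPipeline <- function(subcommand, config, outDir, ...) {
    if (is.character(config) && length(config) == 1 && file.exists(config))
        config <- utils::modifyList(pipelineConfig(), yaml::read_yaml(config))
    validatePipelineConfig(config)
    for (p in Filter(Negate(is.null), config$paths)) {
        if (!file.exists(p))
            stop("input file does not exist: ", p, call. = FALSE)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    extra <- list(...)
    .logMsg("INFO", "running subcommand '", subcommand, "'")
    out <- switch(subcommand,
        simulate = .cmdSimulate(config, outDir, extra),
        cits = .cmdCits(config, outDir, extra),
        classify = .cmdClassify(config, outDir, extra),
        metagene = .cmdMetagene(config, outDir, extra),
        anchor = .cmdAnchor(config, outDir, extra),
        overlap = .cmdOverlap(config, outDir, extra),
        counts = .cmdCounts(config, outDir, extra),
        groups = .cmdGroups(config, outDir, extra),
        stop("unknown subcommand '", subcommand, "'", call. = FALSE))
    .writeManifest(outDir, subcommand, config,
                   inputs = Filter(Negate(is.null), config$paths),
                   outputs = out)
    invisible(out)
}

.loadIndexFromConfig <- function(config) {
    loadAnnotation(config$paths$gtf, config$paths$fasta)
}

.readSampleSheet <- function(path) {
    ss <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("sample_id", "path", "group") %in% colnames(ss)))
        stop("sample sheet must have columns sample_id, path, group")
    ss
}

.tracksFromSheet <- function(ss) {
    tr <- lapply(seq_len(nrow(ss)), function(i)
        extractTruncations(ss$path[i], ss$sample_id[i]))
    names(tr) <- ss$sample_id
    tr
}

.cmdSimulate <- function(config, outDir, extra) {
    spec <- if (!is.null(extra$spec)) extra$spec
            else simulationSpec(seed = config$seed)
    sim <- simulateReference(spec)
    conds <- c("wildtype", "knockdown", "miclip", "smi", "gfp")
    libs <- list()
    for (ci in seq_along(conds)) {
        for (r in seq_len(spec@replicates)) {
            libs[[length(libs) + 1L]] <- simulateClipLibrary(
                sim, conds[ci], r,
                seed = config$seed + 1000L * ci + r)
        }
    }
    writeSimulation(sim, libs, outDir)
    writeSimulationSpec(spec, file.path(outDir, "spec.yaml"))
    list(genome = file.path(outDir, "genome.fa"),
         gtf = file.path(outDir, "annotation.gtf"),
         samples = file.path(outDir, "samples.tsv"))
}

.cmdCits <- function(config, outDir, extra) {
    index <- .loadIndexFromConfig(config)
    ss <- .readSampleSheet(config$paths$samples)
    params <- citsParams(config$cits$fdr_threshold, config$cits$min_count,
                         config$cits$merge_gap)
    group <- if (!is.null(extra$group)) extra$group else "wildtype"
    main <- ss[ss$group == group, , drop = FALSE]
    ctlRows <- ss[ss$group == "gfp", , drop = FALSE]
    if (!nrow(main)) stop("no samples in group '", group, "'")
    ctlPeaks <- GRanges()
    if (nrow(ctlRows)) {
        ctl <- .tracksFromSheet(ctlRows)
        ctlPeaks <- mergeReplicatePeaks(
            lapply(ctl, callCits, index = index, params = params),
            gap = config$cits$merge_gap)
    }
    peaks <- lapply(.tracksFromSheet(main), function(tr) {
        filterAgainstControl(callCits(tr, index, params), ctlPeaks)
    })
    merged <- mergeReplicatePeaks(peaks, gap = config$cits$merge_gap)
    bed <- file.path(outDir, paste0("cits_", group, ".bed"))
    out <- GRanges(seqnames(merged), IRanges::ranges(merged),
                   strand = strand(merged))
    out$name <- rep(group, length(out))
    out$score <- pmin(1000L, as.integer(round(merged$k)))
    rtracklayer::export(out, bed, format = "BED")
    list(cits_bed = bed)
}

.cmdClassify <- function(config, outDir, extra) {
    index <- .loadIndexFromConfig(config)
    ss <- .readSampleSheet(config$paths$samples)
    params <- classifyParams(config$classify$merge_gap,
                             config$classify$extend,
                             config$classify$utr5_fraction,
                             config$classify$drach_pattern)
    cparams <- citsParams(config$cits$fdr_threshold, config$cits$min_count)
    mi <- ss[ss$group == "miclip", , drop = FALSE]
    if (nrow(mi) < 2) stop("classify needs two miclip replicates")
    tracks <- .tracksFromSheet(mi[1:2, ])
    reps <- lapply(tracks, callCits, index = index, params = cparams)
    sites <- classifySites(reps[[1]], reps[[2]], index, params)
    m6aBed <- file.path(outDir, "m6A.bed")
    m6amBed <- file.path(outDir, "m6Am.bed")
    exportSitesBed(sites$m6a, m6aBed)
    exportSitesBed(sites$m6am, m6amBed)
    tsv <- file.path(outDir, "sites.tsv")
    both <- c(sites$m6a, sites$m6am)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(both)),
                   position = start(both),
                   strand = as.character(strand(both)),
                   klass = both$klass, motif = both$motif,
                   support = both$support,
                   peak_start = both$source_start,
                   peak_end = both$source_end),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    list(m6a_bed = m6aBed, m6am_bed = m6amBed, sites_tsv = tsv)
}

.cmdMetagene <- function(config, outDir, extra) {
    index <- .loadIndexFromConfig(config)
    ss <- .readSampleSheet(config$paths$samples)
    group <- if (!is.null(extra$group)) extra$group else ss$group[1]
    tr <- .tracksFromSheet(ss[ss$group == group, , drop = FALSE][1, ,
                                                                 drop = FALSE])
    prof <- metageneProfile(
        tr[[1]], index,
        binCounts = c(utr5 = config$metagene$bins_utr5,
                      cds = config$metagene$bins_cds,
                      utr3 = config$metagene$bins_utr3))
    path <- file.path(outDir, paste0("metagene_", group, ".tsv"))
    exportMetageneTsv(prof, path)
    list(metagene_tsv = path)
}

.cmdAnchor <- function(config, outDir, extra) {
    index <- .loadIndexFromConfig(config)
    ss <- .readSampleSheet(config$paths$samples)
    if (is.null(extra$anchors)) stop("anchor requires an 'anchors' BED path")
    anchors <- rtracklayer::import(extra$anchors, format = "BED")
    group <- if (!is.null(extra$group)) extra$group else ss$group[1]
    tr <- .tracksFromSheet(ss[ss$group == group, , drop = FALSE][1, ,
                                                                 drop = FALSE])
    prof <- anchorProfile(tr[[1]], anchors, index,
                          W = config$anchor$window,
                          Q = config$anchor$quant_window,
                          nullMatch = config$anchor$null_match,
                          seed = config$seed)
    tsv <- file.path(outDir, "anchor_profile.tsv")
    js <- file.path(outDir, "anchor_stats.json")
    exportAnchorProfile(prof, tsv, js)
    list(profile_tsv = tsv, stats_json = js)
}

.cmdOverlap <- function(config, outDir, extra) {
    if (is.null(extra$peaksA) || is.null(extra$peaksB))
        stop("overlap requires 'peaksA' and 'peaksB' BED paths")
    a <- rtracklayer::import(extra$peaksA, format = "BED")
    b <- rtracklayer::import(extra$peaksB, format = "BED")
    res <- overlapPeaks(a, b, extendNt = config$overlap$extend_nt)
    path <- file.path(outDir, "overlap.json")
    jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
    list(overlap_json = path)
}

.cmdCounts <- function(config, outDir, extra) {
    ss <- .readSampleSheet(config$paths$samples)
    if (is.null(extra$sites)) stop("counts requires a 'sites' BED path")
    sites <- rtracklayer::import(extra$sites, format = "BED")
    tracks <- .tracksFromSheet(ss)
    scm <- countSites(sites, tracks, flank = config$counts$flank)
    path <- file.path(outDir, "counts.tsv")
    utils::write.table(
        cbind(site = rownames(SummarizedExperiment::assay(scm)),
              as.data.frame(SummarizedExperiment::assay(scm))),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    sf <- file.path(outDir, "size_factors.tsv")
    utils::write.table(
        data.frame(sample_id = colnames(scm),
                   size_factor = sizeFactors(scm)),
        sf, sep = "\t", quote = FALSE, row.names = FALSE)
    list(counts_tsv = path, size_factors_tsv = sf)
}

.cmdGroups <- function(config, outDir, extra) {
    if (is.null(extra$log2fc) || is.null(extra$targets))
        stop("groups requires 'log2fc' and 'targets' TSV paths")
    lfc <- utils::read.table(extra$log2fc, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    targets <- readLines(extra$targets)
    v <- structure(lfc$log2fc, names = lfc$gene_id)
    cmp <- targetVsNontargetFoldchange(v, targets)
    path <- file.path(outDir, "group_stats.json")
    jsonlite::write_json(
        list(method = cmp@method, statistic = cmp@statistic,
             p_value = cmp@pValue, group_means = as.list(cmp@groupMeans)),
        path, auto_unbox = TRUE, digits = NA)
    list(stats_json = path)
}
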