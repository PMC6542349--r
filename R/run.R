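#' High-level runs: detect, evaluate, simulate
#'
#' These functions tie the package together for command-line style use (a
#' thin Rscript wrapper around them ships in
#' `system.file("scripts", "markerblocks.R", package = "markerBlocks")`).
#' Every run writes its outputs plus a JSON manifest recording the package
#' version, all parameters, the seed and the MD5 checksums of the input
#' files, which is sufficient to reproduce the run bit for bit.
#'
#' @name runs
NULL

.writeManifest <- function(out, command, params, inputs = character(0)) {
    manifest <- list(
        package = "markerBlocks",
        version = as.character(utils::packageVersion("markerBlocks")),
        command = command,
        parameters = params,
        input_md5 = as.list(tools::md5sum(inputs)))
    path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

.loadExperiment <- function(expression, annotation) {
    x <- readExpressionTable(expression)
    ann <- readSampleAnnotation(annotation)
    missing <- setdiff(colnames(x), names(ann))
    if (length(missing))
        stop("sample(s) missing from annotation: ",
             paste(missing, collapse = ", "))
    suppressWarnings(MarkerExperiment(x, ann[colnames(x)]))
}

.runDetector <- function(me, detector, cutoff = 1, spmCutoff = 0.4,
                         zCutoff = 1, seed = 1L) {
    switch(detector,
        rb = detectMarkers(me, cutoff = cutoff),
        spm = spmMarkers(me, cutoff = spmCutoff),
        zscore = zscoreMarkers(me, cutoff = zCutoff),
        random = {
            ref <- detectMarkers(me, cutoff = cutoff)
            sizes <- vapply(markerList(ref), length, integer(1L))
            if (!length(sizes))
                sizes <- stats::setNames(integer(0), character(0))
            randomMarkers(rownames(me), sizes, seed = seed)
        },
        stop("unknown detector '", detector,
             "' (use rb, spm, zscore or random)"))
}

#' @rdname runs
#' @param expression path to the expression table
#'   (see [readExpressionTable()]).
#' @param annotation path to the sample annotation table.
#' @param detector one of `"rb"` (replicate-block), `"spm"`, `"zscore"`,
#'   `"random"` (the random detector matches the per-type set sizes of the
#'   replicate-block detector).
#' @param cutoff expression cutoff of the replicate-block detector
#'   (default 1).
#' @param spmCutoff SPM selection cutoff (default 0.4).
#' @param zCutoff z-score selection cutoff (default 1).
#' @param seed integer master seed.
#' @param out output directory (created if needed).
#' @return `runDetect`: the [MarkerResult-class], invisibly; writes
#'   `markers.tsv` and `manifest.json` under `out`.
#' @export
runDetect <- function(expression, annotation, detector = "rb", cutoff = 1,
                      spmCutoff = 0.4, zCutoff = 1, seed = 1L, out) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    me <- .loadExperiment(expression, annotation)
    res <- .runDetector(me, detector, cutoff, spmCutoff, zCutoff, seed)
    writeMarkerTable(res, file.path(out, "markers.tsv"))
    .writeManifest(out, "detect",
                   list(detector = detector, cutoff = cutoff,
                        spmCutoff = spmCutoff, zCutoff = zCutoff,
                        seed = seed),
                   c(expression = expression, annotation = annotation))
    invisible(res)
}

#' @rdname runs
#' @param gold optional path to a gold-standard table
#'   (see [readGoldStandard()]).
#' @param detectors character vector of detectors to evaluate.
#' @param runs number of k-means restarts (default 100).
#' @param nRandom random sets for the overlap z-test (default 1000).
#' @return `runEvaluate`: list with `clustering` and (when `gold` is given)
#'   `ranking` data.frames, invisibly; writes `report.tsv`, optionally
#'   `ranking.tsv`, and `manifest.json` under `out`.
#' @export
runEvaluate <- function(expression, annotation, gold = NULL,
                        detectors = c("rb", "spm", "zscore", "random"),
                        cutoff = 1, spmCutoff = 0.4, zCutoff = 1,
                        runs = 100L, nRandom = 1000L, seed = 1L, out) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    me <- .loadExperiment(expression, annotation)
    labels <- sampleTypes(me)
    k <- length(unique(labels))
    gold_sets <- NULL
    if (!is.null(gold)) {
        gold_sets <- readGoldStandard(gold)
        unknown <- setdiff(names(gold_sets), unique(labels))
        if (length(unknown))
            stop("gold standard references unknown sample type(s): ",
                 paste(unknown, collapse = ", "))
    }
    seeds <- .deriveSeeds(seed, length(detectors) + 1L)
    full_q <- kmeansQuality(pcaEmbed(me), labels, k, runs = runs,
                            seed = seeds[length(detectors) + 1L])
    clustering <- cbind(data.frame(detector = "none (all genes)",
                                   n_markers = nrow(me)), full_q)
    ranking <- NULL
    for (i in seq_along(detectors)) {
        det <- detectors[i]
        res <- .runDetector(me, det, cutoff, spmCutoff, zCutoff, seeds[i])
        genes <- unique(markerCalls(res)$gene_id)
        if (length(genes) >= 2L) {
            q <- kmeansQuality(pcaEmbed(me[genes, ]), labels, k,
                               runs = runs, seed = seeds[i])
        } else {
            warning("detector '", det, "' selected fewer than 2 genes; ",
                    "clustering not evaluated")
            q <- full_q[0, ]
            q[1L, ] <- NA
            q$n_runs <- 0L
        }
        clustering <- rbind(clustering,
                            cbind(data.frame(detector = det,
                                             n_markers = length(genes)), q))
        if (!is.null(gold_sets)) {
            b <- goldStandardBenchmark(res, gold_sets,
                                       universe = rownames(me),
                                       nRandom = nRandom, seed = seeds[i])
            if (nrow(b))
                ranking <- rbind(ranking,
                                 cbind(data.frame(detector = det), b))
        }
    }
    utils::write.table(clustering, file.path(out, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(ranking))
        utils::write.table(ranking, file.path(out, "ranking.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    .writeManifest(out, "evaluate",
                   list(detectors = detectors, cutoff = cutoff,
                        spmCutoff = spmCutoff, zCutoff = zCutoff, k = k,
                        runs = runs, nRandom = nRandom, seed = seed),
                   c(expression = expression, annotation = annotation,
                     if (!is.null(gold)) c(gold = gold)))
    invisible(list(clustering = clustering, ranking = ranking))
}

#' @rdname runs
#' @param ... generator parameters passed to [simulateExpression()].
#' @return `runSimulate`: the [simulateExpression()] result, invisibly;
#'   writes `expression.tsv`, `annotation.tsv`, `gold.tsv`, `truth.json`
#'   and `manifest.json` under `out`.
#' @export
runSimulate <- function(..., seed, out) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateExpression(..., seed = seed)
    writeExpressionTable(sim$experiment, file.path(out, "expression.tsv"))
    writeSampleAnnotation(sampleTypes(sim$experiment),
                          file.path(out, "annotation.tsv"))
    gold <- suppressWarnings(makeGoldStandard(sim$truth))
    if (length(gold)) writeGoldStandard(gold, file.path(out, "gold.tsv"))
    jsonlite::write_json(
        list(params = simulationParams(sim$truth),
             markers = plantedMarkers(sim$truth)),
        file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    .writeManifest(out, "simulate", simulationParams(sim$truth))
    invisible(sim)
}
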