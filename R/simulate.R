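#' Simulate an expression matrix with planted type-specific markers
#'
#' Generates a log2-scale expression matrix emulating the structure of
#' normalized RNA-seq reference sets with replicated sample types: a
#' minority of genes strongly expressed in exactly one type (the planted
#' markers), a background of non-specific (housekeeping-like, uniform
#' across types) and silent genes. Marker own-type levels are drawn
#' log-normally (one level per gene: normal on the log2 scale around
#' `markerHigh`), other-type levels sit at `markerLow`; housekeeping levels
#' are drawn per gene around `backgroundMean`. Additive Gaussian technical
#' noise (sd `noiseSd`, log2 scale) is applied per value, optional Bernoulli
#' dropout zeroes values independently of expression (scRNA-seq-like
#' capture failure), and values are clipped at 0. Fully determined by
#' `seed`.
#'
#' @param nTypes number of sample types (default 5).
#' @param replicates replicates per type, >= 2 (default 3).
#' @param markersPerType planted markers per type (default 10).
#' @param backgroundGenes total background genes (default 500), split
#'   between housekeeping-like and silent genes by `housekeepingFraction`.
#' @param housekeepingFraction fraction of background genes that are
#'   housekeeping-like (default 0.5).
#' @param markerHigh mean own-type log2 level of marker genes (default 8).
#' @param markerLow other-type log2 level of marker genes (default 0).
#' @param markerLevelSd gene-to-gene sd of marker own-type levels
#'   (default 1).
#' @param backgroundMean mean log2 level of housekeeping-like genes
#'   (default 4).
#' @param backgroundLevelSd gene-to-gene sd of housekeeping levels
#'   (default 1).
#' @param noiseSd per-value technical noise sd on the log2 scale
#'   (default 0.5).
#' @param dropout Bernoulli dropout probability per value (default 0).
#' @param seed integer seed (required).
#' @return list with `experiment` (a [MarkerExperiment-class]) and `truth`
#'   (a [SimulationTruth-class]).
#' @examples
#' sim <- simulateExpression(noiseSd = 0, seed = 7)
#' sim$experiment
#' @export
simulateExpression <- function(nTypes = 5L, replicates = 3L,
                               markersPerType = 10L, backgroundGenes = 500L,
                               housekeepingFraction = 0.5,
                               markerHigh = 8, markerLow = 0,
                               markerLevelSd = 1,
                               backgroundMean = 4, backgroundLevelSd = 1,
                               noiseSd = 0.5, dropout = 0, seed) {
    if (missing(seed)) stop("'seed' is required for reproducibility")
    if (replicates < 2L) stop("need >= 2 replicates per type")
    if (nTypes < 2L) stop("need >= 2 sample types")
    if (markersPerType < 0L) stop("'markersPerType' must be >= 0")
    if (backgroundGenes < 0L) stop("'backgroundGenes' must be >= 0")
    if (housekeepingFraction < 0 || housekeepingFraction > 1)
        stop("'housekeepingFraction' must be in [0, 1]")
    if (noiseSd < 0) stop("'noiseSd' must be >= 0")
    if (dropout < 0 || dropout > 1) stop("'dropout' must be in [0, 1]")
    if (markerHigh <= markerLow)
        stop("'markerHigh' must exceed 'markerLow'")

    types <- sprintf("T%d", seq_len(nTypes))
    s <- nTypes * replicates
    sampleType <- rep(types, each = replicates)
    sample_ids <- sprintf("%s_r%d", sampleType, rep(seq_len(replicates), nTypes))
    n_hk <- round(backgroundGenes * housekeepingFraction)
    n_silent <- backgroundGenes - n_hk
    marker_ids <- if (markersPerType > 0)
        sprintf("mk_%s_%02d", rep(types, each = markersPerType),
                rep(seq_len(markersPerType), nTypes)) else character(0)
    gene_ids <- c(marker_ids,
                  if (n_hk) sprintf("hk_%04d", seq_len(n_hk)) else character(0),
                  if (n_silent) sprintf("si_%04d", seq_len(n_silent))
                  else character(0))
    n <- length(gene_ids)
    if (n == 0L) stop("no genes to simulate")

    x <- .withSeed(seed, {
        base <- matrix(0, n, s)
        row <- 0L
        for (ty in types) {
            if (markersPerType > 0) {
                lvl <- stats::rnorm(markersPerType, markerHigh, markerLevelSd)
                for (j in seq_len(markersPerType)) {
                    row <- row + 1L
                    base[row, ] <- ifelse(sampleType == ty, lvl[j], markerLow)
                }
            }
        }
        if (n_hk) {
            lvl <- stats::rnorm(n_hk, backgroundMean, backgroundLevelSd)
            base[row + seq_len(n_hk), ] <- matrix(rep(lvl, s), n_hk, s)
            row <- row + n_hk
        }
        # silent genes stay at 0
        out <- base
        if (noiseSd > 0)
            out <- out + matrix(stats::rnorm(n * s, 0, noiseSd), n, s)
        if (dropout > 0)
            out[matrix(stats::runif(n * s) < dropout, n, s)] <- 0
        pmax(out, 0)
    })
    dimnames(x) <- list(gene_ids, sample_ids)
    me <- suppressWarnings(
        MarkerExperiment(x, stats::setNames(sampleType, sample_ids)))
    markers <- if (markersPerType > 0)
        stats::setNames(split(marker_ids,
                              rep(types, each = markersPerType))[types], types)
    else stats::setNames(vector("list", 0L), character(0))
    truth <- methods::new("SimulationTruth",
        markers = markers,
        params = list(nTypes = nTypes, replicates = replicates,
                      markersPerType = markersPerType,
                      backgroundGenes = backgroundGenes,
                      housekeepingFraction = housekeepingFraction,
                      markerHigh = markerHigh, markerLow = markerLow,
                      markerLevelSd = markerLevelSd,
                      backgroundMean = backgroundMean,
                      backgroundLevelSd = backgroundLevelSd,
                      noiseSd = noiseSd, dropout = dropout, seed = seed))
    list(experiment = me, truth = truth)
}

#' Planted marker sets
#'
#' @param x a [SimulationTruth-class].
#' @return named list, sample type -> planted marker gene ids.
#' @rdname plantedMarkers
#' @export
setMethod("plantedMarkers", "SimulationTruth", function(x) x@markers)

#' @rdname plantedMarkers
#' @param x a [SimulationTruth-class].
#' @export
simulationParams <- function(x) x@params

setMethod("show", "SimulationTruth", function(object) {
    p <- object@params
    cat("SimulationTruth: ", p$nTypes, " types x ", p$replicates,
        " replicates, ", p$markersPerType, " planted markers/type, ",
        p$backgroundGenes, " background genes\n", sep = "")
    cat("noiseSd = ", p$noiseSd, ", dropout = ", p$dropout,
        ", seed = ", p$seed, "\n", sep = "")
})

#' Convert planted markers to a gold standard
#'
#' @param truth a [SimulationTruth-class].
#' @return named list, type -> gene ids, in the format consumed by
#'   [goldStandardBenchmark()]; types with no planted markers are omitted
#'   with a warning.
#' @export
makeGoldStandard <- function(truth) {
    mk <- plantedMarkers(truth)
    empty <- names(mk)[lengths(mk) == 0L]
    if (length(empty))
        warning("type(s) without planted markers omitted from gold standard: ",
                paste(empty, collapse = ", "))
    mk[lengths(mk) > 0L]
}

#' Read / write a gold-standard marker list
#'
#' Two tab-separated columns with header `sample_type` and `gene_id`, one
#' row per (type, marker gene) pair; a gene may appear under several types.
#'
#' @param path file path.
#' @return `readGoldStandard`: named list, type -> character vector of gene
#'   ids.
#' @export
readGoldStandard <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", quote = "")
    if (!all(c("sample_type", "gene_id") %in% colnames(df)))
        stop("gold-standard table must have columns 'sample_type' and 'gene_id'")
    split(df$gene_id, factor(df$sample_type, levels = unique(df$sample_type)))
}

#' @rdname readGoldStandard
#' @param gold named list, type -> gene ids.
#' @export
writeGoldStandard <- function(gold, path) {
    df <- data.frame(sample_type = rep(names(gold), lengths(gold)),
                     gene_id = unlist(gold, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
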