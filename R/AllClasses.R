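#' MarkerExperiment: a grouped expression matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' between-sample-comparable normalized expression matrix (genes in rows,
#' samples in columns, assay `"exprs"`) together with a `sample_type` column
#' in `colData` assigning each sample to one of `t` replicated sample types
#' (tissues, cell types, conditions).
#'
#' Validity requires: at least one gene and two samples; unique gene and
#' sample identifiers; all expression values finite and non-negative; every
#' sample labelled with exactly one type; at least two distinct types and
#' `t < s`. Types are expected to carry at least two replicates each; types
#' with a single replicate are tolerated (the constructor warns) because the
#' detection procedure remains well defined for them.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [MarkerExperiment()], [sampleTypes()], [replicateCounts()]
#' @export
setClass("MarkerExperiment", contains = "SummarizedExperiment")

.validMarkerExperiment <- function(object) {
    msg <- NULL
    x <- SummarizedExperiment::assay(object, "exprs")
    if (nrow(x) < 1L) msg <- c(msg, "need at least one gene (row)")
    if (ncol(x) < 2L) msg <- c(msg, "need at least two samples (columns)")
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!all(is.finite(x)))
        msg <- c(msg, "expression values must all be finite")
    else if (any(x < 0))
        msg <- c(msg, "expression values must all be non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!"sample_type" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'sample_type' column")
    } else {
        st <- as.character(cd$sample_type)
        if (anyNA(st) || any(!nzchar(st)))
            msg <- c(msg, "every sample must have a non-empty sample_type")
        else {
            t <- length(unique(st))
            if (t < 2L) msg <- c(msg, "need at least two sample types")
            if (t >= ncol(x)) msg <- c(msg, "number of types must be < number of samples")
        }
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("MarkerExperiment", .validMarkerExperiment)

#' MarkerResult: ranked marker calls from one detector
#'
#' Holds the marker calls emitted by a detector, the detector's name, the
#' polarity of its score (`"low_is_specific"` for the replicate-block
#' detector, `"high_is_specific"` for SPM/z-score) and the parameters of the
#' run. `calls` is a data.frame with columns `gene_id`, `sample_type`,
#' `score`, and (for the replicate-block detector) `cut1` and `cut2`; rows
#' are grouped by type and sorted from most to least specific within each
#' type. Genes the replicate-block detector rejected only because of a value
#' tie across the first cut are listed in `parameters$boundary_ties`.
#'
#' @slot calls data.frame of marker calls.
#' @slot detector character(1), one of "rb", "spm", "zscore", "random".
#' @slot polarity character(1), score polarity.
#' @slot parameters named list of run parameters.
#' @seealso [markerCalls()], [markerList()], [writeMarkerTable()]
#' @export
setClass("MarkerResult",
    representation(calls = "data.frame", detector = "character",
                   polarity = "character", parameters = "list"))

.validMarkerResult <- function(object) {
    msg <- NULL
    need <- c("gene_id", "sample_type", "score")
    if (!all(need %in% colnames(object@calls)))
        msg <- c(msg, sprintf("calls must have columns %s",
                              paste(need, collapse = ", ")))
    if (length(object@polarity) != 1L ||
        !object@polarity %in% c("low_is_specific", "high_is_specific"))
        msg <- c(msg, "polarity must be 'low_is_specific' or 'high_is_specific'")
    if (length(object@detector) != 1L)
        msg <- c(msg, "detector must be a single string")
    if (nrow(object@calls) && !all(is.finite(object@calls$score)))
        msg <- c(msg, "scores must be finite")
    if (is.null(msg)) TRUE else msg
}

setValidity("MarkerResult", .validMarkerResult)

#' SimulationTruth: planted markers and generator parameters
#'
#' Records, for a simulated expression matrix, the planted marker gene
#' identifiers per sample type (disjoint across types) and every generator
#' parameter including the seed, so a simulation can be reproduced exactly.
#'
#' @slot markers named list, sample type -> character vector of gene ids.
#' @slot params named list of generator parameters (includes `seed`).
#' @seealso [simulateExpression()], [makeGoldStandard()]
#' @export
setClass("SimulationTruth",
    representation(markers = "list", params = "list"))

.validSimulationTruth <- function(object) {
    msg <- NULL
    mk <- object@markers
    if (length(mk) && is.null(names(mk)))
        msg <- c(msg, "markers must be a named list (names = sample types)")
    all_genes <- unlist(mk, use.names = FALSE)
    if (anyDuplicated(all_genes))
        msg <- c(msg, "planted marker sets must be disjoint across types")
    if (!"seed" %in% names(object@params))
        msg <- c(msg, "params must record the seed")
    if (is.null(msg)) TRUE else msg
}

setValidity("SimulationTruth", .validSimulationTruth)
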