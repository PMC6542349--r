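#' Marker calls as a data.frame
#'
#' @param x a [MarkerResult-class].
#' @return data.frame of calls (grouped by sample type, most specific first
#'   within each type).
#' @rdname markerCalls
#' @export
setMethod("markerCalls", "MarkerResult", function(x) x@calls)

#' Marker gene ids per sample type
#'
#' @param x a [MarkerResult-class].
#' @return named list, sample type -> character vector of gene ids in rank
#'   order (most specific first).
#' @rdname markerList
#' @export
setMethod("markerList", "MarkerResult", function(x) {
    calls <- x@calls
    if (!nrow(calls)) return(stats::setNames(list(), character(0)))
    split(calls$gene_id, factor(calls$sample_type,
                                levels = unique(calls$sample_type)))
})

#' @rdname markerResult-accessors
#' @param x a [MarkerResult-class].
#' @export
detectorName <- function(x) x@detector

#' Accessors for MarkerResult
#'
#' `detectorName` gives the detector label ("rb", "spm", "zscore",
#' "random"); `scorePolarity` says whether small or large scores mean high
#' specificity; `detectorParameters` returns the run parameters.
#'
#' @rdname markerResult-accessors
#' @export
scorePolarity <- function(x) x@polarity

#' @rdname markerResult-accessors
#' @export
detectorParameters <- function(x) x@parameters

setMethod("show", "MarkerResult", function(object) {
    calls <- object@calls
    cat("MarkerResult [", object@detector, "], polarity ",
        object@polarity, "\n", sep = "")
    tab <- table(calls$sample_type)
    cat(nrow(calls), " marker call(s) across ", length(tab),
        " sample type(s)\n", sep = "")
    if (length(tab))
        cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
                  collapse = "\n"), "\n", sep = "")
    nt <- object@parameters$boundary_ties
    if (length(nt))
        cat(length(nt), " gene(s) rejected on a boundary tie\n", sep = "")
})

#' Write a marker table
#'
#' Tab-separated columns `detector`, `gene_id`, `sample_type`, `score`
#' (6 decimal places) and, when present, `cut1`, `cut2`; rows grouped by
#' type, most specific first within type.
#'
#' @param x a [MarkerResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMarkerTable <- function(x, path) {
    calls <- markerCalls(x)
    out <- data.frame(detector = rep(detectorName(x), nrow(calls)),
                      calls, stringsAsFactors = FALSE)
    out$score <- sprintf("%.6f", calls$score)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a marker table written by [writeMarkerTable()]
#'
#' @param path path to the table.
#' @return data.frame of calls with numeric `score`.
#' @export
readMarkerTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    df$score <- as.numeric(df$score)
    for (col in c("cut1", "cut2"))
        if (col %in% colnames(df)) df[[col]] <- as.integer(df[[col]])
    df
}
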