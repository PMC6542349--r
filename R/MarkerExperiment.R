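#' Construct a MarkerExperiment
#'
#' Bundles a normalized expression matrix (genes x samples) with a sample
#' type annotation into a validated [MarkerExperiment-class] object. The
#' matrix must already be normalized so that values are comparable between
#' samples (log2 of RPKM/FPKM/TMM/RLE/size-factor-normalized counts, or any
#' comparable unit); no normalization is performed here.
#'
#' @param exprs numeric matrix of non-negative finite expression values with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param sampleType character vector of type labels, either named by sample
#'   id or in column order of `exprs`.
#' @return A [MarkerExperiment-class].
#' @examples
#' x <- matrix(c(5, 0, 1, 2, 4, 3), nrow = 2, dimnames = list(
#'     c("g1", "g2"), c("s1", "s2", "s3")))
#' me <- MarkerExperiment(x, c(s1 = "A", s2 = "A", s3 = "B"))
#' sampleTypes(me)
#' @export
MarkerExperiment <- function(exprs, sampleType) {
    if (!is.matrix(exprs) || !is.numeric(exprs))
        stop("'exprs' must be a numeric matrix")
    if (!is.null(names(sampleType))) {
        missing <- setdiff(colnames(exprs), names(sampleType))
        if (length(missing))
            stop("no sample_type for sample(s): ",
                 paste(missing, collapse = ", "))
        sampleType <- sampleType[colnames(exprs)]
    } else if (length(sampleType) != ncol(exprs)) {
        stop("'sampleType' length (", length(sampleType),
             ") does not match number of samples (", ncol(exprs), ")")
    }
    st <- as.character(sampleType)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = S4Vectors::DataFrame(sample_type = st,
                                       row.names = colnames(exprs)))
    obj <- methods::new("MarkerExperiment", se)
    singles <- names(which(table(st) < 2L))
    if (length(singles))
        warning("sample type(s) with a single replicate: ",
                paste(singles, collapse = ", "),
                " (the detector expects >= 2 replicates per type)")
    obj
}

#' Sample type labels
#'
#' @param x a [MarkerExperiment-class].
#' @return `sampleTypes`: character vector of per-sample type labels, named
#'   by sample id.
#' @rdname sampleTypes
#' @export
setMethod("sampleTypes", "MarkerExperiment", function(x) {
    st <- as.character(SummarizedExperiment::colData(x)$sample_type)
    names(st) <- colnames(x)
    st
})

#' Replicate counts per sample type
#'
#' @param x a [MarkerExperiment-class] or a character vector of type labels.
#' @return named integer vector, type -> number of replicates.
#' @rdname replicateCounts
#' @export
setMethod("replicateCounts", "MarkerExperiment", function(x) {
    replicateCounts(sampleTypes(x))
})

#' @rdname replicateCounts
#' @export
setMethod("replicateCounts", "character", function(x) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "MarkerExperiment", function(object) {
    methods::callNextMethod()
    tab <- replicateCounts(object)
    cat("sample types(", length(tab), "): ",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
        "\n", sep = "")
})
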