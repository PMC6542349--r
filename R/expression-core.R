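#' Read a delimited expression table
#'
#' Reads a plain-text expression table whose first column (header `gene_id`)
#' holds gene identifiers and whose remaining columns, named by sample id,
#' hold numeric non-negative expression values.
#'
#' @param path path to the table.
#' @param delim field delimiter, tab by default. Decimal point only; no
#'   thousands separators.
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames, preserving the file's row and column order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpressionTable(matrix(1:6, 2, dimnames = list(c("g1", "g2"),
#'     c("s1", "s2", "s3"))), f)
#' readExpressionTable(f)
#' @export
readExpressionTable <- function(path, delim = "\t") {
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", quote = "")
    if (ncol(df) < 2L)
        stop("expression table needs a gene_id column plus >= 1 sample column")
    gene_ids <- df[[1L]]
    dup <- gene_ids[duplicated(gene_ids)]
    if (length(dup))
        stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
    sample_ids <- colnames(df)[-1L]
    dup <- sample_ids[duplicated(sample_ids)]
    if (length(dup))
        stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
    x <- matrix(NA_real_, nrow(df), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                         df[[j + 1L]][bad[1L]], bad[1L], gene_ids[bad[1L]],
                         sample_ids[j]))
        x[, j] <- v
    }
    if (anyNA(x)) stop("missing values are not allowed in the expression table")
    neg <- which(x < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative expression value at gene '%s', sample '%s'",
                     gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]))
    x
}

#' Write a delimited expression table
#'
#' Inverse of [readExpressionTable()]: first column header is `gene_id`.
#'
#' @param x numeric matrix with gene rownames and sample colnames, or a
#'   [MarkerExperiment-class].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path, delim = "\t") {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "exprs")
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sparse Matrix Market expression matrix
#'
#' Reads a coordinate-format MTX file plus two side files listing, one per
#' line, the gene ids (rows) and sample ids (columns), and returns the dense
#' matrix equivalent of [readExpressionTable()].
#'
#' @param mtx path to the MTX coordinate file.
#' @param genes path to the one-id-per-line gene file.
#' @param samples path to the one-id-per-line sample file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMTX <- function(mtx, genes, samples) {
    m <- as.matrix(Matrix::readMM(mtx))
    gene_ids <- readLines(genes)
    sample_ids <- readLines(samples)
    if (length(gene_ids) != nrow(m))
        stop("gene side file has ", length(gene_ids), " ids but matrix has ",
             nrow(m), " rows")
    if (length(sample_ids) != ncol(m))
        stop("sample side file has ", length(sample_ids), " ids but matrix has ",
             ncol(m), " columns")
    if (anyDuplicated(gene_ids))
        stop("duplicated gene id(s): ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    if (anyDuplicated(sample_ids))
        stop("duplicated sample id(s): ",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
    if (any(m < 0)) stop("negative expression values are not allowed")
    dimnames(m) <- list(gene_ids, sample_ids)
    m
}

#' Read a sample annotation table
#'
#' Two tab-separated columns with header `sample_id` and `sample_type`.
#'
#' @param path path to the annotation file.
#' @param delim field delimiter.
#' @return character vector of sample types named by sample id.
#' @export
readSampleAnnotation <- function(path, delim = "\t") {
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", quote = "")
    if (!all(c("sample_id", "sample_type") %in% colnames(df)))
        stop("annotation table must have columns 'sample_id' and 'sample_type'")
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample id(s) in annotation: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    stats::setNames(df$sample_type, df$sample_id)
}

#' Write a sample annotation table
#'
#' @param sampleType character vector of type labels named by sample id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleAnnotation <- function(sampleType, path) {
    utils::write.table(
        data.frame(sample_id = names(sampleType),
                   sample_type = as.character(sampleType)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.exprsApply <- function(x, f) {
    if (methods::is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "exprs") <-
            f(SummarizedExperiment::assay(x, "exprs"))
        x
    } else f(x)
}

#' Log2 transform with a pseudo-count of 1
#'
#' Replaces each value v by log2(v + 1). Shape, gene ids and sample ids are
#' unchanged; the transform is strictly monotone so within-gene value order
#' is preserved.
#'
#' @param x numeric matrix or [MarkerExperiment-class] with values >= 0.
#' @return object of the same class with transformed values.
#' @examples
#' log2Pseudocount(matrix(c(0, 1, 3), 1, dimnames = list("g", c("a", "b", "c"))))
#' @export
log2Pseudocount <- function(x) {
    .exprsApply(x, function(m) {
        if (any(m < 0)) stop("negative values: matrix must be non-negative")
        log2(m + 1)
    })
}

#' Keep genes expressed in a minimum number of samples
#'
#' A gene is kept when it has strictly positive values in at least
#' `minSamples` samples; gene order is preserved. May return a 0-gene object.
#'
#' @param x numeric matrix or [MarkerExperiment-class].
#' @param minSamples minimum number of samples with a positive value
#'   (default 2).
#' @return object of the same class restricted to the surviving genes.
#' @examples
#' x <- matrix(c(5, 5, 0, 1, 0, 0), 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' rownames(filterExpressed(x, 2))
#' @export
filterExpressed <- function(x, minSamples = 2L) {
    if (minSamples < 1L) stop("'minSamples' must be >= 1")
    m <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "exprs") else x
    keep <- rowSums(m > 0) >= minSamples
    x[keep, , drop = FALSE]
}

#' Read a gene id mapping table
#'
#' Three tab-separated columns with header
#' `source_id`, `gene_symbol`, `entrez_id`; `source_id` must be unique. This
#' is an offline lookup table (Ensembl, RefSeq or UCSC ids to symbols /
#' Entrez ids); no network query is made.
#'
#' @param path path to the mapping table.
#' @return data.frame with columns `source_id`, `gene_symbol`, `entrez_id`.
#' @export
readGeneIdMapping <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", quote = "")
    need <- c("source_id", "gene_symbol", "entrez_id")
    if (!all(need %in% colnames(df)))
        stop("mapping table must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(df$source_id))
        stop("duplicated source_id(s) in mapping table: ",
             paste(unique(df$source_id[duplicated(df$source_id)]),
                   collapse = ", "))
    df[need]
}

#' Map gene identifiers to symbols or Entrez ids
#'
#' Renames the genes of `x` using an offline mapping table. Unmapped genes
#' keep their source ids; when two source ids map to the same target the
#' rows are kept and disambiguated with suffixes `.1`, `.2`, ... so the row
#' count is conserved. A report of unmapped and disambiguated genes is
#' attached as attribute `"geneIdReport"` (for a [MarkerExperiment-class],
#' also in `metadata(x)$geneIdReport`).
#'
#' @param x numeric matrix or [MarkerExperiment-class].
#' @param map data.frame as returned by [readGeneIdMapping()].
#' @param target `"symbol"` or `"entrez"`.
#' @return object of the same class with renamed genes.
#' @export
mapGeneIds <- function(x, map, target = c("symbol", "entrez")) {
    target <- match.arg(target)
    if (!is.data.frame(map) || nrow(map) == 0L)
        stop("empty gene id mapping table")
    col <- if (target == "symbol") "gene_symbol" else "entrez_id"
    lut <- stats::setNames(map[[col]], map$source_id)
    old <- if (methods::is(x, "SummarizedExperiment")) rownames(x) else rownames(x)
    new <- unname(lut[old])
    unmapped <- old[is.na(new) | !nzchar(new)]
    new[is.na(new) | !nzchar(new)] <- old[is.na(new) | !nzchar(new)]
    dup_targets <- unique(new[duplicated(new)])
    if (length(dup_targets)) {
        for (d in dup_targets) {
            idx <- which(new == d)
            new[idx] <- paste0(d, ".", seq_along(idx))
        }
    }
    report <- list(unmapped = unmapped, disambiguated = dup_targets,
                   target = target)
    if (methods::is(x, "SummarizedExperiment")) {
        rownames(x) <- new
        S4Vectors::metadata(x)$geneIdReport <- report
    } else {
        rownames(x) <- new
    }
    attr(x, "geneIdReport") <- report
    x
}
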