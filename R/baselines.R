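#' Per-type mean expression profiles
#'
#' Collapses the samples of each type to their mean, giving each gene a
#' length-t profile. The baseline detectors (SPM, z-score) score these
#' per-type profiles so that all detectors rank genes on the same per-type
#' footing.
#'
#' @param x a [MarkerExperiment-class] or a numeric matrix with `sampleType`.
#' @param sampleType character vector of type labels (matrix input only).
#' @return numeric matrix, genes x types.
#' @export
typeMeans <- function(x, sampleType = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        sampleType <- sampleTypes(x)
        x <- SummarizedExperiment::assay(x, "exprs")
    }
    if (is.null(sampleType) || length(sampleType) != ncol(x))
        stop("'sampleType' must match the number of samples")
    st <- factor(as.character(sampleType),
                 levels = unique(as.character(sampleType)))
    t(rowsum(t(x), st) / as.vector(table(st)))
}

#' SPM cosine specificity scores
#'
#' For a gene's per-type profile x, the SPM for type i is the cosine between
#' the profile and the one-hot vector of type i:
#' `SPM_i = x_i / sqrt(sum(x^2))`. Scores lie in [0, 1] (1 = exclusive
#' expression in that type) and their squares sum to 1, which makes the
#' published selection cutoff of 0.4 meaningful.
#'
#' @param profile non-negative numeric vector (per-type means for one gene).
#' @return numeric vector of SPM scores, same length and names; an all-zero
#'   profile gives all zeros with a warning.
#' @examples
#' spmScores(c(3, 4))  # 0.6 0.8
#' @export
spmScores <- function(profile) {
    nrm <- sqrt(sum(profile^2))
    if (nrm == 0) {
        warning("all-zero profile: SPM scores set to 0")
        return(profile * 0)
    }
    profile / nrm
}

#' z-score specificity
#'
#' Standardizes a gene's per-type profile: `z_i = (x_i - mean(x)) / sd(x)`
#' with the sample (n-1 denominator) standard deviation. Large positive z
#' means the type expresses the gene well above the gene's average level.
#'
#' @param profile numeric vector of length >= 2.
#' @return numeric vector of z-scores (sums to 0); a constant profile gives
#'   all zeros with a warning.
#' @examples
#' zscoreScores(c(0, 0, 3))
#' @export
zscoreScores <- function(profile) {
    if (length(profile) < 2L)
        stop("z-scores need a profile of length >= 2")
    s <- stats::sd(profile)
    if (s == 0) {
        warning("constant profile: z-scores set to 0")
        return(profile * 0)
    }
    (profile - mean(profile)) / s
}

#' Threshold selection of markers from a score matrix
#'
#' @param scores numeric matrix, genes x types.
#' @param polarity `"high_is_specific"` keeps `score >= cutoff`,
#'   `"low_is_specific"` keeps `score <= cutoff` (both boundary-inclusive).
#' @param cutoff selection cutoff.
#' @return named list, type -> character vector of selected gene ids.
#' @export
thresholdSelect <- function(scores,
                            polarity = c("high_is_specific", "low_is_specific"),
                            cutoff) {
    polarity <- match.arg(polarity)
    keep <- if (polarity == "high_is_specific") scores >= cutoff
            else scores <= cutoff
    lapply(stats::setNames(colnames(scores), colnames(scores)),
           function(ty) rownames(scores)[keep[, ty]])
}

.baselineResult <- function(x, detector, cutoff) {
    tm <- typeMeans(x)
    scorer <- switch(detector, spm = spmScores, zscore = zscoreScores)
    sc <- t(apply(tm, 1L, function(v) suppressWarnings(scorer(v))))
    dimnames(sc) <- dimnames(tm)
    rows <- do.call(rbind, lapply(colnames(sc), function(ty) {
        sel <- which(sc[, ty] >= cutoff)
        if (!length(sel)) return(NULL)
        ord <- sel[order(-sc[sel, ty], sel)]
        data.frame(gene_id = rownames(sc)[ord], sample_type = ty,
                   score = unname(sc[ord, ty]), stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
        rows <- data.frame(gene_id = character(0), sample_type = character(0),
                           score = numeric(0), stringsAsFactors = FALSE)
    rownames(rows) <- NULL
    methods::new("MarkerResult", calls = rows, detector = detector,
                 polarity = "high_is_specific",
                 parameters = list(cutoff = cutoff))
}

#' SPM baseline detector
#'
#' Scores every gene's per-type mean profile with [spmScores()] and keeps,
#' for each type, the genes with `SPM >= cutoff` (published cutoff 0.4),
#' ranked most specific first.
#'
#' @param x a [MarkerExperiment-class].
#' @param cutoff SPM selection cutoff (default 0.4).
#' @return a [MarkerResult-class] with polarity `"high_is_specific"`.
#' @export
spmMarkers <- function(x, cutoff = 0.4) .baselineResult(x, "spm", cutoff)

#' z-score baseline detector
#'
#' Scores every gene's per-type mean profile with [zscoreScores()] and
#' keeps, for each type, the genes with `z >= cutoff` (published cutoff 1),
#' ranked most specific first.
#'
#' @param x a [MarkerExperiment-class].
#' @param cutoff z-score selection cutoff (default 1).
#' @return a [MarkerResult-class] with polarity `"high_is_specific"`.
#' @export
zscoreMarkers <- function(x, cutoff = 1) .baselineResult(x, "zscore", cutoff)

#' Full baseline score matrices
#'
#' Per-type scores for every gene (no selection), for ranked benchmarking.
#'
#' @param x a [MarkerExperiment-class].
#' @param method `"spm"` or `"zscore"`.
#' @return numeric matrix, genes x types.
#' @export
baselineScores <- function(x, method = c("spm", "zscore")) {
    method <- match.arg(method)
    tm <- typeMeans(x)
    scorer <- if (method == "spm") spmScores else zscoreScores
    sc <- t(apply(tm, 1L, function(v) suppressWarnings(scorer(v))))
    dimnames(sc) <- dimnames(tm)
    sc
}

#' Random baseline detector
#'
#' Draws, for each sample type, a uniform sample of gene ids without
#' replacement, independently across types; reproducible given the seed.
#' Used as the chance baseline: its per-type set sizes are matched to the
#' detector it is benchmarked against.
#'
#' @param universe character vector of candidate gene ids.
#' @param sizes named integer vector, type -> number of genes to draw.
#' @param seed integer seed.
#' @return a [MarkerResult-class] with detector `"random"`; scores are the
#'   draw ranks scaled to (0, 1] (arbitrary, polarity
#'   `"low_is_specific"`).
#' @export
randomMarkers <- function(universe, sizes, seed) {
    if (any(sizes > length(universe)))
        stop("requested size exceeds the gene universe (",
             length(universe), ")")
    if (is.null(names(sizes))) stop("'sizes' must be named by sample type")
    rows <- .withSeed(seed, do.call(rbind, lapply(names(sizes), function(ty) {
        g <- sample(universe, sizes[[ty]])
        if (!length(g)) return(NULL)
        data.frame(gene_id = g, sample_type = ty,
                   score = seq_along(g) / length(g), stringsAsFactors = FALSE)
    })))
    if (is.null(rows))
        rows <- data.frame(gene_id = character(0), sample_type = character(0),
                           score = numeric(0), stringsAsFactors = FALSE)
    rownames(rows) <- NULL
    methods::new("MarkerResult", calls = rows, detector = "random",
                 polarity = "low_is_specific",
                 parameters = list(seed = seed, sizes = as.list(sizes)))
}
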