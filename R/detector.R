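#' Sort one expression profile decreasingly
#'
#' Stable decreasing sort of a gene's expression values across samples; ties
#' are broken by the original sample index (ascending), so results are fully
#' deterministic.
#'
#' @param values numeric vector, one value per sample.
#' @param sampleType character vector of type labels, same length.
#' @return data.frame with columns `value`, `sample_type`, `sample_index`,
#'   rows in non-increasing value order.
#' @examples
#' sortProfile(c(4, 9, 1), c("A", "B", "A"))
#' @export
sortProfile <- function(values, sampleType) {
    if (length(values) != length(sampleType))
        stop("'values' and 'sampleType' lengths differ (",
             length(values), " vs ", length(sampleType), ")")
    ord <- order(-values, seq_along(values))
    data.frame(value = values[ord], sample_type = as.character(sampleType)[ord],
               sample_index = seq_along(values)[ord])
}

#' First cut-point: replicate-block candidacy
#'
#' Given a decreasingly sorted profile, takes as many leading values as the
#' top value's type has replicates (cut-point 1). The gene is a candidate
#' marker of that type when all values before the cut-point belong to the
#' type, all of them are at least `cutoff`, and the block is strictly
#' separated from the next value. The strict-separation requirement makes
#' candidacy independent of how exactly tied values were ordered: when the
#' value at the cut ties with the following value (which necessarily belongs
#' to another type), some orderings of the tie would place a foreign sample
#' inside the block, so such genes are not called; they are reported with
#' `boundary_tie = TRUE` in the candidacy record.
#'
#' @param profile data.frame from [sortProfile()].
#' @param repCounts named integer vector of replicate counts per type (see
#'   [replicateCounts()]).
#' @param cutoff minimum expression for block values (default 1, on the scale
#'   of the matrix as provided).
#' @return list with `is_candidate` (logical), `target_type`, `cut1`
#'   (= replicate count of the target type) and `boundary_tie` (TRUE when
#'   the gene was rejected only because of a value tie across the cut).
#' @export
cutPointOne <- function(profile, repCounts, cutoff = 1) {
    s <- nrow(profile)
    target <- profile$sample_type[1L]
    r <- repCounts[[target]]
    block_ok <- all(profile$sample_type[seq_len(r)] == target) &&
        all(profile$value[seq_len(r)] >= cutoff)
    tie <- r < s && profile$value[r] == profile$value[r + 1L]
    list(is_candidate = block_ok && !tie,
         target_type = target,
         cut1 = as.integer(r),
         boundary_tie = block_ok && tie)
}

#' Second cut-point: replicate closure of the comparison block
#'
#' Starting right after cut-point 1, takes as many values as the next type
#' has replicates; if other types appear inside that window it is grown
#' rightward until every type appearing in the window has all of its
#' replicates inside it (at most to the end of the profile).
#'
#' @param profile data.frame from [sortProfile()].
#' @param cut1 first cut-point (from [cutPointOne()]).
#' @param repCounts named integer vector of replicate counts per type.
#' @return integer cut-point 2 (1-based count of samples up to and including
#'   the end of the comparison block), with `cut1 < cut2 <= s`.
#' @export
cutPointTwo <- function(profile, cut1, repCounts) {
    s <- nrow(profile)
    if (cut1 >= s) stop("cut1 must leave at least one sample after the cut")
    types <- profile$sample_type
    e <- min(cut1 + repCounts[[types[cut1 + 1L]]], s)
    repeat {
        present <- unique(types[(cut1 + 1L):e])
        need <- max(vapply(present,
                           function(u) max(which(types == u)), integer(1L)))
        if (need <= e) break
        e <- min(need, s)
    }
    as.integer(e)
}

#' Ratio specificity score
#'
#' Mean expression of the comparison block (between the two cut-points)
#' divided by the mean of the top replicate block (before cut-point 1).
#' Because the profile is non-increasing the score lies in [0, 1]; 0 means
#' maximal specificity (the candidate's type is the only one expressing the
#' gene) and values near 1 mean no specificity.
#'
#' @param profile data.frame from [sortProfile()].
#' @param cut1,cut2 cut-points with `0 < cut1 < cut2 <= s`.
#' @return numeric score in [0, 1].
#' @examples
#' p <- sortProfile(c(10, 9, 8, 4, 3), c("A", "A", "A", "B", "B"))
#' specificityScore(p, 3, 5)  # 3.5 / 9
#' @export
specificityScore <- function(profile, cut1, cut2) {
    if (cut1 <= 0 || cut2 <= cut1 || cut2 > nrow(profile))
        stop("need 0 < cut1 < cut2 <= number of samples")
    denom <- mean(profile$value[seq_len(cut1)])
    if (denom <= 0) stop("top-block mean is zero; cannot form the score ratio")
    mean(profile$value[(cut1 + 1L):cut2]) / denom
}

.detectMarkersMatrix <- function(x, sampleType, cutoff = 1) {
    if (ncol(x) != length(sampleType))
        stop("annotation length does not match number of samples")
    st <- as.character(sampleType)
    repCounts <- replicateCounts(st)
    if (length(repCounts) < 2L)
        stop("need at least two sample types")
    n <- nrow(x)
    gene <- character(n); type <- character(n)
    score <- numeric(n); c1 <- integer(n); c2 <- integer(n)
    boundary_ties <- character(0)
    k <- 0L
    genes <- rownames(x)
    for (i in seq_len(n)) {
        v <- x[i, ]
        if (all(v <= 0)) next  # silent gene: fails candidacy trivially
        p <- sortProfile(v, st)
        cp1 <- cutPointOne(p, repCounts, cutoff)
        if (cp1$boundary_tie)
            boundary_ties <- c(boundary_ties, genes[i])
        if (!cp1$is_candidate) next
        cut2 <- cutPointTwo(p, cp1$cut1, repCounts)
        k <- k + 1L
        gene[k] <- genes[i]
        type[k] <- cp1$target_type
        score[k] <- specificityScore(p, cp1$cut1, cut2)
        c1[k] <- cp1$cut1
        c2[k] <- cut2
    }
    calls <- data.frame(gene_id = gene[seq_len(k)],
                        sample_type = type[seq_len(k)],
                        score = score[seq_len(k)],
                        cut1 = c1[seq_len(k)], cut2 = c2[seq_len(k)],
                        stringsAsFactors = FALSE)
    # group by type (in annotation order), ascending score within type,
    # stable in gene order for equal scores
    type_order <- match(calls$sample_type, names(repCounts))
    calls <- calls[order(type_order, calls$score, seq_len(nrow(calls))), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    methods::new("MarkerResult", calls = calls, detector = "rb",
                 polarity = "low_is_specific",
                 parameters = list(cutoff = cutoff,
                                   boundary_ties = boundary_ties))
}

#' Detect replicate-block marker genes
#'
#' The core detector. For every gene the expression profile is sorted
#' decreasingly ([sortProfile()]); the gene is a candidate marker of the top
#' value's type when that type's whole replicate block occupies the head of
#' the profile with all values `>= cutoff` ([cutPointOne()]); a second
#' cut-point closing the replicates of the following type(s) is found
#' ([cutPointTwo()]) and the ratio specificity score is attached
#' ([specificityScore()]). Genes failing candidacy are absent from the
#' result. Within each sample type, calls are sorted from most specific
#' (score 0) to least specific (score 1).
#'
#' @param x a [MarkerExperiment-class], or a numeric matrix (genes x
#'   samples) together with `sampleType`.
#' @param sampleType character vector of type labels (matrix method only).
#' @param cutoff expression cutoff applied to the top block (default 1).
#' @param ... passed through.
#' @return a [MarkerResult-class] with polarity `"low_is_specific"`.
#' @examples
#' x <- rbind(g1 = c(10, 9, 8, 4, 3, 2), g2 = c(0, 0, 0, 0, 0, 0))
#' colnames(x) <- paste0("s", 1:6)
#' res <- detectMarkers(x, sampleType = c("A", "A", "A", "B", "B", "B"))
#' markerCalls(res)
#' @rdname detectMarkers
#' @export
setMethod("detectMarkers", "MarkerExperiment", function(x, cutoff = 1, ...) {
    .detectMarkersMatrix(SummarizedExperiment::assay(x, "exprs"),
                         sampleTypes(x), cutoff = cutoff)
})

#' @rdname detectMarkers
#' @export
setMethod("detectMarkers", "matrix", function(x, sampleType, cutoff = 1, ...) {
    .detectMarkersMatrix(x, sampleType, cutoff = cutoff)
})
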