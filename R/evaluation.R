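#' PCA embedding of samples
#'
#' Principal component analysis with samples as observations and genes as
#' features (features centered, optionally unit-scaled), returning the first
#' two principal-component coordinates per sample. The sign of each
#' component is fixed by making its largest-magnitude gene loading positive,
#' so embeddings are reproducible across platforms.
#'
#' @param x numeric matrix (genes x samples) or a [MarkerExperiment-class];
#'   needs >= 2 genes and >= 3 samples.
#' @param scale logical; unit-scale features (default FALSE).
#' @return numeric matrix, samples x 2 (columns `PC1`, `PC2`), with
#'   attribute `"explained"` holding the variance explained by each
#'   component.
#' @export
pcaEmbed <- function(x, scale = FALSE) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "exprs")
    if (nrow(x) < 2L) stop("PCA embedding needs at least 2 genes")
    if (ncol(x) < 3L) stop("PCA embedding needs at least 3 samples")
    if (scale) {
        sds <- apply(x, 1L, stats::sd)
        x <- x[sds > 0, , drop = FALSE]  # constant features carry no signal
        if (nrow(x) < 2L) stop("fewer than 2 variable genes after scaling filter")
    }
    pr <- stats::prcomp(t(x), center = TRUE, scale. = scale)
    k <- min(2L, ncol(pr$x))
    coords <- pr$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, PC2 = 0)
    for (j in seq_len(k)) {
        load <- pr$rotation[, j]
        if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
    }
    colnames(coords) <- c("PC1", "PC2")
    ev <- pr$sdev^2
    attr(coords, "explained") <- ev[seq_len(min(2L, length(ev)))]
    coords
}

#' Normalized mutual information of two partitions
#'
#' Mutual information of the contingency table (natural log) normalized, by
#' default, by the arithmetic mean of the two partition entropies
#' (`sqrt`, `min` and `max` normalizations are also available). 1 for
#' identical partitions up to relabeling; 0 when one partition is a single
#' cluster and the other is uninformative about it.
#'
#' @param a,b vectors of cluster labels, equal length.
#' @param variant normalization: `"arithmetic"` (default), `"sqrt"`,
#'   `"min"`, `"max"`.
#' @return numeric in [0, 1].
#' @examples
#' nmi(c("A", "A", "B", "B"), c(1, 1, 2, 2))  # 1
#' nmi(c("A", "A", "B", "B"), c(1, 2, 1, 2))  # 0
#' @export
nmi <- function(a, b, variant = c("arithmetic", "sqrt", "min", "max")) {
    variant <- match.arg(variant)
    if (length(a) != length(b))
        stop("partitions have different lengths (", length(a), " vs ",
             length(b), ")")
    n <- length(a)
    tab <- table(a, b)
    pij <- tab / n
    pi_ <- rowSums(pij); p_j <- colSums(pij)
    nz <- pij > 0
    mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    ha <- ent(pi_); hb <- ent(p_j)
    denom <- switch(variant,
                    arithmetic = (ha + hb) / 2,
                    sqrt = sqrt(ha * hb),
                    min = min(ha, hb),
                    max = max(ha, hb))
    if (denom == 0) return(1)  # both partitions are single clusters
    max(0, min(1, mi / denom))
}

#' Purity of a clustering against true classes
#'
#' For each predicted cluster, counts the samples of its majority true
#' class; purity is the total over clusters divided by the number of
#' samples. Not symmetric in its arguments; one-sample clusters trivially
#' reach 1.
#'
#' @param pred predicted cluster labels.
#' @param truth true class labels, same length.
#' @return numeric in [0, 1].
#' @examples
#' purity(c(1, 1, 1, 2, 2), c("A", "A", "B", "B", "B"))  # 0.8
#' @export
purity <- function(pred, truth) {
    if (length(pred) != length(truth))
        stop("partitions have different lengths")
    tab <- table(pred, truth)
    sum(apply(tab, 1L, max)) / length(pred)
}

#' Adjusted Rand index
#'
#' Pair-counting Rand index adjusted for chance under the permutation model
#' (hypergeometric baseline): 1 for identical partitions up to relabeling,
#' about 0 for independent random partitions, can be negative.
#'
#' @param a,b vectors of cluster labels, equal length.
#' @return numeric <= 1.
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b))
        stop("partitions have different lengths")
    tab <- table(a, b)
    n <- length(a)
    ch2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(ch2(tab))
    sum_a <- sum(ch2(rowSums(tab)))
    sum_b <- sum(ch2(colSums(tab)))
    expected <- sum_a * sum_b / ch2(n)
    maximum <- (sum_a + sum_b) / 2
    if (maximum == expected) return(1)  # both partitions trivial
    (sum_ij - expected) / (maximum - expected)
}

# One k-means partition of `coords` with centers drawn uniformly from the
# distinct coordinate rows (stats::kmeans rejects duplicate centers, which
# replicated coordinates would otherwise produce). Falls back to grouping by
# distinct coordinate when there are fewer distinct points than k.
.kmeansPartition <- function(coords, k) {
    key <- apply(coords, 1L, paste, collapse = "\r")
    distinct <- !duplicated(key)
    if (sum(distinct) < k) return(match(key, key[distinct]))
    centers <- coords[which(distinct)[sample.int(sum(distinct), k)], ,
                      drop = FALSE]
    fit <- suppressWarnings(
        stats::kmeans(coords, centers = centers, iter.max = 300L,
                      algorithm = "Lloyd"))
    fit$cluster
}

#' Clustering quality of an embedding over repeated k-means runs
#'
#' Runs k-means (Lloyd, random initial centroids, up to 300 iterations)
#' `runs` times on the sample coordinates and scores every partition against
#' the true sample-type labels with NMI, purity and the adjusted Rand index;
#' k-means is restarted from random centroids each run, so means and
#' standard deviations over runs are reported. Each run gets its own seed
#' derived from `seed`, making the whole procedure reproducible.
#'
#' @param coords numeric matrix, samples x d (typically the 2-column
#'   [pcaEmbed()] output).
#' @param trueLabels true sample-type labels, one per sample.
#' @param k number of clusters; must equal the number of distinct true
#'   labels and be <= number of samples.
#' @param runs number of k-means restarts (default 100).
#' @param seed integer master seed.
#' @return one-row data.frame with columns `nmi_mean`, `nmi_sd`,
#'   `purity_mean`, `purity_sd`, `ari_mean`, `ari_sd`, `n_runs`.
#' @export
kmeansQuality <- function(coords, trueLabels, k, runs = 100L, seed) {
    if (k > nrow(coords)) stop("k exceeds the number of samples")
    if (length(trueLabels) != nrow(coords))
        stop("labels do not match the number of samples")
    if (k != length(unique(trueLabels)))
        stop("k must equal the number of distinct true labels")
    if (runs < 1L) stop("'runs' must be >= 1")
    seeds <- .deriveSeeds(seed, runs)
    met <- vapply(seq_len(runs), function(r) {
        part <- .withSeed(seeds[r], .kmeansPartition(coords, k))
        c(nmi(part, trueLabels), purity(part, trueLabels),
          adjustedRandIndex(part, trueLabels))
    }, numeric(3L))
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    data.frame(nmi_mean = mean(met[1L, ]), nmi_sd = sd0(met[1L, ]),
               purity_mean = mean(met[2L, ]), purity_sd = sd0(met[2L, ]),
               ari_mean = mean(met[3L, ]), ari_sd = sd0(met[3L, ]),
               n_runs = runs)
}

# Orient scores so that larger always means more specific.
.specificityOrder <- function(scores, polarity) {
    if (polarity == "low_is_specific") -scores else scores
}

#' Precision-recall curve and AUPRC for one ranked marker list
#'
#' Sweeps the score cutoffs of one type's ranked gene list from most to
#' least specific (tied scores enter together), computing precision (gold
#' fraction of the genes taken so far) and recall (fraction of the gold set
#' retrieved so far) at each cutoff. The area under the curve is the
#' standard non-interpolated step summation `sum((R_k - R_{k-1}) * P_k)`.
#' Gold genes missing from `scores` are never retrieved, so the curve then
#' ends below recall 1.
#'
#' @param scores named numeric vector: one specificity score per gene.
#' @param gold character vector of gold-standard marker gene ids for the
#'   type (non-empty).
#' @param polarity `"low_is_specific"` (ranked ascending) or
#'   `"high_is_specific"`.
#' @param type optional type label, used in error messages only.
#' @return list with `curve` (data.frame `recall`, `precision` per cutoff)
#'   and `auprc`.
#' @export
prCurve <- function(scores, gold,
                    polarity = c("high_is_specific", "low_is_specific"),
                    type = NULL) {
    polarity <- match.arg(polarity)
    if (!length(gold))
        stop("empty gold-standard set",
             if (!is.null(type)) paste0(" for type '", type, "'"))
    if (is.null(names(scores))) stop("'scores' must be named by gene id")
    spec <- .specificityOrder(scores, polarity)
    ord <- order(-spec, seq_along(spec))
    lab <- names(scores)[ord] %in% gold
    spec <- spec[ord]
    last_of_group <- c(spec[-length(spec)] != spec[-1L], TRUE)
    tp <- cumsum(lab)[last_of_group]
    taken <- seq_along(lab)[last_of_group]
    n_gold <- length(unique(gold))
    precision <- tp / taken
    recall <- tp / n_gold
    auprc <- sum(diff(c(0, recall)) * precision)
    list(curve = data.frame(recall = recall, precision = precision),
         auprc = auprc)
}

#' ROC curve and AUROC for one ranked marker list
#'
#' Standard ROC over the same ranking as [prCurve()]. The AUROC equals the
#' Mann-Whitney probability that a randomly chosen gold gene outranks a
#' randomly chosen non-gold gene, ties counting 1/2, and is computed that
#' way (midranks), so all-tied scores give exactly 0.5.
#'
#' @inheritParams prCurve
#' @return list with `curve` (data.frame `fpr`, `tpr` per cutoff) and
#'   `auroc`.
#' @export
rocCurve <- function(scores, gold,
                     polarity = c("high_is_specific", "low_is_specific"),
                     type = NULL) {
    polarity <- match.arg(polarity)
    if (!length(gold))
        stop("empty gold-standard set",
             if (!is.null(type)) paste0(" for type '", type, "'"))
    if (is.null(names(scores))) stop("'scores' must be named by gene id")
    spec <- .specificityOrder(scores, polarity)
    pos <- names(scores) %in% gold
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L) stop("no gold gene appears in the ranking")
    if (n_neg == 0L) stop("ranking contains only gold genes")
    r <- rank(spec, ties.method = "average")
    auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    ord <- order(-spec, seq_along(spec))
    lab <- pos[ord]
    sspec <- spec[ord]
    last_of_group <- c(sspec[-length(sspec)] != sspec[-1L], TRUE)
    tpr <- cumsum(lab)[last_of_group] / n_pos
    fpr <- cumsum(!lab)[last_of_group] / n_neg
    list(curve = data.frame(fpr = fpr, tpr = tpr), auroc = auroc)
}

#' Random-set overlap z-test for a predicted marker set
#'
#' Measures the size of the intersection of a predicted marker set with a
#' gold-standard set and compares it with the overlaps of `nRandom` sets of
#' the same size drawn uniformly from the gene universe, via a z statistic
#' and a one-sided upper-tail normal p-value.
#'
#' @param predicted character vector of predicted marker gene ids (subset of
#'   `universe`).
#' @param gold character vector of gold-standard gene ids (must intersect
#'   `universe`).
#' @param universe character vector: all candidate gene ids.
#' @param nRandom number of random sets (default 1000).
#' @param seed integer seed.
#' @return list with `observed`, `z`, `p`, `random_mean`, `random_sd`.
#' @export
overlapZTest <- function(predicted, gold, universe, nRandom = 1000L, seed) {
    predicted <- unique(predicted); gold <- unique(gold)
    if (length(setdiff(predicted, universe)))
        stop("'predicted' must be a subset of 'universe'")
    if (!length(intersect(gold, universe)))
        stop("gold set does not intersect the gene universe")
    observed <- length(intersect(predicted, gold))
    k <- length(predicted)
    gold_in <- intersect(gold, universe)
    rnd <- .withSeed(seed, vapply(seq_len(nRandom), function(i)
        length(intersect(sample(universe, k), gold_in)), numeric(1L)))
    m <- mean(rnd); s <- stats::sd(rnd)
    if (s == 0) {
        warning("degenerate random overlap distribution (sd = 0)")
        p <- if (observed > m) 0 else 1
        z <- if (observed > m) Inf else if (observed < m) -Inf else 0
    } else {
        z <- (observed - m) / s
        p <- stats::pnorm(z, lower.tail = FALSE)
    }
    list(observed = observed, z = z, p = p, random_mean = m, random_sd = s)
}

#' Per-type ranked specificity scores from a detector result
#'
#' @param x a [MarkerResult-class] (uses its calls) or a genes x types score
#'   matrix such as [baselineScores()] output.
#' @return named list, type -> named numeric score vector.
#' @export
rankedScores <- function(x) {
    if (methods::is(x, "MarkerResult")) {
        calls <- markerCalls(x)
        lapply(split(calls, factor(calls$sample_type,
                                   levels = unique(calls$sample_type))),
               function(df) stats::setNames(df$score, df$gene_id))
    } else if (is.matrix(x)) {
        lapply(stats::setNames(colnames(x), colnames(x)),
               function(ty) x[, ty])
    } else stop("need a MarkerResult or a score matrix")
}

#' Gold-standard benchmark of a ranked detector result
#'
#' Computes, for every sample type with a gold set, the AUPRC and AUROC of
#' the detector's ranked list and the random-set overlap z-test of its
#' selected markers.
#'
#' @param x a [MarkerResult-class] or a genes x types score matrix.
#' @param gold named list, type -> gold gene ids (see [readGoldStandard()]).
#' @param universe gene universe for the overlap test (default: all genes in
#'   the ranking/matrix).
#' @param polarity score polarity; taken from `x` when it is a
#'   [MarkerResult-class].
#' @param nRandom,seed overlap z-test parameters.
#' @return data.frame with one row per type: `sample_type`, `n_gold`,
#'   `auprc`, `auroc` (NA when the ranking has no positives or no
#'   negatives), `overlap`, `overlap_p`.
#' @export
goldStandardBenchmark <- function(x, gold, universe = NULL, polarity = NULL,
                                  nRandom = 1000L, seed = 1L) {
    if (methods::is(x, "MarkerResult")) polarity <- scorePolarity(x)
    if (is.null(polarity)) stop("'polarity' required for a score matrix")
    ranks <- rankedScores(x)
    if (is.null(universe))
        universe <- if (is.matrix(x)) rownames(x)
                    else unique(markerCalls(x)$gene_id)
    types <- intersect(names(gold), names(ranks))
    unknown <- setdiff(names(gold), names(ranks))
    seeds <- .deriveSeeds(seed, max(1L, length(types)))
    rows <- lapply(seq_along(types), function(i) {
        ty <- types[i]
        g <- gold[[ty]]
        sc <- ranks[[ty]]
        pr <- prCurve(sc, g, polarity = polarity, type = ty)
        roc <- tryCatch(rocCurve(sc, g, polarity = polarity, type = ty),
                        error = function(e) list(auroc = NA_real_))
        ov <- overlapZTest(names(sc), g, universe = universe,
                           nRandom = nRandom, seed = seeds[i])
        data.frame(sample_type = ty, n_gold = length(unique(g)),
                   auprc = pr$auprc, auroc = roc$auroc,
                   overlap = ov$observed, overlap_p = ov$p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sample_type = character(0), n_gold = integer(0),
                          auprc = numeric(0), auroc = numeric(0),
                          overlap = integer(0), overlap_p = numeric(0))
    attr(out, "types_without_ranking") <- unknown
    out
}
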