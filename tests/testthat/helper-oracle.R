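# Brute-force reference implementation of the replicate-block procedure,
# written step by step from the prose description and kept deliberately
# naive (selection sort, positional scans) so it is independent of the
# package's vectorized code paths.

oracle_detect_gene <- function(v, types, cutoff = 1) {
    s <- length(v)
    utypes <- unique(types)
    reps <- vapply(utypes, function(u) sum(types == u), integer(1L))
    names(reps) <- utypes

    # step 2: decreasing stable selection sort (ties: smallest index first)
    remaining <- seq_len(s)
    ord <- integer(0)
    while (length(remaining)) {
        best <- remaining[1L]
        for (j in remaining) if (v[j] > v[best]) best <- j
        ord <- c(ord, best)
        remaining <- remaining[remaining != best]
    }
    sv <- v[ord]
    st <- types[ord]

    # step 3: candidacy of the top type's replicate block
    tt <- st[1L]
    r <- reps[[tt]]
    ok <- TRUE
    for (i in seq_len(r))
        if (st[i] != tt || sv[i] < cutoff) ok <- FALSE
    # a value tie across the cut makes the block order-dependent: reject
    if (ok && r < s && sv[r] == sv[r + 1L]) ok <- FALSE
    if (!ok) return(NULL)

    # step 4: grow the comparison window to replicate closure
    u <- st[r + 1L]
    e <- r + reps[[u]]
    if (e > s) e <- s
    repeat {
        grew <- FALSE
        for (ty in unique(st[(r + 1L):e])) {
            last <- 0L
            for (pos in seq_len(s)) if (st[pos] == ty) last <- pos
            if (last > e) { e <- last; grew <- TRUE }
        }
        if (!grew) break
    }
    if (e > s) e <- s

    # step 5: ratio of block means
    num <- sum(sv[(r + 1L):e]) / (e - r)
    den <- sum(sv[seq_len(r)]) / r
    list(target = tt, cut1 = r, cut2 = as.integer(e), score = num / den)
}

# Run the oracle over a matrix and return a calls data.frame shaped like
# markerCalls() output (unsorted).
oracle_detect <- function(x, types, cutoff = 1) {
    rows <- lapply(rownames(x), function(g) {
        res <- oracle_detect_gene(x[g, ], types, cutoff)
        if (is.null(res)) return(NULL)
        data.frame(gene_id = g, sample_type = res$target, score = res$score,
                   cut1 = res$cut1, cut2 = res$cut2, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_id = character(0), sample_type = character(0),
                          score = numeric(0), cut1 = integer(0),
                          cut2 = integer(0))
    out
}
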