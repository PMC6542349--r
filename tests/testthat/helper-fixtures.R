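# Shared in-code fixtures.

# The six-sample hand-trace profile and its annotations.
toy_profile <- c(10, 9, 8, 4, 3, 2)
toy_types <- c("A", "A", "A", "B", "B", "C")
toy_types_mixed <- c("A", "A", "A", "B", "C", "B")

toy_matrix <- function() {
    x <- rbind(g1 = toy_profile,
               g2 = c(10, 0, 8, 0, 0, 0),   # fails candidacy (block broken)
               g3 = rep(0, 6))              # silent
    colnames(x) <- paste0("s", 1:6)
    x
}

# Random grouped matrix: `nTypes` types with `reps` replicates each.
random_matrix <- function(nGenes, nTypes = 3L, reps = 2L, seed,
                          values = NULL) {
    set.seed(seed)
    s <- nTypes * reps
    x <- if (is.null(values))
        matrix(round(runif(nGenes * s, 0, 10), 2), nGenes, s)
    else matrix(sample(values, nGenes * s, replace = TRUE), nGenes, s)
    dimnames(x) <- list(sprintf("g%04d", seq_len(nGenes)),
                        sprintf("s%02d", seq_len(s)))
    list(x = x, types = rep(LETTERS[seq_len(nTypes)], each = reps))
}

expect_same_calls <- function(res, oracle_calls, tol = 1e-12) {
    calls <- markerCalls(res)
    calls <- calls[order(calls$gene_id), , drop = FALSE]
    oracle_calls <- oracle_calls[order(oracle_calls$gene_id), , drop = FALSE]
    expect_identical(calls$gene_id, oracle_calls$gene_id)
    expect_identical(calls$sample_type, oracle_calls$sample_type)
    expect_identical(calls$cut1, oracle_calls$cut1)
    expect_identical(calls$cut2, oracle_calls$cut2)
    expect_equal(calls$score, oracle_calls$score, tolerance = tol)
}
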