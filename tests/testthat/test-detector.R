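test_that("profiles are sorted decreasingly with stable index tie-breaks", {
    p <- sortProfile(c(4, 9, 1), c("A", "B", "A"))
    expect_equal(p$value, c(9, 4, 1))
    expect_identical(p$sample_type, c("B", "A", "A"))
    expect_identical(p$sample_index, c(2L, 1L, 3L))
    # tie: earlier sample first
    p2 <- sortProfile(c(5, 5), c("A", "B"))
    expect_identical(p2$sample_index, c(1L, 2L))
    expect_error(sortProfile(1:3, c("A", "B")), "length")
    # property: non-increasing permutation of the input
    set.seed(3)
    v <- runif(20)
    p3 <- sortProfile(v, rep(c("A", "B"), 10))
    expect_true(all(diff(p3$value) <= 0))
    expect_equal(sort(p3$sample_index), 1:20)
    expect_equal(p3$value, v[p3$sample_index])
})

test_that("first cut-point follows the replicate-block candidacy rule", {
    reps <- replicateCounts(toy_types)
    cp <- cutPointOne(sortProfile(toy_profile, toy_types), reps)
    expect_true(cp$is_candidate)
    expect_identical(cp$target_type, "A")
    expect_identical(cp$cut1, 3L)
    # block broken by a foreign sample
    cp2 <- cutPointOne(sortProfile(c(10, 9, 8), c("A", "B", "A")),
                       replicateCounts(c("A", "B", "A")))
    expect_false(cp2$is_candidate)
    # values below the expression cutoff
    cp3 <- cutPointOne(sortProfile(c(0.5, 0.4, 0, 0), c("A", "A", "B", "B")),
                       c(A = 2L, B = 2L), cutoff = 1)
    expect_false(cp3$is_candidate)
    # tie across the cut boundary: rejected and flagged
    cp4 <- cutPointOne(sortProfile(c(5, 5, 5, 1), c("A", "A", "B", "B")),
                       c(A = 2L, B = 2L))
    expect_false(cp4$is_candidate)
    expect_true(cp4$boundary_tie)
})

test_that("second cut-point closes the replicates of the window types", {
    reps <- replicateCounts(toy_types)
    p <- sortProfile(toy_profile, toy_types)
    expect_identical(cutPointTwo(p, 3L, reps), 5L)
    # mixed window must grow to cover B's second replicate
    reps_m <- replicateCounts(toy_types_mixed)
    p_m <- sortProfile(toy_profile, toy_types_mixed)
    expect_identical(cutPointTwo(p_m, 3L, reps_m), 6L)
    # two-type matrix: window exhausts the profile
    p2 <- sortProfile(c(9, 8, 2, 1), c("A", "A", "B", "B"))
    expect_identical(cutPointTwo(p2, 2L, c(A = 2L, B = 2L)), 4L)
})

test_that("specificity score is the ratio of block means", {
    p <- sortProfile(c(10, 9, 8, 4, 3), c("A", "A", "A", "B", "B"))
    expect_equal(specificityScore(p, 3, 5), 3.5 / 9)
    p0 <- sortProfile(c(5, 5, 0, 0), c("A", "A", "B", "B"))
    expect_equal(specificityScore(p0, 2, 4), 0)
    p1 <- sortProfile(c(7, 7, 7, 7), c("A", "A", "B", "B"))
    expect_equal(specificityScore(p1, 2, 4), 1)
    expect_error(specificityScore(p, 3, 2), "cut")
    pz <- sortProfile(c(0, 0, 0, 0), c("A", "A", "B", "B"))
    expect_error(specificityScore(pz, 2, 4), "zero")
})

test_that("detectMarkers composes the steps on the hand-traced toy", {
    res <- detectMarkers(toy_matrix(), sampleType = toy_types)
    calls <- markerCalls(res)
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$gene_id, "g1")
    expect_identical(calls$sample_type, "A")
    expect_identical(c(calls$cut1, calls$cut2), c(3L, 5L))
    expect_equal(calls$score, 7 / 18)
    expect_identical(scorePolarity(res), "low_is_specific")
    # mixed annotation variant
    calls_m <- markerCalls(detectMarkers(toy_matrix()[1, , drop = FALSE],
                                         sampleType = toy_types_mixed))
    expect_identical(calls_m$cut2, 6L)
    expect_equal(calls_m$score, 1 / 3)
})

test_that("planted perfect markers are all recovered with score 0", {
    sim <- simulateExpression(noiseSd = 0, seed = 101)
    res <- detectMarkers(sim$experiment)
    calls <- markerCalls(res)
    planted <- plantedMarkers(sim$truth)
    expect_setequal(calls$gene_id, unlist(planted))
    expect_true(all(calls$score == 0))
    for (ty in names(planted))
        expect_setequal(markerList(res)[[ty]], planted[[ty]])
})

test_that("detector agrees with the naive step-by-step oracle", {
    for (seed in c(11, 12, 13)) {
        fx <- random_matrix(60, nTypes = 3L, reps = 2L, seed = seed)
        res <- detectMarkers(fx$x, sampleType = fx$types)
        expect_same_calls(res, oracle_detect(fx$x, fx$types))
    }
    # discrete values force heavy ties
    fx <- random_matrix(300, nTypes = 3L, reps = 2L, seed = 77,
                        values = 0:3)
    expect_same_calls(detectMarkers(fx$x, sampleType = fx$types),
                      oracle_detect(fx$x, fx$types))
})

test_that("scores are bounded, scale-equivariant and cutoff-monotone", {
    fx <- random_matrix(400, nTypes = 3L, reps = 3L, seed = 5)
    res <- detectMarkers(fx$x, sampleType = fx$types)
    sc <- markerCalls(res)$score
    expect_true(all(sc >= 0 & sc <= 1))
    # joint scaling of matrix and cutoff leaves everything unchanged
    res_scaled <- detectMarkers(fx$x * 3.7, sampleType = fx$types,
                                cutoff = 3.7)
    expect_equal(markerCalls(res_scaled)$score, markerCalls(res)$score)
    expect_identical(markerCalls(res_scaled)$gene_id,
                     markerCalls(res)$gene_id)
    # raising the cutoff never enlarges the detected set
    sets <- lapply(c(1, 2, 4, 8), function(co)
        markerCalls(detectMarkers(fx$x, sampleType = fx$types,
                                  cutoff = co))$gene_id)
    for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("identical inputs give identical ranked output, grouped by type", {
    fx <- random_matrix(200, nTypes = 4L, reps = 2L, seed = 21)
    r1 <- detectMarkers(fx$x, sampleType = fx$types)
    r2 <- detectMarkers(fx$x, sampleType = fx$types)
    expect_identical(markerCalls(r1), markerCalls(r2))
    calls <- markerCalls(r1)
    for (df in split(calls, calls$sample_type))
        expect_true(all(diff(df$score) >= 0))  # ascending within type
    expect_true(!anyDuplicated(calls$gene_id))  # one target type per gene
})

test_that("constant profiles are boundary-tie rejections, not markers", {
    x <- rbind(hk = rep(4, 6), mk = c(8, 8, 8, 0, 0, 0))
    colnames(x) <- paste0("s", 1:6)
    res <- detectMarkers(x, sampleType = c("A", "A", "A", "B", "B", "B"))
    expect_identical(markerCalls(res)$gene_id, "mk")
    expect_identical(detectorParameters(res)$boundary_ties, "hk")
})

test_that("marker tables round-trip through the tab-separated format", {
    res <- detectMarkers(toy_matrix(), sampleType = toy_types)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeMarkerTable(res, f)
    df <- readMarkerTable(f)
    expect_identical(df$gene_id, "g1")
    expect_identical(df$detector, "rb")
    expect_equal(df$score, round(7 / 18, 6))
    expect_match(readLines(f)[2], "0\\.388889")
})
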