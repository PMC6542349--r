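test_that("clustering metrics match their closed forms", {
    a <- c("A", "A", "B", "B")
    expect_equal(nmi(a, c(1, 1, 2, 2)), 1)
    expect_equal(nmi(a, c(2, 2, 1, 1)), 1)          # relabeling
    expect_equal(nmi(a, c(1, 1, 1, 1)), 0)          # single cluster
    expect_equal(nmi(a, c(1, 2, 1, 2)), 0)          # independent split
    expect_equal(adjustedRandIndex(a, c(1, 1, 2, 2)), 1)
    expect_equal(adjustedRandIndex(a, c(1, 2, 1, 2)), -0.5)
    expect_equal(purity(c(1, 1, 1, 2, 2), c("A", "A", "B", "B", "B")), 0.8)
    expect_equal(purity(a, a), 1)
    expect_equal(purity(1:4, a), 1)                 # singleton clusters
    expect_error(nmi(a, 1:3), "length")
})

test_that("NMI and ARI are symmetric; purity is not", {
    set.seed(14)
    for (i in 1:10) {
        a <- sample(3, 12, replace = TRUE)
        b <- sample(2, 12, replace = TRUE)
        expect_equal(nmi(a, b), nmi(b, a))
        expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
    }
    expect_gt(purity(1:4, c("A", "A", "B", "B")),
              purity(c("A", "A", "B", "B"), 1:4))
})

test_that("ARI agrees with an independent implementation and centers at 0", {
    set.seed(15)
    for (i in 1:25) {
        a <- sample(4, 20, replace = TRUE)
        b <- sample(3, 20, replace = TRUE)
        expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                     tolerance = 1e-12)
    }
    # expectation over random partitions is ~0
    ari <- replicate(4000, adjustedRandIndex(sample(3, 12, replace = TRUE),
                                             sample(3, 12, replace = TRUE)))
    expect_lt(abs(mean(ari)), 0.01)
})

test_that("PCA embeds samples with fixed sign and ordered variance", {
    fx <- random_matrix(40, nTypes = 3L, reps = 3L, seed = 31)
    co <- pcaEmbed(fx$x)
    expect_identical(dim(co), c(9L, 2L))
    ev <- attr(co, "explained")
    expect_gte(ev[1], ev[2])
    # row-order invariance of the gene features
    set.seed(32)
    co_shuf <- pcaEmbed(fx$x[sample(nrow(fx$x)), ])
    expect_equal(co_shuf, co, tolerance = 1e-8)
    # rank-1 data: second component carries ~no variance
    v <- outer(runif(10), seq_len(5))
    dimnames(v) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:5))
    ev1 <- attr(pcaEmbed(v), "explained")
    expect_lt(ev1[2] / ev1[1], 1e-10)
    expect_error(pcaEmbed(v[1, , drop = FALSE]), "2 genes")
})

test_that("k-means quality is perfect on separated clouds and seeded", {
    set.seed(41)
    co <- rbind(matrix(rnorm(20, 0, 0.05), 10),
                matrix(rnorm(20, 5, 0.05), 10))
    labels <- rep(c("A", "B"), each = 10)
    q <- kmeansQuality(co, labels, k = 2, runs = 25, seed = 6)
    expect_equal(q$nmi_mean, 1); expect_equal(q$nmi_sd, 0)
    expect_equal(q$purity_mean, 1)
    expect_equal(q$ari_mean, 1)
    q2 <- kmeansQuality(co, labels, k = 2, runs = 25, seed = 6)
    expect_identical(q, q2)
    expect_error(kmeansQuality(co, labels, k = 25, runs = 1, seed = 1),
                 "exceeds")
})

test_that("degenerate identical coordinates fall back to one cluster", {
    co <- matrix(1, 5, 2)
    labels <- c("A", "A", "A", "B", "B")
    q <- kmeansQuality(co, labels, k = 2, runs = 5, seed = 2)
    expect_equal(q$purity_mean, 0.6)  # majority class 3 of 5
    expect_equal(q$nmi_mean, 0)
})

test_that("PR curve follows the non-interpolated step summation", {
    sc <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
    pr <- prCurve(sc, c("a", "c"), polarity = "high_is_specific")
    expect_equal(pr$curve$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
    expect_equal(pr$auprc, (1 + 2 / 3) / 2)
    # perfect ranking
    expect_equal(prCurve(sc, c("a", "b"), "high_is_specific")$auprc, 1)
    # low_is_specific ranks ascending
    expect_equal(prCurve(sc, c("d", "c"), "low_is_specific")$auprc, 1)
    # reversed polarity degrades the perfect ranking
    expect_lt(prCurve(sc, c("a", "b"), "low_is_specific")$auprc, 1)
    expect_error(prCurve(sc, character(0), type = "A"), "A")
    # tied scores enter together
    tied <- setNames(c(2, 2, 1, 1), c("a", "b", "c", "d"))
    pr_t <- prCurve(tied, c("a", "b"), "high_is_specific")
    expect_identical(nrow(pr_t$curve), 2L)
    expect_equal(pr_t$auprc, 1)
})

test_that("AUROC is the tie-aware rank probability and matches pROC", {
    sc <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
    expect_equal(rocCurve(sc, c("a", "b"), "high_is_specific")$auroc, 1)
    expect_equal(rocCurve(setNames(rep(1, 6), letters[1:6]), c("a", "b"),
                          "high_is_specific")$auroc, 0.5)
    set.seed(51)
    for (i in 1:10) {
        scores <- setNames(sample(0:5, 30, replace = TRUE),
                           sprintf("g%02d", 1:30))
        gold <- sample(names(scores), 8)
        ours <- rocCurve(scores, gold, "high_is_specific")$auroc
        ref <- suppressMessages(as.numeric(pROC::auc(
            pROC::roc(names(scores) %in% gold, scores,
                      direction = "<", quiet = TRUE))))
        expect_equal(ours, ref, tolerance = 1e-12)
    }
})

test_that("AUPRC and AUROC are invariant to monotone score transforms", {
    set.seed(52)
    scores <- setNames(runif(40), sprintf("g%02d", 1:40))
    gold <- sample(names(scores), 10)
    for (f in list(function(x) 10 * x + 3, exp, function(x) x^3)) {
        expect_equal(prCurve(f(scores), gold, "high_is_specific")$auprc,
                     prCurve(scores, gold, "high_is_specific")$auprc)
        expect_equal(rocCurve(f(scores), gold, "high_is_specific")$auroc,
                     rocCurve(scores, gold, "high_is_specific")$auroc)
    }
})

test_that("overlap z-test behaves at the extremes and under the null", {
    universe <- sprintf("g%04d", 1:1000)
    gold <- universe[1:10]
    hit <- overlapZTest(gold, gold, universe, seed = 3)
    expect_identical(hit$observed, 10L)
    expect_lt(hit$p, 1e-6)
    # under the null (prediction drawn by the same mechanism as the random
    # sets), p is roughly uniform
    gold_big <- universe[1:300]
    ps <- vapply(1:200, function(s) {
        pred <- markerBlocks:::.withSeed(1000 + s, sample(universe, 100))
        overlapZTest(pred, gold_big, universe, nRandom = 200, seed = s)$p
    }, numeric(1L))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.001)
    # degenerate: all random overlaps equal
    expect_warning(
        r0 <- overlapZTest(universe[1:2], universe, universe,
                           nRandom = 50, seed = 1),
        "degenerate")
    expect_equal(r0$p, 1)
})

test_that("gold-standard benchmark assembles per-type rows", {
    sim <- simulateExpression(noiseSd = 0, seed = 61)
    res <- detectMarkers(sim$experiment)
    gold <- makeGoldStandard(sim$truth)
    b <- goldStandardBenchmark(res, gold, universe = rownames(sim$experiment),
                               nRandom = 300, seed = 2)
    expect_identical(b$sample_type, names(gold))
    expect_equal(b$auprc, rep(1, 5))
    expect_true(all(b$overlap_p < 1e-6))
    # score-matrix route with full rankings gives AUROC too
    sc <- baselineScores(sim$experiment, "spm")
    # the full-matrix ranking makes the overlap test degenerate (predicted
    # set = universe); only the ranking metrics are meaningful here
    b2 <- suppressWarnings(
        goldStandardBenchmark(sc, gold, polarity = "high_is_specific",
                              nRandom = 300, seed = 2))
    expect_true(all(b2$auroc == 1))
})
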