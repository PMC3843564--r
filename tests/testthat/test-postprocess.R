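# Build a small DecompositionResult by hand for unit tests.
makeResult <- function(cs, tfa) {
    new("DecompositionResult", cs = cs, logTfa = tfa,
        objective = 0, objectiveTrace = c(1, 0), nIterations = 1L,
        converged = TRUE, seed = 1L, restartIndex = 1L)
}

dimn <- function(m, p, n) list(genes = sprintf("g%d", seq_len(m)),
                               tfs = sprintf("T%d", seq_len(p)),
                               conds = sprintf("c%d", seq_len(n)))

test_that("gauge normalization fixes per-column RMS and preserves the product", {
    d <- dimn(2, 1, 2)
    cs <- matrix(c(2, 2), 2, 1, dimnames = d[1:2])
    tfa <- matrix(c(0.3, -0.1), 1, 2, dimnames = d[2:3])
    res <- normalizeGauge(makeResult(cs, tfa))
    expect_equal(unname(csMatrix(res)[, 1]), c(1, 1))
    expect_equal(unname(logTfa(res)[1, ]), c(0.6, -0.2))

    # idempotent, and reconstruction invariant on random fits
    set.seed(5)
    for (i in 1:5) {
        cs <- matrix(rnorm(12), 4, 3, dimnames = dimn(4, 3, 2)[1:2])
        cs[sample(12, 4)] <- 0
        if (any(colSums(cs != 0) == 0)) next
        tfa <- matrix(rnorm(6), 3, 2, dimnames = dimn(4, 3, 2)[2:3])
        r0 <- makeResult(cs, tfa)
        r1 <- normalizeGauge(r0)
        for (k in 1:3) {
            nz <- csMatrix(r1)[, k] != 0
            expect_equal(sqrt(mean(csMatrix(r1)[nz, k]^2)), 1,
                         tolerance = 1e-9)
        }
        expect_lt(norm(csMatrix(r1) %*% logTfa(r1) - cs %*% tfa, "F"), 1e-10)
        r2 <- normalizeGauge(r1)
        expect_equal(csMatrix(r2), csMatrix(r1), tolerance = 1e-12)
    }

    csz <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = dimn(2, 2, 2)[1:2])
    tfaz <- matrix(0, 2, 2, dimnames = dimn(2, 2, 2)[2:3])
    expect_error(normalizeGauge(makeResult(csz, tfaz)), "gauge error")
})

test_that("sign correction flips by anchor majority and flags the anchorless", {
    d <- dimn(3, 2, 2)
    e <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2, dimnames = d[1:2])
    known <- array(TRUE, dim(e), dimnames(e))
    known[, 2] <- FALSE                      # T2 has no anchors
    pat <- ConnectivityPattern(e, known)

    cs <- matrix(c(-1, -1, 0, 0, 1, -1), 3, 2, dimnames = d[1:2])
    tfa <- matrix(1:4 / 10, 2, 2, dimnames = d[2:3])
    out <- correctSigns(makeResult(cs, tfa), pat)
    # T1: both documented-activation anchors fitted negative -> flip
    expect_true(out$flips[["T1"]])
    expect_equal(unname(csMatrix(out$result)[, 1]), c(1, 1, 0))
    expect_equal(unname(logTfa(out$result)[1, ]), unname(-tfa[1, ]))
    # T2: no anchors -> unflipped, flagged
    expect_false(out$flips[["T2"]])
    expect_identical(out$flagged, "T2")
    expect_equal(csMatrix(out$result)[, 2], cs[, 2])

    # all-agreeing fit is untouched; correction is idempotent; the
    # reconstruction is invariant under the flip
    out2 <- correctSigns(out$result, pat)
    expect_false(any(out2$flips))
    expect_identical(csMatrix(out2$result), csMatrix(out$result))
    expect_equal(csMatrix(out$result) %*% logTfa(out$result),
                 cs %*% tfa, tolerance = 1e-12)

    # exact tie -> no flip, flagged
    e3 <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "T1"))
    pat3 <- ConnectivityPattern(e3)
    cs3 <- matrix(c(1, -1), 2, 1, dimnames = dimnames(e3))
    out3 <- correctSigns(makeResult(cs3, matrix(1, 1, 2,
        dimnames = list("T1", c("c1", "c2")))), pat3)
    expect_false(out3$flips[["T1"]])
    expect_identical(out3$flagged, "T1")
})

test_that("aggregation reproduces two-pass statistics and the strength rules", {
    d <- dimn(2, 2, 2)
    mk <- function(a) makeResult(
        matrix(a, 2, 2, dimnames = d[1:2]),
        matrix(a[1:4] / 2, 2, 2, dimnames = d[2:3]))
    # single result: sd 0; |cs| = 1.5 classified strong
    agg1 <- aggregateResults(list(mk(c(1.5, -0.5, 0, -1.4))))
    expect_true(all(agg1@csSd == 0))
    expect_identical(agg1@classification[1, 1], "strong-activation")
    expect_identical(agg1@classification[2, 1], "weak-repression")
    expect_identical(agg1@classification[1, 2], "none")
    expect_identical(agg1@classification[2, 2], "strong-repression")

    # mean -1.4 with CV 0.1 is strong repression
    a <- -1.4; sdev <- 0.14
    vals <- c(a - sdev, a + sdev)   # mean a, sample sd = 0.14 * sqrt(2)
    res2 <- list(mk(c(vals[1], 0, 0, 1)), mk(c(vals[2], 0, 0, 1)))
    agg2 <- aggregateResults(res2)
    cv <- abs(sd(vals) / mean(vals))
    expect_lt(cv, 0.5)
    expect_identical(agg2@classification[1, 1], "strong-repression")

    # high-variability strong-magnitude entries are undetermined
    res3 <- list(mk(c(3, 0, 0, 1)), mk(c(-0.5, 0, 0, 1)))
    agg3 <- aggregateResults(res3)
    expect_identical(agg3@classification[1, 1], "undetermined")

    # means and sds equal an independently coded two-pass computation
    set.seed(17)
    rs <- lapply(1:4, function(i) mk(rnorm(4)))
    agg <- aggregateResults(rs)
    for (i in 1:2) for (j in 1:2) {
        vals <- vapply(rs, function(r) r@cs[i, j], numeric(1))
        mu <- sum(vals) / length(vals)
        s2 <- sum((vals - mu)^2) / (length(vals) - 1)
        expect_equal(agg@csMean[i, j], mu, tolerance = 1e-12)
        expect_equal(agg@csSd[i, j], sqrt(s2), tolerance = 1e-12)
    }

    # permutation invariance
    aggP <- aggregateResults(rev(rs))
    expect_equal(aggP@csMean, agg@csMean, tolerance = 1e-12)
    expect_equal(aggP@csSd, agg@csSd, tolerance = 1e-12)

    # dimension mismatch
    bad <- makeResult(matrix(1, 3, 2,
                             dimnames = list(sprintf("g%d", 1:3),
                                             d$tfs)),
                      matrix(1, 2, 2, dimnames = d[2:3]))
    expect_error(aggregateResults(list(rs[[1]], bad)), "aggregation error")
})

test_that("undetermined classification requires the magnitude criterion too", {
    # CV above threshold but |mean| <= 1 stays weak, not undetermined
    d <- dimn(2, 1, 2)
    mk <- function(v) makeResult(matrix(c(v, 1), 2, 1, dimnames = d[1:2]),
                                 matrix(0, 1, 2, dimnames = d[2:3]))
    agg <- aggregateResults(list(mk(0.9), mk(0.1)))
    expect_identical(agg@classification[1, 1], "weak-activation")
})

test_that("aggregate artifacts round-trip through the exporters", {
    run <- recoveryRun(seed = 55, m = 20, p = 3, nRestarts = 3)
    dir <- withr::local_tempdir()
    writeAggregateResult(run$agg, dir)
    expect_true(all(file.exists(file.path(dir,
        c("cs_mean.tsv", "cs_sd.tsv", "tfa_mean.tsv", "tfa_sd.tsv",
          "classification.tsv", "edges.tsv")))))
    back <- readMatrixTsvForTest(file.path(dir, "cs_mean.tsv"))
    expect_equal(back, run$agg@csMean, tolerance = 0)
    edges <- read.delim(file.path(dir, "edges.tsv"))
    expect_identical(nrow(edges), sum(entries(run$pattern) != 0))
})
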