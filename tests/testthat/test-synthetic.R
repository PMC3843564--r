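test_that("generated patterns are compliant, deterministic and within spec", {
    pat <- generatePattern(m = 55, p = 7, nConditions = 4, seed = 1)
    expect_identical(dim(pat), c(55L, 7L))
    expect_true(isCompliant(checkCompliance(pat, 4, seed = 99)))
    expect_true(all(regulonSizes(pat) >= 2))
    expect_true(all(inDegrees(pat) <= 4))
    expect_true(all(inDegrees(pat) >= 1))

    pat2 <- generatePattern(m = 55, p = 7, nConditions = 4, seed = 1)
    expect_identical(entries(pat2), entries(pat))

    # single-TF patterns are compliant whenever the regulon has >= 2 genes
    p1 <- generatePattern(m = 6, p = 1, targetsPerTf = c(2, 6),
                          nConditions = 2, seed = 3)
    expect_true(isCompliant(checkCompliance(p1, 2)))

    # every emitted small pattern passes the enumeration oracle
    for (s in 1:5) {
        sm <- generatePattern(m = 6, p = 3, targetsPerTf = c(2, 3),
                              nConditions = 3, seed = s)
        expect_true(complianceOracle(entries(sm), 3)$compliant)
    }

    # regulon budget too small to cover every gene: infeasible
    expect_error(generatePattern(m = 10, p = 2, targetsPerTf = c(2, 3),
                                 nConditions = 4, maxRejections = 10),
                 "infeasible-parameters")
})

test_that("ground truth honors the pattern signs and the RMS gauge", {
    pat <- generatePattern(m = 30, p = 4, nConditions = 4, seed = 7)
    truth <- generateTruth(pat, nConditions = 4, seed = 8)
    e <- entries(pat)
    expect_true(all(sign(truth@csTrue[e != 0]) == e[e != 0]))
    expect_true(all(truth@csTrue[e == 0] == 0))
    for (k in seq_len(4)) {
        nz <- e[, k] != 0
        expect_equal(sqrt(mean(truth@csTrue[nz, k]^2)), 1,
                     tolerance = 1e-9)
    }
    # nonzero magnitudes bounded away from zero pre-normalization
    expect_true(all(abs(truth@csTrue[e != 0]) > 0))

    t2 <- generateTruth(pat, nConditions = 4, seed = 8)
    expect_identical(t2@csTrue, truth@csTrue)
    expect_identical(t2@logTfaTrue, truth@logTfaTrue)

    t0 <- generateTruth(pat, tfaScale = 0, nConditions = 4, seed = 9)
    expect_true(all(t0@logTfaTrue == 0))
})

test_that("replicate simulation applies log-normal noise of the stated size", {
    pat <- generatePattern(m = 200, p = 7, targetsPerTf = c(25, 40),
                           nConditions = 4, seed = 10)
    truth <- generateTruth(pat, nConditions = 4, noiseSd = 0.05,
                           nReplicates = 2, seed = 11)
    expr <- simulateReplicates(truth)
    expect_true(all(vapply(ratioMatrices(expr),
                           function(m) all(m > 0), logical(1))))
    base <- truth@csTrue %*% truth@logTfaTrue
    for (lg in logRatios(expr)) {
        resid <- lg - base
        expect_lt(abs(sd(resid) - 0.05), 3 * 0.05 / sqrt(200 * 4))
    }

    # noiseless: replicates identical and exactly consistent with the model
    truth0 <- generateTruth(pat, nConditions = 4, noiseSd = 0,
                            nReplicates = 3, seed = 12)
    expr0 <- simulateReplicates(truth0)
    lgs <- logRatios(expr0)
    expect_identical(lgs[[1]], lgs[[2]])
    expect_equal(lgs[[1]], truth0@csTrue %*% truth0@logTfaTrue,
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the floral fixture matches its documented edges", {
    fx <- floralFixture()
    pat <- fx$pattern
    e <- entries(pat)
    expect_identical(dim(pat), c(27L, 7L))
    expect_setequal(tfIds(pat), c("LFY", "AG", "SEP3", "AP2", "AGL15",
                                  "HY5", "AP3/PI"))
    # AGL15 -> RAV2 documented with unknown direction, encoded +1
    expect_identical(unname(e["RAV2", "AGL15"]), 1)
    expect_false(directionKnown(pat)["RAV2", "AGL15"])
    expect_false(directionKnown(pat)["AGL22", "AGL15"])
    expect_false(directionKnown(pat)["AGL25", "AGL15"])
    expect_false(directionKnown(pat)["EDF4", "AGL15"])
    expect_true(directionKnown(pat)["LEA7", "AGL15"])
    # HLH1 has exactly two regulators of opposite documented sign
    expect_identical(sum(e["HLH1", ] != 0), 2L)
    expect_identical(unname(e["HLH1", "HY5"]), 1)
    expect_identical(unname(e["HLH1", "AP2"]), -1)
    expect_true(all(directionKnown(pat)[c("HLH1", "RD20"), "AP2"]))
    # LFY's twelve text-listed targets
    expect_identical(unname(regulonSizes(pat)[["LFY"]]), 12)

    # lossless SIF round trip
    sif <- withr::local_tempfile(fileext = ".sif")
    writeConnectivity(pat, sif, "sif-edges")
    back <- readConnectivity(sif, "sif-edges")
    expect_identical(entries(back)[geneIds(pat), tfIds(pat)], e)
    expect_identical(directionKnown(back)[geneIds(pat), tfIds(pat)],
                     directionKnown(pat))
})

test_that("makeDataset materializes a reproducible study directory", {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    makeDataset(d1, m = 16, p = 3, nConditions = 4, nReplicates = 2,
                seed = 21)
    makeDataset(d2, m = 16, p = 3, nConditions = 4, nReplicates = 2,
                seed = 21)
    files <- c("pattern.tsv", "pattern.tsv.known.tsv", "cs_true.tsv",
               "log_tfa_true.tsv", "expression_rep1.tsv",
               "expression_rep2.tsv", "manifest.tsv")
    expect_true(all(file.exists(file.path(d1, files))))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         info = f)
    # the emitted pattern + expression reload into a working study
    pat <- readConnectivity(file.path(d1, "pattern.tsv"), "matrix-tsv")
    expr <- readExpression(file.path(d1, sprintf("expression_rep%d.tsv", 1:2)))
    expect_identical(geneIds(pat), geneIds(expr))
    expect_true(isCompliant(checkCompliance(pat, 4)))
})

test_that("full-loop recovery: decompose-correct-aggregate recovers the truth", {
    # sigma = 0: activities match truth almost exactly after alignment
    run0 <- recoveryRun(seed = 301, noiseSd = 0, nReplicates = 1,
                        nRestarts = 5)
    expect_true(all(run0$csAbsCor >= 0.999))
    expect_equal(logTfa(run0$agg), run0$truth@logTfaTrue,
                 tolerance = 1e-6)
    expect_equal(csMatrix(run0$agg), run0$truth@csTrue, tolerance = 1e-6)

    # sigma = 0.05, a few seeds of the full study design
    for (s in c(401, 402, 403)) {
        run <- recoveryRun(seed = s)
        expect_true(all(run$csAbsCor >= 0.95), info = paste("seed", s))
    }
})
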