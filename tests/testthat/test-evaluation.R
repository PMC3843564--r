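test_that("simulated expression is the plain matrix product", {
    cs <- matrix(0, 3, 2)
    tfa <- matrix(rnorm(4), 2, 2)
    expect_identical(simulateExpression(cs, tfa), matrix(0, 3, 2))
    expect_equal(simulateExpression(matrix(2, 1, 1), matrix(0.3, 1, 1)),
                 matrix(0.6, 1, 1))
    expect_error(simulateExpression(matrix(1, 2, 3), matrix(1, 2, 2)),
                 "dimension error")

    set.seed(3)
    cs <- matrix(rnorm(12), 4, 3)
    tfa <- matrix(rnorm(6), 3, 2)
    want <- matrix(0, 4, 2)
    for (i in 1:4) for (j in 1:2) for (k in 1:3)
        want[i, j] <- want[i, j] + cs[i, k] * tfa[k, j]
    expect_equal(simulateExpression(cs, tfa), want, tolerance = 1e-12)
})

test_that("reconstruction R2 matches its textbook definition", {
    set.seed(9)
    meas <- matrix(rnorm(20), 5, 4)
    expect_equal(reconstructionR2(meas, meas), 1)
    grand <- matrix(mean(meas), 5, 4)
    expect_equal(reconstructionR2(meas, grand), 0)
    expect_error(reconstructionR2(matrix(2, 3, 3), matrix(1, 3, 3)),
                 "degenerate-variance")

    sim <- meas + 0.3 * matrix(rnorm(20), 5, 4)
    ssRes <- 0; ssTot <- 0; mu <- sum(meas) / length(meas)
    for (i in 1:5) for (j in 1:4) {
        ssRes <- ssRes + (meas[i, j] - sim[i, j])^2
        ssTot <- ssTot + (meas[i, j] - mu)^2
    }
    expect_equal(reconstructionR2(meas, sim), 1 - ssRes / ssTot,
                 tolerance = 1e-12)

    # invariant under a common affine rescaling of both matrices
    expect_equal(reconstructionR2(3 * meas - 2, 3 * sim - 2),
                 reconstructionR2(meas, sim), tolerance = 1e-10)

    # replicate sets are averaged per gene x condition first
    reps <- list(meas + 0.1, meas - 0.1)
    expect_equal(reconstructionR2(reps, sim),
                 reconstructionR2(meas, sim), tolerance = 1e-10)
})

test_that("min-max normalization maps to [0,1] and flags constants", {
    expect_equal(as.numeric(minmaxNormalize(c(2, 4, 6, 8))),
                 c(0, 1/3, 2/3, 1), tolerance = 1e-12)
    cst <- minmaxNormalize(c(3, 3, 3, 3))
    expect_equal(as.numeric(cst), rep(0.5, 4))
    expect_true(attr(cst, "degenerate"))
    expect_error(minmaxNormalize(1), "domain error")

    set.seed(21)
    x <- rnorm(6)
    n1 <- minmaxNormalize(x)
    expect_equal(unname(minmaxNormalize(as.numeric(n1))), unname(n1),
                 tolerance = 1e-12)          # idempotent
    expect_equal(unname(minmaxNormalize(2.5 * x + 7)), unname(n1),
                 tolerance = 1e-12)          # positive-affine invariant
})

test_that("TFA-mRNA parity normalizes then correlates, splitting dimers", {
    conds <- sprintf("c%d", 1:4)
    tfa <- matrix(c(0.1, 0.4, 0.2, 0.6,
                    0.5, 0.3, 0.2, 0.1), 2, 4, byrow = TRUE,
                  dimnames = list(c("LFY", "AP3/PI"), conds))
    # mRNA for LFY identical to its activity; AP3 negated; PI matching
    mk <- function(v) 10^v
    mrna <- rbind(LFY = mk(tfa["LFY", ]),
                  AP3 = mk(-tfa["AP3/PI", ]),
                  PI = mk(tfa["AP3/PI", ]))
    colnames(mrna) <- conds
    tab <- TFExpressionTable(list(mrna),
                             tfIds = c("LFY", "AP3/PI", "AP3/PI"))
    par <- tfaMrnaParity(tfa, tab)
    expect_length(par, 3)
    byGene <- setNames(vapply(par, `[[`, numeric(1), "correlation"),
                       vapply(par, `[[`, character(1), "gene"))
    expect_equal(byGene[["LFY"]], 1, tolerance = 1e-12)
    expect_equal(byGene[["AP3"]], -1, tolerance = 1e-12)
    expect_equal(byGene[["PI"]], 1, tolerance = 1e-12)

    # hand-rolled covariance / (sd * sd) oracle on random 4-point series
    set.seed(33)
    for (i in 1:5) {
        a <- rnorm(4); b <- rnorm(4)
        tfa2 <- matrix(a, 1, 4, dimnames = list("T1", conds))
        tab2 <- TFExpressionTable(list(matrix(10^b, 1, 4,
            dimnames = list("T1", conds))))
        an <- (a - min(a)) / (max(a) - min(a))
        bn <- (b - min(b)) / (max(b) - min(b))
        num <- sum((an - mean(an)) * (bn - mean(bn)))
        den <- sqrt(sum((an - mean(an))^2) * sum((bn - mean(bn))^2))
        expect_equal(tfaMrnaParity(tfa2, tab2)[[1]]$correlation,
                     num / den, tolerance = 1e-12)
    }

    expect_error(tfaMrnaParity(
        matrix(1:4, 1, 4, dimnames = list("ZZZ", conds)), tab),
        "alignment error")
})

test_that("pairwise condition tests are Welch t with strict alpha", {
    arr <- array(0, c(1, 2, 3),
                 dimnames = list("T1", c("c1", "c2"), NULL))
    arr[1, 1, ] <- c(1, 2, 3)
    arr[1, 2, ] <- c(1, 2, 3)
    res <- pairwiseConditionTest(arr)
    expect_equal(res$p, 1)          # identical sample sets: zero effect
    expect_false(res$significant)

    # closed-form Welch oracle on 3-vs-3 toy samples
    x <- c(0.1, 0.5, 0.2); y <- c(1.1, 0.9, 1.4)
    arr[1, 1, ] <- x; arr[1, 2, ] <- y
    res2 <- pairwiseConditionTest(arr)
    se2 <- var(x) / 3 + var(y) / 3
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
    pval <- 2 * pt(-abs(tstat), df)
    expect_equal(res2$statistic, tstat, tolerance = 1e-12)
    expect_equal(res2$df, df, tolerance = 1e-9)
    expect_equal(res2$p, pval, tolerance = 1e-12)

    # strict inequality at the cutoff
    expect_identical(unname(res2$significant), res2$p < 0.05)
    resEdge <- pairwiseConditionTest(arr, alpha = res2$p)
    expect_false(resEdge$significant)

    expect_error(pairwiseConditionTest(array(1, c(1, 2, 1))),
                 "insufficient-replication")

    # every unordered pair appears once
    arr3 <- array(rnorm(2 * 4 * 3), c(2, 4, 3),
                  dimnames = list(c("T1", "T2"), sprintf("c%d", 1:4), NULL))
    res3 <- pairwiseConditionTest(arr3)
    expect_identical(nrow(res3), 2L * 6L)
})

test_that("noise-free pipeline reconstructs expression essentially perfectly", {
    run <- recoveryRun(seed = 77, m = 30, p = 4, noiseSd = 0,
                       nReplicates = 2, nRestarts = 5)
    sim <- simulateExpression(csMatrix(run$agg), logTfa(run$agg))
    r2 <- reconstructionR2(run$expr, sim)
    expect_gte(r2, 1 - 1e-9)
})

test_that("evaluation report assembles and serializes", {
    run <- recoveryRun(seed = 88, m = 20, p = 3, nReplicates = 3,
                       nRestarts = 3)
    # TF mRNA proportional to true activity
    mrna <- 10^run$truth@logTfaTrue
    tab <- TFExpressionTable(list(mrna))
    rep_ <- evaluateModel(run$agg, run$expr, results = run$results,
                          tfExpr = tab)
    expect_s4_class(rep_, "EvaluationReport")
    expect_lte(rep_@rSquared, 1)
    expect_gt(rep_@rSquared, 0.8)
    expect_identical(nrow(rep_@pairwiseTests), 3L * 6L)
    expect_true(all(rep_@pairwiseTests$p >= 0 & rep_@pairwiseTests$p <= 1))

    dir <- withr::local_tempdir()
    writeEvaluationReport(rep_, dir)
    expect_true(all(file.exists(file.path(dir,
        c("parity.tsv", "pairwise_tests.tsv", "scatter.tsv",
          "evaluation.tsv")))))
    sc <- read.delim(file.path(dir, "scatter.tsv"))
    expect_identical(nrow(sc), 20L * 4L)
})
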