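#' Simulate log expression from a fitted model
#'
#' The model-implied ("simulated") log10 expression is the plain matrix
#' product of the connectivity strengths with the log10 TF activities.
#'
#' @param cs m x p numeric matrix.
#' @param logTfa p x n numeric matrix.
#' @return m x n numeric matrix of simulated log10 expression ratios.
#' @export
simulateExpression <- function(cs, logTfa) {
    if (ncol(cs) != nrow(logTfa))
        stop("dimension error: cs and logTfa are not conformable")
    cs %*% logTfa
}

#' Pooled reconstruction R-squared
#'
#' Agreement between measured and model-simulated log expression, pooled
#' over every gene-condition pair as one global scatter:
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the grand mean of the measured values. When the measurement is
#' a replicate set, replicates are averaged per gene and condition
#' before comparison.
#'
#' @param measured m x n numeric matrix of measured log10 ratios, or an
#'   [ExpressionRatioSet-class] (replicates are averaged in log space),
#'   or a list of replicate log matrices.
#' @param simulated m x n numeric matrix from [simulateExpression()].
#' @return numeric scalar in \eqn{(-\infty, 1]}.
#' @export
reconstructionR2 <- function(measured, simulated) {
    if (is(measured, "ExpressionRatioSet")) measured <- meanLogRatios(measured)
    if (is.list(measured)) measured <- Reduce(`+`, measured) / length(measured)
    if (!identical(dim(measured), dim(simulated)))
        stop("dimension error: measured and simulated shapes differ")
    ssTot <- sum((measured - mean(measured))^2)
    if (ssTot == 0)
        stop("degenerate-variance error: measured matrix is constant")
    1 - sum((measured - simulated)^2) / ssTot
}

#' Min-max normalize a condition series
#'
#' Maps a series to [0, 1] by \eqn{(x - \min)/(\max - \min)}. A constant
#' series is mapped to all 0.5 and flagged via the \code{"degenerate"}
#' attribute rather than erroring, so that a flat activity profile can
#' still be drawn on a parity plot.
#'
#' @param series numeric vector of length at least 2.
#' @return numeric vector in [0, 1] with attribute \code{degenerate}
#'   (logical).
#' @export
minmaxNormalize <- function(series) {
    if (length(series) < 2L)
        stop("domain error: series must have length >= 2")
    rng <- range(series)
    if (rng[1] == rng[2]) {
        out <- rep(0.5, length(series))
        names(out) <- names(series)
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    out <- (series - rng[1]) / (rng[2] - rng[1])
    attr(out, "degenerate") <- FALSE
    out
}

#' TF-activity versus TF-mRNA parity
#'
#' For each TF, min-max normalizes its inferred activity series and the
#' log10 mRNA series of its encoding gene (averaged over replicates)
#' across conditions, and reports their Pearson correlation. A composite
#' regulator (TF id containing \code{"/"}, e.g. a dimer) is compared
#' against each constituent gene's series separately.
#'
#' @param tfaMean p x n matrix of mean log10 TF activities (rownames =
#'   TF ids, colnames = condition ids).
#' @param tfExpr a [TFExpressionTable-class] with matching condition
#'   labels.
#' @return list of comparisons; each element has components \code{tf},
#'   \code{gene}, \code{tfa}, \code{mrna} (normalized series),
#'   \code{correlation}, \code{degenerateTfa}, \code{degenerateMrna}.
#' @export
tfaMrnaParity <- function(tfaMean, tfExpr) {
    if (!identical(colnames(tfaMean), conditionIds(tfExpr)))
        stop("alignment error: condition labels differ")
    mrna <- tfMeanLogExpression(tfExpr)
    out <- list()
    for (tf in rownames(tfaMean)) {
        rows <- which(tfExpr@tfIds == tf)
        if (length(rows) == 0L && grepl("/", tf, fixed = TRUE))
            rows <- which(tfExpr@geneIds %in% strsplit(tf, "/", fixed = TRUE)[[1]])
        if (length(rows) == 0L)
            stop("alignment error: no mRNA series for TF '", tf, "'")
        for (i in rows) {
            a <- minmaxNormalize(tfaMean[tf, ])
            m <- minmaxNormalize(mrna[i, ])
            degA <- attr(a, "degenerate")
            degM <- attr(m, "degenerate")
            r <- if (degA || degM) NA_real_ else cor(a, m)
            out[[length(out) + 1L]] <- list(
                tf = tf, gene = tfExpr@geneIds[i], tfa = as.numeric(a),
                mrna = as.numeric(m), correlation = r,
                degenerateTfa = degA, degenerateMrna = degM)
        }
    }
    out
}

#' Pairwise condition tests on TF activities
#'
#' Two-sided Welch (unequal-variance) t tests for every unordered pair
#' of conditions, per TF, using the replicate activities as samples.
#' Significance is \eqn{p < \alpha} (strict); no multiple-testing
#' correction is applied, and that choice is surfaced in the report.
#'
#' @param tfaReplicates p x n x r numeric array of per-replicate log10
#'   TF activities, or a list of p x n matrices (one per replicate).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame with columns tf, conditionA, conditionB,
#'   statistic, df, p, significant.
#' @export
pairwiseConditionTest <- function(tfaReplicates, alpha = 0.05) {
    if (is.list(tfaReplicates)) {
        tfaReplicates <- simplify2array(tfaReplicates)
    }
    stopifnot(length(dim(tfaReplicates)) == 3L)
    if (dim(tfaReplicates)[3] < 2L)
        stop("insufficient-replication error: >= 2 samples per condition required")
    tfs <- dimnames(tfaReplicates)[[1]]
    conds <- dimnames(tfaReplicates)[[2]]
    if (is.null(tfs)) tfs <- paste0("TF", seq_len(dim(tfaReplicates)[1]))
    if (is.null(conds)) conds <- paste0("cond", seq_len(dim(tfaReplicates)[2]))
    rows <- list()
    for (k in seq_along(tfs)) {
        for (a in seq_len(length(conds) - 1L)) {
            for (b in seq((a + 1L), length(conds))) {
                x <- tfaReplicates[k, a, ]
                y <- tfaReplicates[k, b, ]
                stderr2 <- var(x) / length(x) + var(y) / length(y)
                # mirror t.test's "essentially constant" guard: a zero
                # effect with (near-)zero spread is no evidence at all
                if (sqrt(stderr2) < 10 * .Machine$double.eps *
                        max(abs(mean(x)), abs(mean(y)), 1e-300)) {
                    eq <- abs(mean(x) - mean(y)) <=
                        1e-8 * max(abs(mean(x)), abs(mean(y)), 1e-300)
                    pv <- if (eq) 1 else 0
                    stat <- if (eq) 0 else Inf
                    df <- NA_real_
                } else {
                    tt <- t.test(x, y, var.equal = FALSE)
                    pv <- tt$p.value
                    stat <- unname(tt$statistic)
                    df <- unname(tt$parameter)
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    tf = tfs[k], conditionA = conds[a], conditionB = conds[b],
                    statistic = stat, df = df, p = pv,
                    significant = pv < alpha, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

#' Evaluate a fitted model against the measurements
#'
#' Convenience wrapper assembling an [EvaluationReport-class]: pooled
#' reconstruction R-squared (replicates averaged before comparison),
#' TF-activity/TF-mRNA parity, and pairwise Welch tests across the
#' replicate activities.
#'
#' @param agg an [AggregateResult-class].
#' @param expr the measured [ExpressionRatioSet-class] (aligned).
#' @param results the per-replicate corrected
#'   [DecompositionResult-class] list (for the pairwise tests); optional
#'   when only R-squared and parity are wanted.
#' @param tfExpr optional [TFExpressionTable-class] for the parity
#'   comparison.
#' @param alpha significance cutoff for the pairwise tests.
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(agg, expr, results = NULL, tfExpr = NULL,
                          alpha = 0.05) {
    sim <- simulateExpression(agg@csMean, agg@tfaMean)
    meas <- meanLogRatios(expr)
    r2 <- reconstructionR2(meas, sim)
    parity <- if (!is.null(tfExpr)) tfaMrnaParity(agg@tfaMean, tfExpr)
              else list()
    tests <- data.frame()
    if (!is.null(results) && length(results) >= 2L)
        tests <- pairwiseConditionTest(lapply(results, slot, "logTfa"),
                                       alpha = alpha)
    scatter <- data.frame(
        gene = rep(rownames(meas), ncol(meas)),
        condition = rep(colnames(meas), each = nrow(meas)),
        measured = as.numeric(meas), simulated = as.numeric(sim),
        stringsAsFactors = FALSE)
    notes <- c("r_squared pooled over all gene-condition pairs; replicates averaged before comparison",
               "pairwise tests: Welch two-sample t, no multiplicity correction")
    deg <- vapply(parity, function(x) x$degenerateTfa || x$degenerateMrna,
                  logical(1))
    if (any(deg))
        notes <- c(notes, paste0("degenerate (constant) parity series for: ",
            paste(unique(vapply(parity[deg], `[[`, character(1), "tf")),
                  collapse = ", ")))
    new("EvaluationReport", rSquared = r2, parity = parity,
        pairwiseTests = tests, alpha = alpha, scatter = scatter,
        notes = notes)
}

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: reconstruction R^2 = %.3f\n",
                object@rSquared))
    if (length(object@parity)) {
        cat("  TFA-vs-mRNA parity correlations:\n")
        for (x in object@parity)
            cat(sprintf("    %s (%s): %s\n", x$tf, x$gene,
                        ifelse(is.na(x$correlation), "degenerate",
                               sprintf("%.3f", x$correlation))))
    }
    if (nrow(object@pairwiseTests))
        cat(sprintf("  %d/%d pairwise condition tests significant at alpha = %g\n",
                    sum(object@pairwiseTests$significant),
                    nrow(object@pairwiseTests), object@alpha))
    for (n in object@notes) cat("  note:", n, "\n")
})

#' Export an evaluation report as TSV artifacts
#'
#' Writes \code{parity.tsv}, \code{pairwise_tests.tsv} and
#' \code{scatter.tsv} (measured vs simulated log expression pairs for
#' external plotting) plus \code{evaluation.tsv} with the scalar
#' statistics.
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory (created if absent).
#' @export
writeEvaluationReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (length(report@parity)) {
        lines <- "tf\tgene\tcondition\ttfa_norm\tmrna_norm\tcorrelation"
        for (x in report@parity) {
            conds <- seq_along(x$tfa)
            lines <- c(lines, sprintf("%s\t%s\t%d\t%.17g\t%.17g\t%.17g",
                                      x$tf, x$gene, conds, x$tfa, x$mrna,
                                      x$correlation))
        }
        writeLines(lines, file.path(dir, "parity.tsv"))
    }
    if (nrow(report@pairwiseTests)) {
        t <- report@pairwiseTests
        writeLines(c("tf\tcondition_a\tcondition_b\tstatistic\tdf\tp\tsignificant",
                     sprintf("%s\t%s\t%s\t%.17g\t%.17g\t%.17g\t%s",
                             t$tf, t$conditionA, t$conditionB, t$statistic,
                             t$df, t$p, t$significant)),
                   file.path(dir, "pairwise_tests.tsv"))
    }
    s <- report@scatter
    writeLines(c("gene\tcondition\tmeasured\tsimulated",
                 sprintf("%s\t%s\t%.17g\t%.17g", s$gene, s$condition,
                         s$measured, s$simulated)),
               file.path(dir, "scatter.tsv"))
    writeKeyValue(list(r_squared = report@rSquared, alpha = report@alpha,
                       notes = report@notes),
                  file.path(dir, "evaluation.tsv"))
    invisible(dir)
}
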