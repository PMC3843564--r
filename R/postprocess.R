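#' Fix the per-TF scaling gauge
#'
#' The decomposition is invariant under scaling any CS column by
#' \eqn{c \neq 0} and the matching TFA row by \eqn{1/c}, so raw fits
#' from different restarts or replicates live in arbitrary gauges. This
#' function fixes the convention: every CS column is rescaled so the
#' root-mean-square of its nonzero entries equals 1, and the TFA row is
#' scaled by the reciprocal. The reconstruction
#' \eqn{CS \cdot \log TFA} is unchanged (to rounding). Under this gauge
#' the |CS| > 1 strong-interaction threshold reads "above the column's
#' typical magnitude".
#'
#' @param result a [DecompositionResult-class].
#' @return the gauge-normalized [DecompositionResult-class].
#' @export
normalizeGauge <- function(result) {
    cs <- result@cs
    lt <- result@logTfa
    for (k in seq_len(ncol(cs))) {
        nz <- cs[, k] != 0
        if (!any(nz))
            stop("gauge error: all-zero CS column '", colnames(cs)[k], "'")
        s <- sqrt(mean(cs[nz, k]^2))
        cs[, k] <- cs[, k] / s
        lt[k, ] <- lt[k, ] * s
    }
    initialize(result, cs = cs, logTfa = lt)
}

#' Correct per-TF sign indeterminacies against documented directions
#'
#' A negative gauge factor inverts the sign of a TF's activity and of
#' all its connectivity strengths simultaneously, so fitted signs are
#' only meaningful after anchoring. Anchors are the documented edges
#' whose regulatory direction is experimentally established
#' (\code{directionKnown} is \code{TRUE}); edges documented with unknown
#' direction never anchor. For each TF, if the majority of its anchors
#' carry a fitted CS sign opposite to the documented sign, the CS column
#' and the TFA row are negated. A TF with no anchors, or an exact tie,
#' is left unflipped and flagged.
#'
#' @param result a gauge-normalized [DecompositionResult-class].
#' @param pattern the [ConnectivityPattern-class] the fit honoured.
#' @return list with components \code{result} (sign-corrected),
#'   \code{flips} (named logical per TF) and \code{flagged} (TF ids with
#'   no usable anchors or a tie).
#' @export
correctSigns <- function(result, pattern) {
    cs <- result@cs
    lt <- result@logTfa
    e <- entries(pattern)
    known <- directionKnown(pattern)
    stopifnot(identical(dim(cs), dim(e)))
    tfs <- colnames(e)
    flips <- setNames(logical(length(tfs)), tfs)
    flagged <- character(0)
    for (k in seq_along(tfs)) {
        anchor <- which(e[, k] != 0 & known[, k])
        if (length(anchor) == 0L) {
            flagged <- c(flagged, tfs[k])
            next
        }
        agree <- sum(sign(cs[anchor, k]) == e[anchor, k])
        disagree <- sum(sign(cs[anchor, k]) == -e[anchor, k])
        if (disagree > agree) {
            cs[, k] <- -cs[, k]
            lt[k, ] <- -lt[k, ]
            flips[k] <- TRUE
        } else if (disagree == agree && disagree > 0L) {
            flagged <- c(flagged, tfs[k])
        }
    }
    list(result = initialize(result, cs = cs, logTfa = lt),
         flips = flips, flagged = flagged)
}

.classLabels <- c("strong-activation", "strong-repression",
                  "weak-activation", "weak-repression", "none",
                  "undetermined")

#' Aggregate decompositions across replicates and restarts
#'
#' Element-wise mean and sample standard deviation of CS and log TFA
#' over a list of gauge-normalized, sign-corrected fits (by default the
#' best-of-restarts fit of each biological replicate), plus the
#' interaction classification. Two criteria define a strong interaction:
#' mean CS above +1 (activation) or below -1 (repression), and low
#' run-to-run variability (coefficient of variation |sd/mean| below
#' \code{cvMax}). Entries passing the magnitude criterion but not the
#' variability one are \code{undetermined}; nonzero entries of magnitude
#' at most 1 are weak; structural zeros are \code{none}.
#'
#' @param results list of [DecompositionResult-class] with identical
#'   dimensions, already gauge-normalized and sign-corrected.
#' @param cvMax variability threshold (default 0.5).
#' @param flips optional list of per-TF flip vectors (one per result, as
#'   returned by [correctSigns()]); the aggregate records the majority.
#' @param flagged character vector of TFs flagged during sign
#'   correction.
#' @return an [AggregateResult-class].
#' @export
aggregateResults <- function(results, cvMax = 0.5, flips = NULL,
                             flagged = character(0)) {
    stopifnot(length(results) >= 1L)
    dims <- dim(results[[1]]@cs)
    for (r in results)
        if (!identical(dim(r@cs), dims) ||
            !identical(dim(r@logTfa), dim(results[[1]]@logTfa)))
            stop("aggregation error: result dimensions differ")
    csList <- lapply(results, slot, "cs")
    tfaList <- lapply(results, slot, "logTfa")
    csMean <- Reduce(`+`, csList) / length(csList)
    tfaMean <- Reduce(`+`, tfaList) / length(tfaList)
    csSd <- matListSd(csList, csMean)
    tfaSd <- matListSd(tfaList, tfaMean)

    cls <- array("none", dim(csMean), dimnames(csMean))
    nz <- csMean != 0
    cv <- array(Inf, dim(csMean))
    cv[nz] <- abs(csSd[nz] / csMean[nz])
    strong <- nz & abs(csMean) > 1 & cv < cvMax
    undet <- nz & abs(csMean) > 1 & cv >= cvMax
    weak <- nz & abs(csMean) <= 1
    cls[strong & csMean > 0] <- "strong-activation"
    cls[strong & csMean < 0] <- "strong-repression"
    cls[weak & csMean > 0] <- "weak-activation"
    cls[weak & csMean < 0] <- "weak-repression"
    cls[undet] <- "undetermined"

    tfs <- colnames(csMean)
    flipsOut <- setNames(logical(length(tfs)), tfs)
    if (!is.null(flips) && length(flips)) {
        fm <- do.call(rbind, flips)
        flipsOut <- colMeans(fm) > 0.5
        names(flipsOut) <- tfs
    }
    new("AggregateResult", csMean = csMean, csSd = csSd,
        tfaMean = tfaMean, tfaSd = tfaSd, flipsApplied = flipsOut,
        flaggedTfs = unique(flagged),
        classification = cls, cvMax = cvMax,
        nRuns = length(results))
}

#' @rdname DecompositionResult-class
#' @export
setMethod("csMatrix", "AggregateResult", function(x) x@csMean)

#' @rdname DecompositionResult-class
#' @export
setMethod("logTfa", "AggregateResult", function(x) x@tfaMean)

setMethod("show", "AggregateResult", function(object) {
    cat(sprintf("AggregateResult over %d run(s): %d genes x %d TFs x %d conditions\n",
                object@nRuns, nrow(object@csMean), ncol(object@csMean),
                ncol(object@tfaMean)))
    tab <- table(factor(object@classification[object@csMean != 0 |
                            object@classification != "none"],
                        levels = .classLabels))
    tab <- tab[tab > 0]
    if (length(tab))
        cat("  interactions:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if (any(object@flipsApplied))
        cat("  sign-flipped TFs:",
            paste(names(which(object@flipsApplied)), collapse = ", "), "\n")
    if (length(object@flaggedTfs))
        cat("  flagged (no anchors/tie):",
            paste(object@flaggedTfs, collapse = ", "), "\n")
})

#' Export an aggregate result as TSV artifacts
#'
#' Writes \code{cs_mean.tsv}, \code{cs_sd.tsv}, \code{tfa_mean.tsv},
#' \code{tfa_sd.tsv}, \code{classification.tsv} and a CS-weighted edge
#' list \code{edges.tsv} (\code{tf, gene, cs_mean, cs_sd, class}) for
#' network viewers.
#'
#' @param agg an [AggregateResult-class].
#' @param dir output directory (created if absent).
#' @export
writeAggregateResult <- function(agg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMatrixTsv(agg@csMean, file.path(dir, "cs_mean.tsv"), "gene")
    writeMatrixTsv(agg@csSd, file.path(dir, "cs_sd.tsv"), "gene")
    writeMatrixTsv(agg@tfaMean, file.path(dir, "tfa_mean.tsv"), "tf")
    writeMatrixTsv(agg@tfaSd, file.path(dir, "tfa_sd.tsv"), "tf")
    writeMatrixTsv(agg@classification, file.path(dir, "classification.tsv"),
                   "gene")
    idx <- which(agg@classification != "none", arr.ind = TRUE)
    idx <- idx[order(colnames(agg@csMean)[idx[, 2]],
                     rownames(agg@csMean)[idx[, 1]]), , drop = FALSE]
    lines <- c("tf\tgene\tcs_mean\tcs_sd\tclass",
               sprintf("%s\t%s\t%.17g\t%.17g\t%s",
                       colnames(agg@csMean)[idx[, 2]],
                       rownames(agg@csMean)[idx[, 1]],
                       agg@csMean[idx], agg@csSd[idx],
                       agg@classification[idx]))
    writeLines(lines, file.path(dir, "edges.tsv"))
    invisible(dir)
}
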