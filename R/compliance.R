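#' Generic (structural) rank of a sign pattern
#'
#' The generic rank of a sparsity/sign pattern is the rank its matrix
#' attains for almost every choice of nonzero values. It is computed
#' numerically: each nonzero entry is replaced by an independent draw
#' from a continuous distribution bounded away from zero
#' (sign \eqn{\times} U(0.5, 1.5)) and the numerical rank of the
#' realization is taken; the maximum over \code{trials} realizations is
#' returned. For the pattern sizes in scope this equals the exact
#' structural rank with probability essentially 1, and is pinned against
#' an exhaustive minor-expansion oracle in the test suite.
#'
#' @param entries numeric matrix whose zero pattern (and signs) define
#'   the structure; values are only inspected for being zero/nonzero.
#' @param trials number of random realizations (default 5).
#' @param seed integer RNG seed; the result is deterministic given it.
#' @return integer generic rank.
#' @examples
#' genericRank(diag(2), seed = 1)   # 2
#' @export
genericRank <- function(entries, trials = 5L, seed = 1L) {
    stopifnot(trials >= 1L)
    if (length(entries) == 0L || nrow(entries) == 0L || ncol(entries) == 0L)
        stop("dimension error: empty matrix has no generic rank")
    nz <- which(entries != 0)
    if (length(nz) == 0L) return(0L)
    withSeed(seed, {
        best <- 0L
        for (t in seq_len(trials)) {
            r <- entries
            r[nz] <- sign(entries[nz]) * runif(length(nz), 0.5, 1.5)
            best <- max(best, qr(r)$rank)
        }
        as.integer(best)
    })
}

#' Test NCA compliance of a connectivity pattern
#'
#' The bilinear decomposition \eqn{\log G = CS \cdot \log TFA} with a
#' fixed zero pattern on \eqn{CS} is unique up to one scale per TF only
#' when the pattern satisfies structural identifiability criteria:
#' \enumerate{
#'   \item the pattern has full generic column rank \eqn{p};
#'   \item for every TF, deleting its column and every gene it regulates
#'     leaves a pattern of generic rank \eqn{p - 1};
#'   \item the data dimension suffices for the original algorithm,
#'     \eqn{n \ge p}.
#' }
#' Criterion 3 frequently fails for small condition sets (e.g. 7 TFs
#' observed over 4 conditions); the fit then runs in limited-data mode,
#' which additionally requires every gene's in-degree to be at most
#' \eqn{n} (each gene's regression sub-problem is determined) and every
#' TF to regulate at least two genes. The overall \code{compliant} flag
#' is criteria 1 and 2 plus the limited-data conditions; criterion 3 is
#' reported for information.
#'
#' @param pattern a [ConnectivityPattern-class].
#' @param nConditions number of expression conditions \eqn{n}.
#' @param seed RNG seed for the generic-rank realizations.
#' @param trials realizations per rank evaluation.
#' @return a [ComplianceReport-class]; always returned, never an error.
#' @export
checkCompliance <- function(pattern, nConditions, seed = 1L, trials = 5L) {
    e <- entries(pattern)
    p <- ncol(e)
    tfs <- colnames(e)
    r1 <- genericRank(e, trials = trials, seed = seed)
    c1 <- r1 == p
    r2 <- integer(0)
    c2 <- logical(0)
    if (p > 1L) {
        r2 <- vapply(seq_len(p), function(l) {
            keepGenes <- e[, l] == 0
            sub <- e[keepGenes, -l, drop = FALSE]
            if (nrow(sub) == 0L || all(sub == 0)) return(0L)
            genericRank(sub, trials = trials, seed = seed + l)
        }, integer(1))
        c2 <- r2 == p - 1L
    } else {
        r2 <- 0L
        c2 <- TRUE          # p = 1: reduced pattern must have rank 0
    }
    names(c2) <- tfs
    names(r2) <- tfs
    c3 <- nConditions >= p
    indeg <- as.integer(rowSums(e != 0))
    names(indeg) <- rownames(e)
    reg <- as.integer(colSums(e != 0))
    names(reg) <- tfs
    limOk <- all(indeg <= nConditions) && all(reg >= 2L)
    offTfs <- sort(unique(c(tfs[!c2], tfs[reg < 2L])))
    if (!c1) offTfs <- sort(unique(c(offTfs, tfs)))
    offGenes <- sort(names(indeg)[indeg > nConditions])
    new("ComplianceReport",
        criterion1Ok = c1, rank1 = r1, criterion2Ok = c2, rank2 = r2,
        criterion3Ok = c3, limitedDataOk = limOk, inDegree = indeg,
        regulonSize = reg, offendingTfs = offTfs, offendingGenes = offGenes,
        nConditions = as.integer(nConditions),
        compliant = c1 && all(c2) && limOk)
}

#' @rdname ComplianceReport-class
#' @export
setMethod("isCompliant", "ComplianceReport", function(x) x@compliant)

setMethod("show", "ComplianceReport", function(object) {
    cat("ComplianceReport\n")
    cat(sprintf("  criterion 1 (full generic column rank): %s (rank %d)\n",
                object@criterion1Ok, object@rank1))
    cat(sprintf("  criterion 2 (reduced-rank per TF):      %s\n",
                all(object@criterion2Ok)))
    cat(sprintf("  criterion 3 (n >= p):                   %s%s\n",
                object@criterion3Ok,
                if (!object@criterion3Ok) "  [limited-data mode]" else ""))
    cat(sprintf("  limited-data conditions:                %s\n",
                object@limitedDataOk))
    cat(sprintf("  compliant: %s\n", object@compliant))
    if (length(object@offendingTfs))
        cat("  offending TFs:", paste(object@offendingTfs, collapse = ", "), "\n")
    if (length(object@offendingGenes))
        cat("  offending genes:", paste(object@offendingGenes, collapse = ", "), "\n")
})

#' Serialize a compliance report
#'
#' Writes a machine-readable key-value file (one \code{key<TAB>value}
#' line per field).
#'
#' @param report a [ComplianceReport-class].
#' @param path output path.
#' @export
writeComplianceReport <- function(report, path) {
    writeKeyValue(list(
        criterion1_ok = report@criterion1Ok,
        rank1 = report@rank1,
        criterion2_ok = paste0(names(report@criterion2Ok), "=",
                               report@criterion2Ok),
        criterion3_ok = report@criterion3Ok,
        limited_data_ok = report@limitedDataOk,
        compliant = report@compliant,
        n_conditions = report@nConditions,
        offending_tfs = if (length(report@offendingTfs))
            report@offendingTfs else "-",
        offending_genes = if (length(report@offendingGenes))
            report@offendingGenes else "-"), path)
}
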