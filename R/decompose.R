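#' Decompose log expression into connectivity strengths and TF activities
#'
#' Fits the constrained bilinear model
#' \deqn{\log_{10} G_{m \times n} = CS_{m \times p} \cdot
#'       \log_{10} TFA_{p \times n}}
#' by two-step alternating least squares under the fixed zero pattern of
#' the connectivity matrix: the CS step solves one ordinary
#' least-squares problem per gene restricted to its regulators
#' (\eqn{k_i} unknowns, \eqn{n} equations), the TFA step one per
#' condition (\eqn{p} unknowns, \eqn{m} equations). Each half-step is an
#' exact minimizer, so the squared Frobenius residual is non-increasing
#' throughout. The initial log TFA is drawn uniformly from [-1, 1];
#' \code{nRestarts} independent initializations are fitted and the best
#' final objective is returned, because alternating minimization of a
#' bilinear objective can stall in non-global stationary points.
#'
#' Fewer conditions than TFs (\eqn{n < p}) is permitted — the
#' limited-data regime — provided the pattern passes
#' [checkCompliance()], which bounds each gene's in-degree by \eqn{n};
#' the TFA step stays overdetermined because \eqn{m \gg p}.
#'
#' The raw fit is only defined up to a per-TF scale and sign (see
#' [normalizeGauge()] and [correctSigns()]).
#'
#' @param logG m x n numeric matrix of log10 expression ratios; rownames
#'   must match the pattern's gene ids.
#' @param pattern a compliant [ConnectivityPattern-class].
#' @param seed integer RNG seed.
#' @param maxIter maximum number of full iterations (default 1000).
#' @param tol relative objective-change convergence threshold
#'   (default 1e-9).
#' @param nRestarts number of random restarts (default 10).
#' @param complianceTrials realizations used by the compliance pre-check.
#' @return a [DecompositionResult-class].
#' @examples
#' pat <- generatePattern(m = 12, p = 2, nConditions = 4, seed = 1)
#' truth <- generateTruth(pat, nConditions = 4, seed = 1, noiseSd = 0)
#' lg <- logRatios(simulateReplicates(truth))[[1]]
#' fit <- decompose(lg, pat, seed = 1)
#' objective(fit)   # ~ 0: an exact factorization exists
#' @export
decompose <- function(logG, pattern, seed = 1L, maxIter = 1000L,
                      tol = 1e-9, nRestarts = 10L, complianceTrials = 5L) {
    e <- entries(pattern)
    if (!identical(rownames(logG), rownames(e)))
        stop("alignment error: logG rows must match the pattern's genes")
    rep_ <- checkCompliance(pattern, nConditions = ncol(logG),
                            seed = seed, trials = complianceTrials)
    if (!isCompliant(rep_))
        stop("compliance error: pattern fails NCA-compliance (offending: ",
             paste(c(rep_@offendingTfs, rep_@offendingGenes),
                   collapse = ", "), ")")
    p <- ncol(e)
    n <- ncol(logG)
    inits <- withSeed(seed,
        array(runif(p * n * nRestarts, -1, 1), c(p, n, nRestarts)))
    fit <- tryCatch(
        alsFitCpp(logG, (e != 0) * 1.0, inits, as.integer(maxIter), tol),
        error = function(err) {
            msg <- conditionMessage(err)
            if (grepl("^RANKDEF:", msg)) {
                i <- as.integer(sub("^RANKDEF:", "", msg))
                stop("rank-deficiency error: collinear regulator activities for gene '",
                     rownames(e)[i], "'", call. = FALSE)
            }
            if (grepl("RANKDEFTFA", msg))
                stop("rank-deficiency error: CS matrix lost column rank in TFA step",
                     call. = FALSE)
            stop(err)
        })
    cs <- fit$cs
    dimnames(cs) <- dimnames(e)
    lt <- fit$logTfa
    dimnames(lt) <- list(colnames(e), colnames(logG))
    new("DecompositionResult", cs = cs, logTfa = lt,
        objective = fit$objective, objectiveTrace = fit$trace,
        nIterations = as.integer(fit$iterations),
        converged = fit$converged, seed = as.integer(seed),
        restartIndex = as.integer(fit$restartIndex))
}

#' Fit each biological replicate independently
#'
#' Runs [decompose()] once per replicate matrix; replicate \eqn{r} uses
#' derived seed \code{seed + r} so the whole set is reproducible from
#' one seed while replicates get independent initializations.
#'
#' @param expr an [ExpressionRatioSet-class] aligned to \code{pattern}
#'   (see [alignPattern()]).
#' @param pattern a compliant [ConnectivityPattern-class].
#' @inheritParams decompose
#' @return list of [DecompositionResult-class], one per replicate.
#' @export
decomposeReplicates <- function(expr, pattern, seed = 1L, maxIter = 1000L,
                                tol = 1e-9, nRestarts = 10L) {
    lgs <- logRatios(expr)
    lapply(seq_along(lgs), function(r)
        decompose(lgs[[r]], pattern, seed = seed + r, maxIter = maxIter,
                  tol = tol, nRestarts = nRestarts))
}

#' @rdname DecompositionResult-class
#' @export
setMethod("csMatrix", "DecompositionResult", function(x) x@cs)

#' @rdname DecompositionResult-class
#' @export
setMethod("logTfa", "DecompositionResult", function(x) x@logTfa)

#' @rdname DecompositionResult-class
#' @export
setMethod("objective", "DecompositionResult", function(x) x@objective)

#' @rdname DecompositionResult-class
#' @export
setMethod("converged", "DecompositionResult", function(x) x@converged)

setMethod("show", "DecompositionResult", function(object) {
    cat(sprintf("DecompositionResult: %d genes x %d TFs x %d conditions\n",
                nrow(object@cs), ncol(object@cs), ncol(object@logTfa)))
    cat(sprintf("  objective %.6g after %d iteration(s), converged: %s (restart %d, seed %d)\n",
                object@objective, object@nIterations, object@converged,
                object@restartIndex, object@seed))
})

#' Serialize a decomposition result
#'
#' Writes \code{cs.tsv} (genes x TFs), \code{log_tfa.tsv}
#' (TFs x conditions) and \code{run_metadata.tsv} (key-value) into a
#' directory.
#'
#' @param result a [DecompositionResult-class].
#' @param dir output directory (created if absent).
#' @export
writeDecomposition <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMatrixTsv(result@cs, file.path(dir, "cs.tsv"), "gene")
    writeMatrixTsv(result@logTfa, file.path(dir, "log_tfa.tsv"), "tf")
    writeKeyValue(list(seed = result@seed, objective = result@objective,
                       iterations = result@nIterations,
                       converged = result@converged,
                       restart_index = result@restartIndex),
                  file.path(dir, "run_metadata.tsv"))
    invisible(dir)
}
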