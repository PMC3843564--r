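#' @import methods
#' @importFrom stats rnorm runif rgamma sd var cor t.test
#' @importFrom utils read.delim write.table
NULL

#' Signed ternary TF-to-gene connectivity pattern
#'
#' The documented network prior: an \eqn{m \times p} matrix over
#' \{-1, 0, +1\} whose rows are target genes and whose columns are
#' transcription factors (TFs). An entry of +1 encodes a documented
#' activation, -1 a documented repression and 0 no documented interaction.
#' Documented edges whose regulatory direction is unknown are encoded +1
#' and flagged in \code{directionKnown} so that downstream sign correction
#' never anchors on them.
#'
#' @slot entries numeric matrix over \{-1, 0, 1\}, genes in rows (with
#'   rownames), TFs in columns (with colnames).
#' @slot directionKnown logical matrix of the same shape; \code{FALSE}
#'   marks a documented edge whose direction is not experimentally
#'   established (such entries must be 0 or +1).
#'
#' @section Invariants:
#' No duplicated gene or TF labels; every TF column has at least one
#' nonzero entry (a TF with an empty regulon is rejected at construction).
#'
#' @seealso [ConnectivityPattern()], [readConnectivity()], [checkCompliance()]
#' @export
setClass("ConnectivityPattern",
    representation(entries = "matrix", directionKnown = "matrix"))

setValidity("ConnectivityPattern", function(object) {
    e <- object@entries
    d <- object@directionKnown
    msg <- character()
    if (!is.numeric(e)) msg <- c(msg, "'entries' must be numeric")
    if (!is.logical(d)) msg <- c(msg, "'directionKnown' must be logical")
    if (!identical(dim(e), dim(d)))
        msg <- c(msg, "'entries' and 'directionKnown' must have equal dim")
    if (is.null(rownames(e)) || is.null(colnames(e)))
        msg <- c(msg, "'entries' must carry gene rownames and TF colnames")
    if (length(msg)) return(msg)
    if (anyDuplicated(rownames(e)))
        msg <- c(msg, "duplicated gene labels")
    if (anyDuplicated(colnames(e)))
        msg <- c(msg, "duplicated TF labels")
    if (!all(e %in% c(-1, 0, 1)))
        msg <- c(msg, "entries must lie in {-1, 0, 1}")
    if (any(!d & !(e %in% c(0, 1))))
        msg <- c(msg, "directionKnown == FALSE requires entry in {0, +1}")
    empty <- colnames(e)[colSums(e != 0) == 0]
    if (length(empty))
        msg <- c(msg, paste0("TF(s) with empty regulon: ",
                             paste(empty, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Replicate-wise positive expression-ratio matrices
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assays are the
#' biological replicates: each assay is a genes-by-conditions matrix of
#' strictly positive expression ratios relative to a control condition.
#' The log view used throughout the decomposition is base 10 and is not
#' configurable.
#'
#' @seealso [ExpressionRatioSet()], [logRatios()], [readExpression()]
#' @export
#' @import SummarizedExperiment
setClass("ExpressionRatioSet", contains = "SummarizedExperiment")

setValidity("ExpressionRatioSet", function(object) {
    a <- SummarizedExperiment::assays(object)
    msg <- character()
    if (length(a) < 1L) msg <- c(msg, "at least one replicate assay required")
    if (ncol(object) < 2L) msg <- c(msg, "at least two conditions required")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene rownames and condition colnames required")
    for (i in seq_along(a)) {
        v <- a[[i]]
        if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
            msg <- c(msg, sprintf(
                "replicate %d contains nonpositive or missing ratios", i))
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Expression ratios of the genes encoding the TFs
#'
#' Per-TF, per-condition, per-replicate positive expression ratios of the
#' genes that encode the transcription factors, used to compare inferred
#' TF activities with TF mRNA levels. A composite regulator (e.g. a
#' heterodimer labelled \code{"AP3/PI"}) is represented by one row per
#' constituent gene.
#'
#' @slot tfIds character; regulator label each row series belongs to.
#' @slot geneIds character; the encoding gene measured (equals
#'   \code{tfIds} except for composite regulators).
#' @slot conditionIds character; condition labels.
#' @slot replicates list of (length(tfIds) x length(conditionIds))
#'   positive matrices, one per biological replicate.
#' @export
setClass("TFExpressionTable",
    representation(tfIds = "character", geneIds = "character",
                   conditionIds = "character", replicates = "list"))

setValidity("TFExpressionTable", function(object) {
    msg <- character()
    if (length(object@geneIds) != length(object@tfIds))
        msg <- c(msg, "tfIds and geneIds must have equal length")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "duplicated encoding-gene labels")
    for (r in object@replicates) {
        if (!is.matrix(r) ||
            !identical(dim(r), c(length(object@tfIds),
                                 length(object@conditionIds))))
            msg <- c(msg, "replicate matrices must be p x n")
        else if (any(!is.finite(r)) || any(r <= 0))
            msg <- c(msg, "ratios must be strictly positive")
    }
    if (length(msg)) unique(msg) else TRUE
})

#' Structural identifiability diagnostics for a connectivity pattern
#'
#' Produced by [checkCompliance()]. The decomposition of log expression
#' into CS and log TFA is unique up to per-TF scaling only when the
#' pattern satisfies the NCA-compliance rank criteria; this report
#' records each criterion, generic ranks, and the offending labels.
#'
#' @slot criterion1Ok logical; generic column rank of the pattern equals p.
#' @slot rank1 integer; that generic rank.
#' @slot criterion2Ok named logical per TF; after deleting a TF's column
#'   and every gene it regulates, the reduced pattern keeps generic rank
#'   p - 1.
#' @slot rank2 named integer; the reduced-pattern generic ranks.
#' @slot criterion3Ok logical; data-dimension sufficiency of the original
#'   algorithm, n >= p. When \code{FALSE} the fit runs in limited-data
#'   mode.
#' @slot limitedDataOk logical; every gene's in-degree is at most n and
#'   every TF regulates at least two genes.
#' @slot inDegree,regulonSize named integer diagnostics.
#' @slot offendingTfs,offendingGenes labels violating a criterion.
#' @slot nConditions integer n used for the check.
#' @slot compliant logical; criteria 1 and 2 plus the limited-data
#'   conditions all hold.
#' @export
setClass("ComplianceReport",
    representation(criterion1Ok = "logical", rank1 = "integer",
                   criterion2Ok = "logical", rank2 = "integer",
                   criterion3Ok = "logical", limitedDataOk = "logical",
                   inDegree = "integer", regulonSize = "integer",
                   offendingTfs = "character", offendingGenes = "character",
                   nConditions = "integer", compliant = "logical"))

#' Ordered record of removals performed by the pruner
#'
#' Each action removes one TF or one gene with one reason drawn from
#' \code{tf-encoding-gene}, \code{in-degree-exceeds-conditions},
#' \code{regulon-too-small}, \code{rank-deficiency},
#' \code{orphaned-gene}. Replaying the actions on the initial pattern
#' reproduces the pruned pattern exactly (see [replayTrace()]).
#'
#' @slot actions data.frame with columns kind ("tf-removed"/"gene-removed"),
#'   label, reason.
#' @slot initialDims,finalDims integer c(m, p) before and after pruning.
#' @export
setClass("PruneTrace",
    representation(actions = "data.frame", initialDims = "integer",
                   finalDims = "integer"))

#' One fitted NCA decomposition
#'
#' Result of [decompose()] on a single replicate's log10 expression
#' matrix: fitted connectivity strengths honouring the zero pattern and
#' log10 TF activities, with convergence metadata. The raw fit is only
#' defined up to a per-TF scale and sign; see [normalizeGauge()] and
#' [correctSigns()].
#'
#' @slot cs m x p numeric; exactly zero wherever the pattern is zero.
#' @slot logTfa p x n numeric; log10 fold activity relative to control.
#' @slot objective final squared Frobenius residual.
#' @slot objectiveTrace objective after every half-step (CS step, TFA
#'   step, ...); non-increasing by construction.
#' @slot nIterations,converged,seed,restartIndex run metadata;
#'   \code{restartIndex} is the 1-based index of the winning restart.
#' @export
setClass("DecompositionResult",
    representation(cs = "matrix", logTfa = "matrix", objective = "numeric",
                   objectiveTrace = "numeric", nIterations = "integer",
                   converged = "logical", seed = "integer",
                   restartIndex = "integer"))

setValidity("DecompositionResult", function(object) {
    msg <- character()
    if (ncol(object@cs) != nrow(object@logTfa))
        msg <- c(msg, "cs and logTfa are not conformable")
    if (length(object@objective) != 1L || object@objective < 0)
        msg <- c(msg, "objective must be a single nonnegative number")
    if (is.unsorted(rev(object@objectiveTrace), strict = FALSE) &&
        any(diff(object@objectiveTrace) > 1e-8 * (1 + object@objectiveTrace[1L])))
        msg <- c(msg, "objective trace must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Replicate/restart aggregate of corrected decompositions
#'
#' Element-wise mean and sample standard deviation of CS and log TFA over
#' gauge-normalized, sign-corrected decompositions, plus the
#' strong/weak interaction classification: an interaction is strong when
#' |mean CS| > 1 and its coefficient of variation across runs stays below
#' \code{cvMax}; nonzero entries failing only the variability criterion
#' are \code{undetermined}; |mean CS| <= 1 entries are weak.
#'
#' @slot csMean,csSd m x p numeric matrices.
#' @slot tfaMean,tfaSd p x n numeric matrices.
#' @slot flipsApplied named logical per TF; whether the sign gauge was
#'   flipped by [correctSigns()] in the majority of runs.
#' @slot flaggedTfs TFs with no usable sign anchors (or an exact tie).
#' @slot classification m x p character matrix over
#'   \{strong-activation, strong-repression, weak-activation,
#'   weak-repression, none, undetermined\}.
#' @slot cvMax numeric; variability threshold used.
#' @slot nRuns integer; number of pooled runs.
#' @export
setClass("AggregateResult",
    representation(csMean = "matrix", csSd = "matrix", tfaMean = "matrix",
                   tfaSd = "matrix", flipsApplied = "logical",
                   flaggedTfs = "character", classification = "matrix",
                   cvMax = "numeric", nRuns = "integer"))

#' Model-evaluation statistics
#'
#' Holds the pooled reconstruction R-squared between measured and
#' NCA-simulated log expression, min-max-normalized TF-activity /
#' TF-mRNA parity series with their Pearson correlations, and
#' Welch-test p-values for every unordered condition pair per TF.
#'
#' @slot rSquared numeric in (-Inf, 1].
#' @slot parity list, one element per TF/constituent-gene comparison with
#'   components tf, gene, tfa (normalized), mrna (normalized),
#'   correlation, degenerateTfa, degenerateMrna.
#' @slot pairwiseTests data.frame: tf, conditionA, conditionB, statistic,
#'   df, p, significant.
#' @slot alpha numeric significance cutoff (strict inequality).
#' @slot scatter data.frame of (measured, simulated) pairs pooled over
#'   genes and conditions.
#' @slot notes character; methodological flags (pooling convention,
#'   degenerate series).
#' @export
setClass("EvaluationReport",
    representation(rSquared = "numeric", parity = "list",
                   pairwiseTests = "data.frame", alpha = "numeric",
                   scatter = "data.frame", notes = "character"))

#' Ground truth for a synthetic NCA study
#'
#' A compliant connectivity pattern together with the gauge-normalized
#' true connectivity strengths, true log10 TF activities, and the
#' log-normal measurement-noise model used to simulate replicate
#' expression.
#'
#' @slot pattern [ConnectivityPattern-class].
#' @slot csTrue m x p numeric; signs agree with the pattern, each
#'   column's nonzero entries have root-mean-square 1.
#' @slot logTfaTrue p x n numeric, log10 fold vs control.
#' @slot noiseSd numeric; additive Gaussian sd in log10 units
#'   (multiplicative log-normal on ratios).
#' @slot nReplicates,seed integer metadata.
#' @export
setClass("SyntheticTruth",
    representation(pattern = "ConnectivityPattern", csTrue = "matrix",
                   logTfaTrue = "matrix", noiseSd = "numeric",
                   nReplicates = "integer", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    e <- entries(object@pattern)
    if (!identical(dim(e), dim(object@csTrue)))
        msg <- c(msg, "csTrue shape must match the pattern")
    else {
        nz <- e != 0
        if (any(sign(object@csTrue[nz]) != e[nz]))
            msg <- c(msg, "sign(csTrue) must equal the pattern where nonzero")
        if (any(object@csTrue[!nz] != 0))
            msg <- c(msg, "csTrue must be zero where the pattern is zero")
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Declarative configuration for the staged pipeline
#'
#' All inputs and tunables for [runCheck()], [runPrune()], [runFit()],
#' [runEvaluate()] and [runSimulate()]. The seed is mandatory: no stage
#' ever falls back to wall-clock randomness.
#'
#' @slot connectivity path to the connectivity input (matrix TSV or SIF).
#' @slot connectivityFormat "matrix-tsv" or "sif-edges".
#' @slot expression character vector of replicate expression TSV paths.
#' @slot tfExpression optional path to a TF-mRNA expression TSV
#'   (long format), or NA.
#' @slot tfEncodingGenes named character; maps a TF id to the gene id
#'   encoding it, used by the pruner.
#' @slot seed,maxIter,nRestarts integers; tol, cvMax, alpha numerics.
#' @slot outDir output directory for stage artifacts.
#' @export
setClass("RunConfig",
    representation(connectivity = "character", connectivityFormat = "character",
                   expression = "character", tfExpression = "character",
                   tfEncodingGenes = "character", seed = "integer",
                   maxIter = "integer", tol = "numeric",
                   nRestarts = "integer", cvMax = "numeric",
                   alpha = "numeric", outDir = "character"))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
    if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
    if (object@nRestarts < 1L) msg <- c(msg, "nRestarts must be >= 1")
    if (object@cvMax <= 0) msg <- c(msg, "cvMax must be > 0")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})
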