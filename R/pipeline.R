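#' Build a pipeline run configuration
#'
#' All stages of the staged pipeline ([runCheck()], [runPrune()],
#' [runFit()], [runEvaluate()], [runSimulate()]) consume one declarative
#' configuration. The seed is mandatory — no stage ever falls back to
#' wall-clock randomness — and every parameter is echoed into the output
#' manifest so a run is reproducible from its artifacts alone.
#'
#' @param connectivity path to the connectivity input.
#' @param expression character vector of replicate expression TSV paths.
#' @param seed integer RNG seed (mandatory).
#' @param outDir output directory for stage artifacts.
#' @param connectivityFormat \code{"matrix-tsv"} or \code{"sif-edges"}.
#' @param tfExpression optional path to a TF-mRNA table (long TSV with
#'   columns \code{tf}, \code{gene}, \code{replicate}, then one column
#'   per condition).
#' @param tfEncodingGenes named character mapping TF id to encoding gene
#'   id (used by the pruner).
#' @param maxIter,tol,nRestarts solver settings (see [decompose()]).
#' @param cvMax variability threshold for classification.
#' @param alpha significance cutoff for pairwise tests.
#' @return a [RunConfig-class].
#' @export
ncaConfig <- function(connectivity = NA_character_,
                      expression = character(0), seed, outDir = ".",
                      connectivityFormat = c("matrix-tsv", "sif-edges"),
                      tfExpression = NA_character_,
                      tfEncodingGenes = character(0), maxIter = 1000L,
                      tol = 1e-9, nRestarts = 10L, cvMax = 0.5,
                      alpha = 0.05) {
    new("RunConfig", connectivity = connectivity,
        connectivityFormat = match.arg(connectivityFormat),
        expression = expression, tfExpression = tfExpression,
        tfEncodingGenes = tfEncodingGenes, seed = as.integer(seed),
        maxIter = as.integer(maxIter), tol = tol,
        nRestarts = as.integer(nRestarts), cvMax = cvMax, alpha = alpha,
        outDir = outDir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Field names mirror the [ncaConfig()] arguments;
#' \code{tf_encoding_genes} may be a mapping of TF id to gene id.
#'
#' @param path YAML file path.
#' @return a [RunConfig-class].
#' @export
readNcaConfig <- function(path) {
    y <- yaml::read_yaml(path)
    enc <- character(0)
    if (!is.null(y$tf_encoding_genes))
        enc <- unlist(y$tf_encoding_genes)
    ncaConfig(connectivity = y$connectivity %||% NA_character_,
              expression = as.character(y$expression %||% character(0)),
              seed = y$seed,
              outDir = y$out_dir %||% ".",
              connectivityFormat = y$connectivity_format %||% "matrix-tsv",
              tfExpression = y$tf_expression %||% NA_character_,
              tfEncodingGenes = enc,
              maxIter = y$max_iter %||% 1000L,
              tol = y$tol %||% 1e-9,
              nRestarts = y$n_restarts %||% 10L,
              cvMax = y$cv_max %||% 0.5,
              alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig\n")
    cat("  connectivity:", object@connectivity,
        sprintf("(%s)\n", object@connectivityFormat))
    cat("  expression:", length(object@expression), "replicate file(s)\n")
    cat(sprintf("  seed %d, maxIter %d, tol %g, nRestarts %d, cvMax %g, alpha %g\n",
                object@seed, object@maxIter, object@tol, object@nRestarts,
                object@cvMax, object@alpha))
    cat("  outDir:", object@outDir, "\n")
})

loadInputs <- function(config) {
    if (is.na(config@connectivity) || !file.exists(config@connectivity))
        stop("configuration error: connectivity input missing")
    if (length(config@expression) == 0L ||
        !all(file.exists(config@expression)))
        stop("configuration error: expression input(s) missing")
    pat <- readConnectivity(config@connectivity, config@connectivityFormat)
    expr <- readExpression(config@expression)
    al <- alignPattern(pat, expr)
    al
}

writeManifest <- function(config, stage, outputs) {
    inputs <- c(config@connectivity, config@expression)
    inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
    sums <- tools::md5sum(c(inputs, outputs))
    writeKeyValue(c(
        list(stage = stage,
             package_version = as.character(utils::packageVersion("ncatools")),
             seed = config@seed, max_iter = config@maxIter,
             tol = config@tol, n_restarts = config@nRestarts,
             cv_max = config@cvMax, alpha = config@alpha),
        setNames(as.list(unname(sums)),
                 paste0("md5:", basename(names(sums))))),
        file.path(config@outDir, paste0("manifest_", stage, ".tsv")))
}

#' Pipeline stage: compliance check
#'
#' Reads and aligns the inputs, runs [checkCompliance()] against the
#' number of observed conditions, and writes
#' \code{compliance_report.tsv} plus a stage manifest.
#'
#' @param config a [RunConfig-class].
#' @return the [ComplianceReport-class], invisibly the artifacts too.
#' @export
runCheck <- function(config) {
    al <- loadInputs(config)
    rep_ <- checkCompliance(al$pattern, ncol(al$expr), seed = config@seed)
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(config@outDir, "compliance_report.tsv")
    writeComplianceReport(rep_, out)
    writeManifest(config, "check", out)
    rep_
}

#' Pipeline stage: prune to compliance
#'
#' Reads and aligns the inputs, runs [pruneToCompliance()], and writes
#' the pruned pattern (\code{pattern_pruned.tsv} + direction-known
#' companion), the removal trace (\code{prune_trace.tsv}) and a stage
#' manifest.
#'
#' @param config a [RunConfig-class].
#' @return list with components \code{pattern} and \code{trace}.
#' @export
runPrune <- function(config) {
    al <- loadInputs(config)
    pr <- pruneToCompliance(al$pattern, ncol(al$expr),
                            tfEncodingGenes = config@tfEncodingGenes,
                            seed = config@seed)
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    pout <- file.path(config@outDir, "pattern_pruned.tsv")
    writeConnectivity(pr$pattern, pout, "matrix-tsv")
    tout <- file.path(config@outDir, "prune_trace.tsv")
    writePruneTrace(pr$trace, tout)
    writeManifest(config, "prune", c(pout, paste0(pout, ".known.tsv"), tout))
    pr
}

# Shared fit steps: check -> prune -> per-replicate decompose ->
# gauge -> sign correction -> aggregate. Returns everything downstream
# stages need.
fitPipeline <- function(config) {
    al <- loadInputs(config)
    pr <- pruneToCompliance(al$pattern, ncol(al$expr),
                            tfEncodingGenes = config@tfEncodingGenes,
                            seed = config@seed)
    keep <- geneIds(pr$pattern)
    mats <- lapply(ratioMatrices(al$expr),
                   function(m) m[keep, , drop = FALSE])
    expr <- ExpressionRatioSet(mats)
    fits <- decomposeReplicates(expr, pr$pattern, seed = config@seed,
                                maxIter = config@maxIter, tol = config@tol,
                                nRestarts = config@nRestarts)
    corrected <- lapply(fits, function(f)
        correctSigns(normalizeGauge(f), pr$pattern))
    results <- lapply(corrected, `[[`, "result")
    flips <- lapply(corrected, `[[`, "flips")
    flagged <- unique(unlist(lapply(corrected, `[[`, "flagged")))
    agg <- aggregateResults(results, cvMax = config@cvMax, flips = flips,
                            flagged = as.character(flagged))
    list(align = al, prune = pr, expr = expr, results = results,
         agg = agg)
}

#' Pipeline stage: full fit
#'
#' Runs check, prune, per-replicate decomposition (best of
#' \code{nRestarts}), gauge normalization, sign correction and
#' aggregation, then writes the aggregate artifacts (see
#' [writeAggregateResult()]), the prune trace, and a stage manifest.
#'
#' @param config a [RunConfig-class].
#' @return the [AggregateResult-class].
#' @export
runFit <- function(config) {
    st <- fitPipeline(config)
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    writeAggregateResult(st$agg, config@outDir)
    writePruneTrace(st$prune$trace,
                    file.path(config@outDir, "prune_trace.tsv"))
    outs <- file.path(config@outDir,
                      c("cs_mean.tsv", "cs_sd.tsv", "tfa_mean.tsv",
                        "tfa_sd.tsv", "classification.tsv", "edges.tsv",
                        "prune_trace.tsv"))
    writeManifest(config, "fit", outs)
    st$agg
}

#' Pipeline stage: evaluation
#'
#' Re-runs the fit steps deterministically from the configuration, then
#' computes the evaluation statistics ([evaluateModel()]) and writes the
#' report artifacts plus a stage manifest.
#'
#' @param config a [RunConfig-class].
#' @return the [EvaluationReport-class].
#' @export
runEvaluate <- function(config) {
    st <- fitPipeline(config)
    tfExpr <- NULL
    if (!is.na(config@tfExpression)) {
        if (!file.exists(config@tfExpression))
            stop("configuration error: tfExpression input missing")
        tfExpr <- readTfExpression(config@tfExpression)
    }
    rep_ <- evaluateModel(st$agg, st$expr, results = st$results,
                          tfExpr = tfExpr, alpha = config@alpha)
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    writeEvaluationReport(rep_, config@outDir)
    outs <- file.path(config@outDir, c("scatter.tsv", "evaluation.tsv"))
    writeManifest(config, "evaluate", outs)
    rep_
}

#' Pipeline stage: simulate a synthetic study
#'
#' Materializes a reproducible synthetic study (see [makeDataset()])
#' under the configured output directory using the configured seed.
#'
#' @param config a [RunConfig-class]; only \code{seed} and
#'   \code{outDir} are consulted.
#' @param ... passed through to [makeDataset()] (dimensions, noise).
#' @return invisibly, the [makeDataset()] value.
#' @export
runSimulate <- function(config, ...) {
    makeDataset(config@outDir, seed = config@seed, ...)
}

#' Read a TF-mRNA expression table
#'
#' Long TSV with columns \code{tf}, \code{gene}, \code{replicate}, then
#' one column per condition holding positive expression ratios; one row
#' per encoding gene and replicate.
#'
#' @param path TSV path.
#' @return a [TFExpressionTable-class].
#' @export
readTfExpression <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(all(c("tf", "gene", "replicate") %in% names(df)))
    conds <- setdiff(names(df), c("tf", "gene", "replicate"))
    reps <- sort(unique(df$replicate))
    genes <- unique(df$gene)
    tfs <- df$tf[match(genes, df$gene)]
    mats <- lapply(reps, function(r) {
        sub <- df[df$replicate == r, ]
        m <- as.matrix(sub[match(genes, sub$gene), conds, drop = FALSE])
        rownames(m) <- genes
        storage.mode(m) <- "double"
        m
    })
    TFExpressionTable(mats, tfIds = tfs)
}

#' Write a TF-mRNA expression table
#'
#' @param tfExpr a [TFExpressionTable-class].
#' @param path output TSV path.
#' @export
writeTfExpression <- function(tfExpr, path) {
    lines <- paste(c("tf", "gene", "replicate", tfExpr@conditionIds),
                   collapse = "\t")
    for (r in seq_along(tfExpr@replicates)) {
        m <- tfExpr@replicates[[r]]
        lines <- c(lines, vapply(seq_len(nrow(m)), function(i)
            paste(c(tfExpr@tfIds[i], tfExpr@geneIds[i], r,
                    sprintf("%.17g", m[i, ])), collapse = "\t"),
            character(1)))
    }
    writeLines(lines, path)
    invisible(path)
}
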