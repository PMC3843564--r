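#' Construct an expression-ratio set
#'
#' @param replicates list of genes-by-conditions matrices of strictly
#'   positive expression ratios relative to a control; all replicates
#'   must share dimnames.
#' @return an [ExpressionRatioSet-class].
#' @examples
#' m <- matrix(10^rnorm(8), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("c1", "c2")))
#' ExpressionRatioSet(list(rep1 = m))
#' @export
ExpressionRatioSet <- function(replicates) {
    stopifnot(is.list(replicates), length(replicates) >= 1L)
    ref <- dimnames(replicates[[1]])
    for (i in seq_along(replicates)) {
        if (!identical(dimnames(replicates[[i]]), ref))
            stop("alignment error: replicate ", i,
                 " labels differ from replicate 1")
    }
    if (is.null(names(replicates)))
        names(replicates) <- paste0("rep", seq_along(replicates))
    new("ExpressionRatioSet",
        SummarizedExperiment::SummarizedExperiment(assays = replicates))
}

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("ratioMatrices", "ExpressionRatioSet", function(x) {
    lapply(SummarizedExperiment::assays(x), function(a) {
        m <- as.matrix(a)
        dimnames(m) <- dimnames(x)
        m
    })
})

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("logRatios", "ExpressionRatioSet",
          function(x) lapply(ratioMatrices(x), log10))

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("nReplicates", "ExpressionRatioSet",
          function(x) length(SummarizedExperiment::assays(x)))

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("meanLogRatios", "ExpressionRatioSet", function(x) {
    l <- logRatios(x)
    Reduce(`+`, l) / length(l)
})

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("conditionIds", "ExpressionRatioSet", function(x) colnames(x))

#' @rdname ExpressionRatioSet-class
#' @export
setMethod("geneIds", "ExpressionRatioSet", function(x) rownames(x))

setMethod("show", "ExpressionRatioSet", function(object) {
    cat(sprintf("ExpressionRatioSet: %d genes x %d conditions, %d replicate(s), log base 10\n",
                nrow(object), ncol(object), nReplicates(object)))
    cat("conditions:", paste(colnames(object), collapse = ", "), "\n")
})

#' Read replicate expression-ratio TSVs
#'
#' Each file is one biological replicate: a genes-by-conditions table of
#' strictly positive expression ratios (header row = condition ids, first
#' column = gene ids). All files must carry identical labels. A ratio of
#' 1.0 corresponds to a log10 value of 0 (no change vs control).
#'
#' @param paths character vector of file paths, one per replicate.
#' @return an [ExpressionRatioSet-class].
#' @export
readExpression <- function(paths) {
    stopifnot(length(paths) >= 1L)
    mats <- lapply(paths, function(p) {
        if (!file.exists(p)) stop("file not found: ", p)
        m <- readMatrixTsv(p)
        bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf(
                "domain error: nonpositive/missing ratio in %s at gene '%s', condition '%s'",
                p, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
        m
    })
    ref <- dimnames(mats[[1]])
    for (i in seq_along(mats))
        if (!identical(dimnames(mats[[i]]), ref))
            stop("alignment error: labels in ", paths[i],
                 " differ from ", paths[1])
    names(mats) <- paste0("rep", seq_along(mats))
    ExpressionRatioSet(mats)
}

#' Write replicate expression-ratio TSVs
#'
#' @param expr an [ExpressionRatioSet-class].
#' @param paths one output path per replicate.
#' @export
writeExpression <- function(expr, paths) {
    mats <- ratioMatrices(expr)
    stopifnot(length(paths) == length(mats))
    for (i in seq_along(mats))
        writeMatrixTsv(mats[[i]], paths[i], rowLabel = "gene")
    invisible(paths)
}

#' Align a connectivity pattern with an expression set
#'
#' Restricts both objects to the genes they share, preserving the
#' pattern's gene order, and reports what was dropped on each side.
#' Genes carrying a missing value in any replicate are not imputed but
#' dropped with a warning: the decomposition has no missing-data
#' mechanism. TFs whose regulon becomes empty after the gene drop are
#' removed (and reported), since an empty-regulon TF is unfittable.
#'
#' @param pattern a [ConnectivityPattern-class].
#' @param expr an [ExpressionRatioSet-class].
#' @return list with components \code{pattern}, \code{expr},
#'   \code{droppedFromPattern}, \code{droppedFromExpression},
#'   \code{droppedTfs}.
#' @export
alignPattern <- function(pattern, expr) {
    common <- intersect(geneIds(pattern), geneIds(expr))
    if (length(common) == 0L)
        stop("alignment error: no genes shared between pattern and expression")
    droppedP <- setdiff(geneIds(pattern), common)
    droppedE <- setdiff(geneIds(expr), common)
    keep <- geneIds(pattern)[geneIds(pattern) %in% common]
    e <- entries(pattern)[keep, , drop = FALSE]
    emptyTfs <- colnames(e)[colSums(e != 0) == 0]
    if (length(emptyTfs))
        warning("TF(s) lost their whole regulon during alignment: ",
                paste(emptyTfs, collapse = ", "))
    pat2 <- subsetPattern(pattern, genes = keep,
                          tfs = setdiff(tfIds(pattern), emptyTfs))
    mats <- lapply(ratioMatrices(expr),
                   function(m) m[keep, , drop = FALSE])
    list(pattern = pat2, expr = ExpressionRatioSet(mats),
         droppedFromPattern = droppedP, droppedFromExpression = droppedE,
         droppedTfs = emptyTfs)
}

#' Construct a TF-expression table
#'
#' @param ratios list of replicate matrices (rows = encoding genes,
#'   columns = conditions) of positive expression ratios.
#' @param tfIds regulator label for each row; defaults to the rownames.
#'   For a composite regulator, repeat its label for each constituent
#'   gene row (e.g. rows \code{AP3} and \code{PI} both labelled
#'   \code{"AP3/PI"}).
#' @return a [TFExpressionTable-class].
#' @export
TFExpressionTable <- function(ratios, tfIds = NULL) {
    stopifnot(is.list(ratios), length(ratios) >= 1L)
    ref <- dimnames(ratios[[1]])
    for (r in ratios)
        if (!identical(dimnames(r), ref))
            stop("alignment error: replicate labels differ")
    if (is.null(tfIds)) tfIds <- ref[[1]]
    new("TFExpressionTable", tfIds = tfIds, geneIds = ref[[1]],
        conditionIds = ref[[2]], replicates = ratios)
}

#' @rdname TFExpressionTable-class
#' @param x a \code{TFExpressionTable}.
#' @export
setMethod("tfIds", "TFExpressionTable", function(x) x@tfIds)

#' @rdname TFExpressionTable-class
#' @export
setMethod("conditionIds", "TFExpressionTable", function(x) x@conditionIds)

# Mean log10 mRNA ratio per encoding gene across replicates.
tfMeanLogExpression <- function(x) {
    l <- lapply(x@replicates, log10)
    m <- Reduce(`+`, l) / length(l)
    dimnames(m) <- list(x@geneIds, x@conditionIds)
    m
}

setMethod("show", "TFExpressionTable", function(object) {
    cat(sprintf("TFExpressionTable: %d encoding gene(s), %d condition(s), %d replicate(s)\n",
                length(object@geneIds), length(object@conditionIds),
                length(object@replicates)))
})
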