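# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

# Full-precision, locale-independent TSV writer for labelled matrices.
# %.17g round-trips doubles exactly, so reruns are bit-identical.
writeMatrixTsv <- function(m, path, rowLabel = "id") {
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    fmt <- if (is.numeric(m)) function(v) sprintf("%.17g", v) else identity
    lines <- c(paste(c(rowLabel, colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

readMatrixTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
}

writeKeyValue <- function(x, path) {
    vals <- vapply(x, function(v) {
        if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
        else paste(as.character(v), collapse = ",")
    }, character(1))
    writeLines(paste(names(x), vals, sep = "\t"), path)
    invisible(path)
}

# Sample standard deviation column-wise over a list of equal-shape
# matrices; returns 0 (not NA) for a single run.
matListSd <- function(mats, means) {
    k <- length(mats)
    if (k == 1L) return(array(0, dim(means), dimnames = dimnames(means)))
    ss <- Reduce(`+`, lapply(mats, function(m) (m - means)^2))
    out <- sqrt(ss / (k - 1L))
    dimnames(out) <- dimnames(means)
    out
}
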