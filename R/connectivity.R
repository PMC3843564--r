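#' Construct a connectivity pattern
#'
#' @param entries numeric matrix over \{-1, 0, 1\} with gene rownames and
#'   TF colnames (genes in rows, TFs in columns).
#' @param directionKnown logical matrix of the same shape, or \code{NULL}
#'   to mark every documented edge as direction-known.
#' @return a [ConnectivityPattern-class].
#' @examples
#' e <- matrix(c(1, -1, 0, 0, 0, 1, 1, 0), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("TFa", "TFb")))
#' ConnectivityPattern(e)
#' @export
ConnectivityPattern <- function(entries, directionKnown = NULL) {
    storage.mode(entries) <- "double"
    if (is.null(directionKnown)) {
        directionKnown <- array(TRUE, dim(entries), dimnames(entries))
    }
    dimnames(directionKnown) <- dimnames(entries)
    bad <- entries[!(entries %in% c(-1, 0, 1))]
    if (length(bad))
        stop("encoding error: entries outside {-1, 0, 1}: ",
             paste(unique(bad), collapse = ", "))
    empty <- colnames(entries)[colSums(entries != 0) == 0]
    if (length(empty))
        stop("empty-regulon error: TF(s) with no targets: ",
             paste(empty, collapse = ", "))
    new("ConnectivityPattern", entries = entries,
        directionKnown = directionKnown)
}

#' @rdname ConnectivityPattern-class
#' @export
setMethod("tfIds", "ConnectivityPattern", function(x) colnames(x@entries))

#' @rdname ConnectivityPattern-class
#' @export
setMethod("geneIds", "ConnectivityPattern", function(x) rownames(x@entries))

#' @rdname ConnectivityPattern-class
#' @export
setMethod("entries", "ConnectivityPattern", function(x) x@entries)

#' @rdname ConnectivityPattern-class
#' @export
setMethod("directionKnown", "ConnectivityPattern",
          function(x) x@directionKnown)

#' @rdname ConnectivityPattern-class
#' @export
setMethod("regulonSizes", "ConnectivityPattern",
          function(x) colSums(x@entries != 0))

#' @rdname ConnectivityPattern-class
#' @export
setMethod("inDegrees", "ConnectivityPattern",
          function(x) rowSums(x@entries != 0))

#' @rdname ConnectivityPattern-class
#' @export
setMethod("dim", "ConnectivityPattern", function(x) dim(x@entries))

setMethod("show", "ConnectivityPattern", function(object) {
    d <- dim(object)
    cat(sprintf("ConnectivityPattern: %d genes x %d TFs, %d edges (%d repressing, %d unknown-direction)\n",
                d[1], d[2], sum(object@entries != 0),
                sum(object@entries == -1),
                sum(object@entries != 0 & !object@directionKnown)))
    cat("TFs:", paste(tfIds(object), collapse = ", "), "\n")
})

# Restrict a pattern to subsets of genes/TFs, keeping label order.
subsetPattern <- function(pattern, genes = geneIds(pattern),
                          tfs = tfIds(pattern)) {
    ConnectivityPattern(
        pattern@entries[genes, tfs, drop = FALSE],
        pattern@directionKnown[genes, tfs, drop = FALSE])
}

.sifRelations <- c(activates = 1, represses = -1, regulates = 1)

#' Read or write a connectivity pattern
#'
#' Two plain-text serializations are supported. \code{matrix-tsv} is a
#' genes-by-TFs table of \{-1, 0, 1\} entries (header row = TF ids, first
#' column = gene ids), optionally accompanied by a companion file
#' \code{<path>.known.tsv} of \{0, 1\} flags for \code{directionKnown}.
#' \code{sif-edges} is a three-column tab-separated edge list
#' \code{tf <TAB> relation <TAB> gene} with relation one of
#' \code{activates}, \code{represses}, \code{regulates}; a
#' \code{regulates} edge encodes a documented interaction of unknown
#' direction and maps to entry +1 with \code{directionKnown = FALSE}.
#'
#' @param path file to read or write.
#' @param format \code{"matrix-tsv"} or \code{"sif-edges"}.
#' @return \code{readConnectivity} returns a [ConnectivityPattern-class];
#'   \code{writeConnectivity} returns \code{path} invisibly.
#' @export
readConnectivity <- function(path, format = c("matrix-tsv", "sif-edges")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "matrix-tsv") {
        m <- readMatrixTsv(path)
        if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
            stop("label error: duplicated gene or TF labels in ", path)
        known <- NULL
        kpath <- paste0(path, ".known.tsv")
        if (file.exists(kpath)) {
            k <- readMatrixTsv(kpath)
            if (!identical(dimnames(k), dimnames(m)))
                stop("label error: direction-known companion labels differ")
            known <- k != 0
        }
        return(ConnectivityPattern(m, known))
    }
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("tf", "relation", "gene"))
    if (!all(df$relation %in% names(.sifRelations)))
        stop("encoding error: unknown relation(s): ",
             paste(setdiff(df$relation, names(.sifRelations)), collapse = ", "))
    if (anyDuplicated(df[c("tf", "gene")]))
        stop("label error: duplicated tf-gene edge in ", path)
    genes <- unique(df$gene)
    tfs <- unique(df$tf)
    e <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
    k <- matrix(TRUE, length(genes), length(tfs), dimnames = list(genes, tfs))
    idx <- cbind(match(df$gene, genes), match(df$tf, tfs))
    e[idx] <- .sifRelations[df$relation]
    k[idx] <- df$relation != "regulates"
    ConnectivityPattern(e, k)
}

#' @rdname readConnectivity
#' @param pattern a [ConnectivityPattern-class] to serialize.
#' @export
writeConnectivity <- function(pattern, path,
                              format = c("matrix-tsv", "sif-edges")) {
    format <- match.arg(format)
    if (format == "matrix-tsv") {
        e <- entries(pattern)
        storage.mode(e) <- "integer"
        writeMatrixTsv(e, path, rowLabel = "gene")
        k <- pattern@directionKnown * 1L
        storage.mode(k) <- "integer"
        writeMatrixTsv(k, paste0(path, ".known.tsv"), rowLabel = "gene")
        return(invisible(path))
    }
    e <- entries(pattern)
    k <- directionKnown(pattern)
    rows <- character(0)
    for (tf in tfIds(pattern)) {
        for (g in geneIds(pattern)) {
            if (e[g, tf] == 0) next
            rel <- if (!k[g, tf]) "regulates"
                   else if (e[g, tf] > 0) "activates" else "represses"
            rows <- c(rows, paste(tf, rel, g, sep = "\t"))
        }
    }
    writeLines(rows, path)
    invisible(path)
}
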