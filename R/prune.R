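# Compliance logic on a raw entries matrix (intermediate pruning states
# may have empty regulons, which ConnectivityPattern's validity rejects).
complianceRaw <- function(e, nConditions, seed = 1L, trials = 5L) {
    p <- ncol(e)
    tfs <- colnames(e)
    r1 <- if (all(e == 0)) 0L else genericRank(e, trials, seed)
    c1 <- r1 == p
    if (p > 1L) {
        c2 <- vapply(seq_len(p), function(l) {
            sub <- e[e[, l] == 0, -l, drop = FALSE]
            r <- if (nrow(sub) == 0L || all(sub == 0)) 0L
                 else genericRank(sub, trials, seed + l)
            r == p - 1L
        }, logical(1))
    } else c2 <- TRUE
    names(c2) <- if (p > 1L) tfs else tfs[1L]
    reg <- colSums(e != 0)
    indeg <- rowSums(e != 0)
    list(c1 = c1, c2 = c2, reg = reg, indeg = indeg,
         compliant = c1 && all(c2) && all(indeg <= nConditions) &&
             all(reg >= 2))
}

# TFs implicated in a rank deficiency: every TF whose criterion-2 test
# fails, together with the TFs whose column vanishes inside a failing
# reduced pattern (the usual cause: one regulon contained in another).
# If only criterion 1 fails, every TF is a candidate.
implicatedTfs <- function(e, raw) {
    tfs <- colnames(e)
    imp <- character(0)
    if (ncol(e) > 1L) {
        for (l in which(!raw$c2)) {
            sub <- e[e[, l] == 0, -l, drop = FALSE]
            zero <- colnames(sub)[colSums(sub != 0) == 0]
            imp <- c(imp, tfs[l], zero)
        }
    }
    if (!raw$c1 && length(imp) == 0L) imp <- tfs
    sort(unique(imp))
}

#' Prune a network to an NCA-compliant subnetwork
#'
#' Greedy, deterministic reduction of a connectivity pattern until
#' [checkCompliance()] passes, recording every removal. The order of
#' operations is fixed:
#' \enumerate{
#'   \item drop genes that encode any retained TF (a TF cannot appear as
#'     its own target without confounding the decomposition);
#'   \item drop genes whose in-degree exceeds the number of conditions
#'     (their regression sub-problem would be underdetermined);
#'   \item repeatedly drop the TF with the smallest regulon among those
#'     regulating fewer than two genes or implicated in a rank
#'     deficiency (ties broken lexicographically by TF id), dropping
#'     genes orphaned (in-degree 0) after each TF removal, until the
#'     pattern is compliant.
#' }
#' TFs are preferred over genes for removal except for the two
#' gene-specific rules above.
#'
#' @param pattern a [ConnectivityPattern-class].
#' @param nConditions number of expression conditions.
#' @param tfEncodingGenes named character vector mapping a TF id to the
#'   gene id that encodes it (used by rule 1); may be empty.
#' @param seed RNG seed for the generic-rank realizations.
#' @param trials realizations per rank evaluation.
#' @return list with components \code{pattern} (compliant
#'   [ConnectivityPattern-class]) and \code{trace}
#'   ([PruneTrace-class]).
#' @export
pruneToCompliance <- function(pattern, nConditions,
                              tfEncodingGenes = character(0),
                              seed = 1L, trials = 5L) {
    e <- entries(pattern)
    init <- dim(e)
    act <- function(kind, label, reason)
        data.frame(kind = kind, label = label, reason = reason,
                   stringsAsFactors = FALSE)
    actions <- act(character(0), character(0), character(0))

    dropGenes <- function(e, genes, reason) {
        for (g in genes)
            actions <<- rbind(actions, act("gene-removed", g, reason))
        e[setdiff(rownames(e), genes), , drop = FALSE]
    }

    # (1) genes encoding a retained TF
    enc <- unname(tfEncodingGenes[names(tfEncodingGenes) %in% colnames(e)])
    enc <- rownames(e)[rownames(e) %in% enc]
    if (length(enc)) e <- dropGenes(e, enc, "tf-encoding-gene")

    # (2) genes whose in-degree exceeds n
    over <- rownames(e)[rowSums(e != 0) > nConditions]
    if (length(over)) e <- dropGenes(e, over, "in-degree-exceeds-conditions")

    # (3) TF removals until compliant
    iter <- 0L
    repeat {
        iter <- iter + 1L
        if (ncol(e) == 0L || nrow(e) == 0L)
            stop(errorCondition(
                "infeasibility error: pattern pruned to empty",
                class = c("ncaInfeasibleError", "error", "condition"),
                trace = actions))
        raw <- complianceRaw(e, nConditions, seed + 100L * iter, trials)
        if (raw$compliant) break
        cand <- names(raw$reg)[raw$reg < 2]
        reason <- "regulon-too-small"
        if (length(cand) == 0L) {
            cand <- implicatedTfs(e, raw)
            reason <- "rank-deficiency"
        }
        if (length(cand) == 0L)
            stop(errorCondition(
                "infeasibility error: non-compliant but nothing removable",
                class = c("ncaInfeasibleError", "error", "condition"),
                trace = actions))
        cand <- cand[order(raw$reg[cand], cand)]
        tf <- cand[1L]
        actions <- rbind(actions, act("tf-removed", tf, reason))
        e <- e[, setdiff(colnames(e), tf), drop = FALSE]
        orphans <- rownames(e)[rowSums(e != 0) == 0]
        if (length(orphans)) e <- dropGenes(e, orphans, "orphaned-gene")
    }

    pruned <- subsetPattern(pattern, genes = rownames(e), tfs = colnames(e))
    trace <- new("PruneTrace", actions = actions,
                 initialDims = as.integer(init),
                 finalDims = as.integer(dim(e)))
    list(pattern = pruned, trace = trace)
}

#' Replay a prune trace
#'
#' Applies the recorded removals, in order, to a pattern. Replaying the
#' trace returned by [pruneToCompliance()] on its input reproduces the
#' pruned pattern exactly.
#'
#' @param pattern the initial [ConnectivityPattern-class].
#' @param trace a [PruneTrace-class].
#' @return the pruned [ConnectivityPattern-class].
#' @export
replayTrace <- function(pattern, trace) {
    genes <- geneIds(pattern)
    tfs <- tfIds(pattern)
    a <- trace@actions
    for (i in seq_len(nrow(a))) {
        if (a$kind[i] == "tf-removed") tfs <- setdiff(tfs, a$label[i])
        else genes <- setdiff(genes, a$label[i])
    }
    subsetPattern(pattern, genes = genes, tfs = tfs)
}

setMethod("show", "PruneTrace", function(object) {
    cat(sprintf("PruneTrace: %d x %d -> %d x %d (%d removal(s))\n",
                object@initialDims[1], object@initialDims[2],
                object@finalDims[1], object@finalDims[2],
                nrow(object@actions)))
    a <- object@actions
    for (i in seq_len(nrow(a)))
        cat(sprintf("  %s\t%s\t[%s]\n", a$kind[i], a$label[i], a$reason[i]))
})

#' Serialize a prune trace (one action per line)
#'
#' @param trace a [PruneTrace-class].
#' @param path output path.
#' @export
writePruneTrace <- function(trace, path) {
    a <- trace@actions
    lines <- c(sprintf("initial\t%d\t%d", trace@initialDims[1],
                       trace@initialDims[2]),
               sprintf("%s\t%s\t%s", a$kind, a$label, a$reason),
               sprintf("final\t%d\t%d", trace@finalDims[1],
                       trace@finalDims[2]))
    writeLines(lines, path)
    invisible(path)
}
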