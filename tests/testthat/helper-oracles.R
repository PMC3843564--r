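# Independent oracles used to pin the randomized implementations.
# These deliberately use brute-force enumeration, not linear algebra.

# All permutations of 1..k (k small).
permsOf <- function(k) {
    if (k == 1L) return(list(1L))
    out <- list()
    for (sub in permsOf(k - 1L)) {
        for (pos in seq_len(k)) {
            out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
        }
    }
    out
}

# Symbolic (structural) rank by exhaustive minor expansion: an r x r
# minor is generically nonzero iff at least one of its permutation
# products has all factors nonzero (independent continuous entries
# cannot cancel). Returns the largest such r.
structuralRankOracle <- function(e) {
    m <- nrow(e)
    p <- ncol(e)
    if (m == 0L || p == 0L || all(e == 0)) return(0L)
    for (r in seq(min(m, p), 1L)) {
        rows <- utils::combn(m, r, simplify = FALSE)
        cols <- utils::combn(p, r, simplify = FALSE)
        perms <- permsOf(r)
        for (rc in rows) {
            for (cc in cols) {
                for (pm in perms) {
                    if (all(e[cbind(rc, cc[pm])] != 0)) return(r)
                }
            }
        }
    }
    0L
}

# Compliance decision from the enumeration oracle alone.
complianceOracle <- function(e, nConditions) {
    p <- ncol(e)
    c1 <- structuralRankOracle(e) == p
    c2 <- if (p > 1L) {
        vapply(seq_len(p), function(l) {
            sub <- e[e[, l] == 0, -l, drop = FALSE]
            structuralRankOracle(sub) == p - 1L
        }, logical(1))
    } else TRUE
    lim <- all(rowSums(e != 0) <= nConditions) && all(colSums(e != 0) >= 2)
    list(c1 = c1, c2 = c2,
         compliant = c1 && all(c2) && lim)
}

# Enumerate every gene-row support multiset for an m x p pattern.
# Generic rank (hence the compliance decision) is invariant under row
# permutation and under the signs of nonzero entries, so these
# multisets cover ALL sign patterns of that shape.  Columns that end up
# all-zero are skipped (ConnectivityPattern rejects empty regulons).
rowMultisetPatterns <- function(m, p) {
    types <- 0:(2^p - 1)                 # bitmask of regulators per gene
    combos <- utils::combn(length(types) + m - 1L, m)
    out <- list()
    for (j in seq_len(ncol(combos))) {
        typeIdx <- combos[, j] - seq_len(m) + 1L
        e <- matrix(0, m, p)
        for (i in seq_len(m))
            e[i, ] <- as.numeric(
                bitwAnd(types[typeIdx[i]], 2^(seq_len(p) - 1L)) > 0)
        if (any(colSums(e) == 0)) next
        dimnames(e) <- list(sprintf("g%d", seq_len(m)),
                            sprintf("t%d", seq_len(p)))
        out[[length(out) + 1L]] <- e
    }
    out
}

# Random valid pattern with mixed signs and unknown directions, for
# round-trip and property tests (independent of generatePattern).
randomTestPattern <- function(m, p, seed) {
    set.seed(seed)
    repeat {
        e <- matrix(sample(c(-1, 0, 0, 1), m * p, replace = TRUE), m, p,
                    dimnames = list(sprintf("g%02d", seq_len(m)),
                                    sprintf("tf%d", seq_len(p))))
        if (all(colSums(e != 0) >= 1) && all(rowSums(e != 0) >= 1)) break
    }
    k <- array(TRUE, dim(e), dimnames(e))
    unk <- which(e == 1)             # unknown-direction only on +1 edges
    if (length(unk) > 1L) {
        drop <- sample(unk, ceiling(length(unk) / 4))
        k[drop] <- FALSE
    }
    ConnectivityPattern(e, k)
}

# Read back a labelled numeric TSV (independent of the package reader).
readMatrixTsvForTest <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
}

# Per-column Pearson correlation between fitted and true nonzero CS.
csColumnCor <- function(csFit, truth) {
    e <- entries(truth@pattern)
    vapply(seq_len(ncol(e)), function(k) {
        nz <- e[, k] != 0
        suppressWarnings(cor(csFit[nz, k], truth@csTrue[nz, k]))
    }, numeric(1))
}

# Run the full synthetic recovery loop once; returns per-column |r|
# for CS plus the corrected fits and aggregate.
recoveryRun <- function(seed, m = 50L, p = 7L, n = 4L, noiseSd = 0.05,
                        nReplicates = 3L, nRestarts = 10L) {
    pat <- generatePattern(m = m, p = p, nConditions = n, maxInDegree = 3L,
                           seed = seed)
    truth <- generateTruth(pat, nConditions = n, noiseSd = noiseSd,
                           nReplicates = nReplicates, seed = seed + 100L)
    expr <- simulateReplicates(truth)
    fits <- decomposeReplicates(expr, pat, seed = seed,
                                nRestarts = nRestarts)
    corrected <- lapply(fits, function(f)
        correctSigns(normalizeGauge(f), pat))
    results <- lapply(corrected, `[[`, "result")
    agg <- aggregateResults(results,
                            flips = lapply(corrected, `[[`, "flips"))
    list(pattern = pat, truth = truth, expr = expr, results = results,
         agg = agg, csAbsCor = abs(csColumnCor(csMatrix(agg), truth)))
}
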