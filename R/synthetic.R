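#' Generate a random compliant connectivity pattern
#'
#' Rejection-samples sparse signed bipartite TF-to-gene patterns until
#' [checkCompliance()] passes. Each TF draws a regulon size uniformly
#' from \code{targetsPerTf}; every gene receives at least one regulator
#' and no gene's in-degree exceeds \code{maxInDegree} (which must not
#' exceed the number of conditions, or the per-gene regression would be
#' underdetermined). Each edge is repressing with probability
#' \code{repressionFraction}. The defaults mirror the scale of a small
#' curated floral network: 55 genes, 7 TFs, regulons of 2-12 genes,
#' observed over 4 conditions.
#'
#' @param m number of genes (>= 2p).
#' @param p number of TFs.
#' @param targetsPerTf length-2 integer range of regulon sizes
#'   (minimum >= 2).
#' @param repressionFraction probability an edge is repressing.
#' @param nConditions number of conditions the pattern must be
#'   identifiable for.
#' @param maxInDegree cap on gene in-degree (default
#'   \code{nConditions}).
#' @param seed integer RNG seed; the result is deterministic given it.
#' @param maxRejections attempts before giving up.
#' @return a compliant [ConnectivityPattern-class].
#' @export
generatePattern <- function(m = 55L, p = 7L, targetsPerTf = c(2L, 12L),
                            repressionFraction = 0.3, nConditions = 4L,
                            maxInDegree = nConditions, seed = 1L,
                            maxRejections = 1000L) {
    stopifnot(m >= 2L * p, targetsPerTf[1] >= 2L,
              maxInDegree <= nConditions, maxInDegree >= 1L)
    genes <- sprintf("G%03d", seq_len(m))
    tfs <- sprintf("TF%d", seq_len(p))
    withSeed(seed, {
        for (try in seq_len(maxRejections)) {
            sizes <- sample(seq(targetsPerTf[1], min(targetsPerTf[2], m)),
                            p, replace = TRUE)
            if (sum(sizes) < m || sum(sizes) > m * maxInDegree) next
            e <- matrix(0, m, p, dimnames = list(genes, tfs))
            # first pass: cover every gene once, respecting capacities
            cap <- sizes
            ok <- TRUE
            for (g in sample.int(m)) {
                avail <- which(cap > 0)
                if (!length(avail)) { ok <- FALSE; break }
                k <- avail[sample.int(length(avail), 1L)]
                e[g, k] <- 1
                cap[k] <- cap[k] - 1L
            }
            if (!ok) next
            # second pass: fill remaining regulon slots under the cap
            for (k in sample.int(p)) {
                while (cap[k] > 0L) {
                    free <- which(e[, k] == 0 & rowSums(e != 0) < maxInDegree)
                    if (!length(free)) { ok <- FALSE; break }
                    g <- free[sample.int(length(free), 1L)]
                    e[g, k] <- 1
                    cap[k] <- cap[k] - 1L
                }
                if (!ok) break
            }
            if (!ok) next
            nz <- which(e != 0)
            e[nz] <- ifelse(runif(length(nz)) < repressionFraction, -1, 1)
            pat <- ConnectivityPattern(e)
            rep_ <- checkCompliance(pat, nConditions,
                                    seed = sample.int(2^30, 1L))
            if (isCompliant(rep_)) return(pat)
        }
        stop("infeasible-parameters error: no compliant pattern in ",
             maxRejections, " attempts")
    })
}

#' Generate ground-truth strengths and activities for a pattern
#'
#' Nonzero true |CS| values are drawn bounded away from zero
#' (\code{csMin} plus a mean-1 gamma with shape \code{csShape}) so that
#' every edge is identifiable in recovery experiments, signed by the
#' pattern, then gauge-normalized so each column's nonzero entries have
#' root-mean-square 1. True log10 TF activities are zero-mean Gaussian
#' with spread \code{tfaScale} (log10 fold vs control);
#' \code{tfaScale = 0} makes every condition equal the control.
#'
#' @param pattern a compliant [ConnectivityPattern-class].
#' @param tfaScale sd of true log10 TF activities (default 0.5).
#' @param csShape gamma shape for the |CS| magnitudes (default 2).
#' @param csMin lower bound on pre-normalization |CS| (default 0.2).
#' @param nConditions number of conditions.
#' @param noiseSd measurement noise sd in log10 units (default 0.05).
#' @param nReplicates biological replicates to simulate (default 3).
#' @param seed integer RNG seed.
#' @return a [SyntheticTruth-class].
#' @export
generateTruth <- function(pattern, tfaScale = 0.5, csShape = 2,
                          csMin = 0.2, nConditions = 4L, noiseSd = 0.05,
                          nReplicates = 3L, seed = 1L) {
    e <- entries(pattern)
    withSeed(seed, {
        cs <- e
        nz <- which(e != 0)
        mag <- csMin + rgamma(length(nz), shape = csShape,
                              scale = 1 / csShape)
        cs[nz] <- e[nz] * mag
        for (k in seq_len(ncol(cs))) {
            nzk <- cs[, k] != 0
            cs[, k] <- cs[, k] / sqrt(mean(cs[nzk, k]^2))
        }
        tfa <- matrix(rnorm(ncol(e) * nConditions, 0, tfaScale),
                      ncol(e), nConditions,
                      dimnames = list(colnames(e),
                                      sprintf("cond%d", seq_len(nConditions))))
        new("SyntheticTruth", pattern = pattern, csTrue = cs,
            logTfaTrue = tfa, noiseSd = noiseSd,
            nReplicates = as.integer(nReplicates), seed = as.integer(seed))
    })
}

#' Simulate noisy replicate expression from a synthetic truth
#'
#' For each replicate, \eqn{\log_{10} G = CS_{true} \cdot
#' \log_{10} TFA_{true} + \epsilon} with i.i.d. Gaussian
#' \eqn{\epsilon} of sd \code{noiseSd} in log10 units — i.e.
#' multiplicative log-normal noise on the returned positive ratios,
#' the standard error model for ratio-to-control expression data.
#'
#' @param truth a [SyntheticTruth-class].
#' @return an [ExpressionRatioSet-class] with
#'   \code{truth@nReplicates} assays.
#' @export
simulateReplicates <- function(truth) {
    base <- truth@csTrue %*% truth@logTfaTrue
    withSeed(truth@seed + 777L, {
        mats <- lapply(seq_len(truth@nReplicates), function(r) {
            eps <- matrix(rnorm(length(base), 0, truth@noiseSd),
                          nrow(base), ncol(base))
            10^(base + eps)
        })
        names(mats) <- paste0("rep", seq_along(mats))
        ExpressionRatioSet(mats)
    })
}

setMethod("show", "SyntheticTruth", function(object) {
    d <- dim(object@pattern)
    cat(sprintf("SyntheticTruth: %d genes x %d TFs x %d conditions, noise sd %.3g (log10), %d replicate(s), seed %d\n",
                d[1], d[2], ncol(object@logTfaTrue), object@noiseSd,
                object@nReplicates, object@seed))
})

#' The partial floral-development network stated in running text
#'
#' A small fixture: the TF-to-gene edges of the Arabidopsis
#' floral-development network that can be reconstructed from prose alone
#' — LFY's twelve listed targets, AG to CRC, SEP3 to four AGL genes, AP2
#' repressing HLH1 and RD20, AGL15's seven targets (four of which are
#' documented with unknown direction and therefore encoded +1 with
#' \code{directionKnown = FALSE}), HY5 activating HLH1, RAV2, RD20 and
#' UNK4, and the AP3/PI dimer regulating FLO10. This is deliberately
#' \emph{not} a reconstruction of the full curated 10-TF/57-gene
#' network; it is a synthetic partial stand-in assembled from named
#' pairs, suitable for exercising parsers, compliance checking and
#' pruning on realistic labels.
#'
#' @return list with components \code{pattern}
#'   (a [ConnectivityPattern-class]) and \code{edges} (data.frame
#'   tf/relation/gene of the documented edges).
#' @examples
#' fx <- floralFixture()
#' dim(fx$pattern)
#' @export
floralFixture <- function() {
    lfy <- c("ACR7", "HB51", "GRA1", "UNK3", "MYB17", "TLP8",
             "ASN1", "BGLU15", "BZIP", "LEA", "UNK2", "SUS4")
    edges <- rbind(
        data.frame(tf = "LFY", relation = "activates", gene = lfy),
        data.frame(tf = "AG", relation = "activates", gene = "CRC"),
        data.frame(tf = "SEP3", relation = "activates",
                   gene = c("AGL4", "AGL3", "AGL8", "AGL22")),
        data.frame(tf = "AP2", relation = "represses",
                   gene = c("HLH1", "RD20")),
        data.frame(tf = "AGL15", relation = "regulates",
                   gene = c("AGL22", "AGL25", "EDF4", "RAV2")),
        data.frame(tf = "AGL15", relation = "activates",
                   gene = c("LEA7", "CSP4", "CBF2")),
        data.frame(tf = "HY5", relation = "activates",
                   gene = c("HLH1", "RAV2", "RD20", "UNK4")),
        data.frame(tf = "AP3/PI", relation = "activates", gene = "FLO10"))
    path <- tempfile(fileext = ".sif")
    on.exit(unlink(path))
    writeLines(sprintf("%s\t%s\t%s", edges$tf, edges$relation, edges$gene),
               path)
    list(pattern = readConnectivity(path, "sif-edges"), edges = edges)
}

#' Materialize a reproducible synthetic study directory
#'
#' Writes a complete synthetic NCA study — connectivity pattern (matrix
#' TSV with direction-known companion), true CS and log TFA, one
#' expression-ratio TSV per replicate, and a manifest recording every
#' generator parameter and the seed — so a study can be regenerated
#' bit-for-bit.
#'
#' @param dir output directory (created if absent).
#' @inheritParams generatePattern
#' @inheritParams generateTruth
#' @return invisibly, a list with the truth and the written paths.
#' @export
makeDataset <- function(dir, m = 55L, p = 7L, targetsPerTf = c(2L, 12L),
                        repressionFraction = 0.3, nConditions = 4L,
                        maxInDegree = nConditions, tfaScale = 0.5,
                        csShape = 2, csMin = 0.2, noiseSd = 0.05,
                        nReplicates = 3L, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pat <- generatePattern(m, p, targetsPerTf, repressionFraction,
                           nConditions, maxInDegree, seed = seed)
    truth <- generateTruth(pat, tfaScale, csShape, csMin, nConditions,
                           noiseSd, nReplicates, seed = seed + 1L)
    expr <- simulateReplicates(truth)
    writeConnectivity(pat, file.path(dir, "pattern.tsv"), "matrix-tsv")
    writeMatrixTsv(truth@csTrue, file.path(dir, "cs_true.tsv"), "gene")
    writeMatrixTsv(truth@logTfaTrue, file.path(dir, "log_tfa_true.tsv"),
                   "tf")
    paths <- file.path(dir, sprintf("expression_rep%d.tsv",
                                    seq_len(nReplicates)))
    writeExpression(expr, paths)
    writeKeyValue(list(m = m, p = p, targets_min = targetsPerTf[1],
                       targets_max = targetsPerTf[2],
                       repression_fraction = repressionFraction,
                       n_conditions = nConditions,
                       max_in_degree = maxInDegree, tfa_scale = tfaScale,
                       cs_shape = csShape, cs_min = csMin,
                       noise_sd = noiseSd, n_replicates = nReplicates,
                       seed = seed),
                  file.path(dir, "manifest.tsv"))
    invisible(list(truth = truth, expr = expr,
                   paths = c(file.path(dir, "pattern.tsv"), paths)))
}
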