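---
title: "Network component analysis with ncatools: model, identifiability and design choices"
author: "ncatools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network component analysis with ncatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncatools)
```

## The model

Transcription-factor (TF) gene-regulatory networks are usually curated as
Boolean facts: TF $\ell$ activates, represses, or is not known to regulate
gene $i$. Network component analysis (NCA) turns such a curated prior plus
condition-wise expression measurements into quantitative estimates, by
decomposing the log-ratio expression matrix as a constrained bilinear
product

$$
\log_{10} G_{m \times n} \;=\; CS_{m \times p} \cdot \log_{10} TFA_{p \times n},
$$

where $G$ holds positive expression ratios of $m$ genes across $n$
conditions relative to a control, $CS$ holds real-valued connectivity
strengths whose zero pattern is fixed by the curated network (entry
$(i,\ell)$ may be nonzero only if TF $\ell$ is documented to regulate gene
$i$), and $\log_{10} TFA$ holds the latent condition-wise activities of the
TFs, as log-fold changes versus the same control. The sign of a fitted CS
entry is read as activation ($+$) versus repression ($-$); TF activity is
deliberately distinct from TF mRNA, since it absorbs post-transcriptional
and post-translational regulation.

The model is log-linear: each gene's log expression is a weighted sum of
the log activities of its documented regulators. All logs are base 10 and
this is not configurable — the expression container records it and every
downstream quantity (CS magnitudes, activity fold changes, noise sd) is
interpreted in log10 units.

## Structural identifiability ("NCA compliance")

A bilinear factorization is never unique without constraints: for any
invertible $X$, $(CS\,X)(X^{-1}\log TFA)$ reproduces the same data. The
zero pattern removes most of this freedom. `checkCompliance()` tests the
standard structural criteria under which the only remaining freedom is one
scale (and sign) per TF:

1. the connectivity pattern has full generic column rank $p$;
2. for each TF, deleting its column and all genes it regulates leaves a
   pattern of generic rank $p-1$;
3. the data are rich enough, $n \ge p$.

Generic rank is computed numerically: each structural nonzero is replaced
by an independent draw from sign $\times\, U(0.5, 1.5)$ (continuous,
bounded away from zero) and the maximum numerical rank over 5 realizations
is taken. For patterns of this size the probability that a random
realization misses the generic rank is essentially zero; the test suite
pins the implementation against an exhaustive minor-expansion oracle on
every small pattern shape (all row-support multisets with $m \le 6$,
$p \le 3$, which — because generic rank is invariant under row order and
entry signs — covers every sign pattern of those shapes exactly).

**Limited-data mode.** Small designed experiments often violate criterion
3: a typical curated floral network has 7 TFs observed over 4 cell types.
The package follows the modified-algorithm route: criterion 3 is reported
but not enforced, and instead every gene's in-degree must be at most $n$
(so each gene's regression sub-problem in the solver is determined) and
every TF must regulate at least two genes. These are exactly the
conditions under which the alternating solver's sub-problems are solvable,
and they are what the overall `compliant` flag asserts, together with
criteria 1–2. The precise identifiability conditions of the
limited-data algorithm are a design decision of this package, documented
here rather than hidden.

## Pruning

Curated networks are rarely compliant as retrieved. `pruneToCompliance()`
reduces a pattern deterministically, preferring to remove TFs over genes,
with two gene-specific exceptions applied first:

1. genes that encode a retained TF are dropped (`tf-encoding-gene`) — a
   TF appearing among its own targets confounds activity and expression;
2. genes with in-degree above $n$ are dropped
   (`in-degree-exceeds-conditions`) — their sub-problem is
   underdetermined.

Then TFs are removed one at a time: among TFs regulating fewer than two
genes or implicated in a rank deficiency, the one with the smallest
regulon goes first (ties broken lexicographically by label), genes
orphaned by a TF removal are dropped (`orphaned-gene`), and the criteria
are re-checked until the pattern is compliant. "Implicated" means the TF
whose criterion-2 test fails together with any TF whose column vanishes in
that reduced pattern — the common cause is one regulon being a subset of
another, and removing the smaller-regulon member of such a pair is both
cheaper and sufficient. Every removal is recorded in a `PruneTrace` whose
replay on the input reproduces the output exactly; the pruner is
idempotent. No attempt is made to find the *maximum* compliant subnetwork
(that search is combinatorial); the greedy, trace-documented reduction is
the contract.

The bundled text-reconstructed floral fixture (`floralFixture()`)
illustrates a subtlety: besides its two single-target TFs (AG and AP3/PI,
removed with `regulon-too-small`), its AP2 regulon \{HLH1, RD20\} is a
strict subset of the HY5 regulon, so criterion 2 fails for HY5 and the
pruner also removes AP2 with `rank-deficiency`. This is a real property of
the partial network stated in prose — the full curated network from which
it is drawn gives AP2 additional targets and does not have this
degeneracy.

## Fitting: alternating least squares with restarts

`decompose()` minimizes $\|\log_{10} G - CS \cdot \log_{10} TFA\|_F^2$ by
two-step least squares:

* **CS step** — for each gene independently, an ordinary least-squares
  problem in its $k_i \le n$ regulators' activities;
* **TFA step** — for each condition independently, an ordinary
  least-squares problem in all $p$ activities given $CS$
  (overdetermined because $m \gg p$).

Each half-step is an exact minimizer, so the objective is non-increasing
at every half-step; the per-half-step objective trace is stored on the
result and asserted in the tests. Iteration stops when the relative
objective change falls below `tol` (default $10^{-9}$) or after `maxIter`
(default 1000) iterations.

Because the objective is bilinear, alternating minimization can stall in
non-global stationary points, and run-to-run variability under random
initialization is a real phenomenon worth measuring rather than hiding.
Restarts are therefore first-class: the initial $\log TFA$ is drawn
uniformly from $[-1, 1]$ (a small-magnitude initializer keeps the first
CS step well scaled for log10-fold data), `nRestarts` independent runs
(default 10) are fitted, and the best final objective is returned along
with the index of the winning restart. No regularization is applied — the
method is plain two-step least squares. Biological replicates are fitted
independently (`decomposeReplicates()`), replicate $r$ using derived seed
`seed + r`; all randomness is seeded and no function falls back to
wall-clock entropy.

## Gauge and sign conventions

The fitted pair $(CS, \log TFA)$ is only defined up to one scale per TF:
scaling a CS column by $c \neq 0$ and its activity row by $1/c$ leaves the
product unchanged. Two post-processing steps fix this:

* `normalizeGauge()` rescales every CS column so the root-mean-square of
  its nonzero entries is 1 (activity rows get the reciprocal). The
  curated literature never states its normalization and treats CS as
  relative rather than absolute; under this declared convention the
  conventional $|CS| > 1$ "strong interaction" threshold reads "above the
  column's typical magnitude".
* `correctSigns()` resolves the residual per-TF sign ambiguity by
  majority vote over *anchors* — documented edges whose regulatory
  direction is experimentally established. Documented edges of unknown
  direction (encoded $+1$ but flagged `directionKnown = FALSE`) never
  anchor. A TF with no anchors or an exact tie is left unflipped and
  flagged, not guessed.

`aggregateResults()` pools the corrected best-of-restarts fits across
replicates into element-wise means and sample standard deviations, and
classifies each documented interaction: strong activation/repression
requires $|\overline{CS}| > 1$ *and* a coefficient of variation below
`cvMax` (default 0.5 — the low-variability criterion is stated
qualitatively in the literature without a threshold, so the default is a
declared choice); large-magnitude but high-variability entries are
`undetermined`; $0 < |\overline{CS}| \le 1$ is weak; structural zeros are
`none`.

## Evaluation

* `reconstructionR2()` pools every gene $\times$ condition pair into one
  scatter of measured versus model-simulated log expression and reports
  $R^2 = 1 - SS_{res}/SS_{tot}$ about the grand mean. Replicates are
  averaged per gene and condition *before* comparison (the
  pooling-after-averaging convention is flagged in the report, since
  either order is defensible).
* `tfaMrnaParity()` min-max normalizes each TF's activity series and the
  log10 mRNA series of its encoding gene to $[0,1]$ and reports Pearson
  correlations. A constant series maps to all 0.5 with a degeneracy flag
  rather than an error, so a flat activity profile still renders on a
  parity plot. Composite regulators (ids containing `/`, e.g. a dimer)
  are compared against each constituent gene separately.
* `pairwiseConditionTest()` runs two-sided Welch $t$ tests on the
  replicate activities for every unordered condition pair, significant at
  strict $p < \alpha$ (default 0.05), with no multiple-testing
  correction; both choices are surfaced in the report notes.

## The synthetic-data generator

`generatePattern()`, `generateTruth()` and `simulateReplicates()` define
the study conditions under which the package's claims are tested:

* sparse signed bipartite patterns at the scale of a small curated
  network (defaults: 55 genes, 7 TFs, regulons of 2–12 genes, 4
  conditions, ~30% repressing edges), rejection-sampled until compliant,
  with every gene regulated and in-degree capped at $n$;
* true CS magnitudes bounded below (0.2 plus a mean-1 gamma, shape 2,
  before gauge normalization) so that no edge is unidentifiably close
  to zero in recovery experiments; true activities zero-mean Gaussian
  with sd `tfaScale` = 0.5 log10 units — the literature gives no
  effect-size scale for activity fold changes, so this is a free
  parameter chosen once as a realistic one-to-threefold activity swing;
* measurement noise additive Gaussian in log10 space (sd 0.05 by
  default, 3 replicates), i.e. multiplicative log-normal on ratios — the
  standard error model for ratio-to-control expression data.

What the generator does *not* emulate: probe-level artifacts, batch
effects, missingness, outliers, or correlated noise. Passing recovery
tests therefore demonstrate correctness of the estimator under the
model's own assumptions, not robustness to everything real expression
data can do.

Problem sizes used by the test and acceptance suites (50 genes / 7 TFs /
4 conditions; 50 independent studies for the noisy-recovery rate; all
pattern shapes up to $6 \times 3$ for the compliance oracle) were chosen
to exercise the paper-scale regime while keeping a full run in the order
of a minute or two on one CPU.

## Numerical choices and degenerate inputs

* Rank decisions use `qr()` with its default tolerance on realizations
  bounded away from zero; five trials, maximum taken.
* The ALS convergence test is relative: $(f_{t-1} - f_t) \le
  \mathrm{tol}\cdot\max(f_{t-1}, 10^{-300})$, robust to exactly-zero
  objectives on noise-free data.
* A gene whose regulators' activity rows become numerically collinear
  raises a rank-deficiency error naming the gene rather than silently
  pseudo-inverting.
* Constant series in min-max normalization return 0.5 with a flag;
  zero-variance Welch comparisons return $p = 1$ (no effect) or $p = 0$
  (deterministic difference) instead of erroring.
* Ties everywhere (pruning candidates, restart winners) break
  deterministically: lexicographic labels, lowest restart index.
* All TSV artifacts are written with `%.17g`, so reruns of a stage with
  an identical configuration are bit-for-bit identical, and manifests
  record input/output MD5 checksums plus the full parameter echo.

## Known limitations

* The greedy pruner documents, but does not optimize, its reduction; a
  different removal order could retain a larger compliant subnetwork.
* Uncertainty is empirical (spread across restarts and replicates); no
  analytic confidence intervals are provided.
* Genes with missing values are dropped at alignment, not imputed — the
  decomposition has no missing-data mechanism.
* With $n < p$ the decomposition relies on the sparsity pattern for
  identifiability; patterns that barely satisfy the criteria can still
  be poorly conditioned, which manifests as high replicate/restart
  dispersion and `undetermined` classifications rather than as warnings.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
pat   <- generatePattern(m = 55, p = 7, nConditions = 4, seed = 1)
truth <- generateTruth(pat, nConditions = 4, noiseSd = 0.05,
                       nReplicates = 3, seed = 2)
expr  <- simulateReplicates(truth)
fits  <- decomposeReplicates(expr, pat, seed = 3)
corr  <- lapply(fits, function(f) correctSigns(normalizeGauge(f), pat))
agg   <- aggregateResults(lapply(corr, `[[`, "result"),
                          flips = lapply(corr, `[[`, "flips"))
evaluateModel(agg, expr, results = lapply(corr, `[[`, "result"))
```

The same steps are available as staged, artifact-writing pipeline calls
(`runCheck()`, `runPrune()`, `runFit()`, `runEvaluate()`,
`runSimulate()`) driven by an `ncaConfig()` object or a YAML file.
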