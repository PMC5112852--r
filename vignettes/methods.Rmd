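---
title: "Pathway-guided gene selection: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided gene selection: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GSReduce)
```

# The problem

Two-class transcriptomic studies (diseased vs control) routinely measure
thousands of genes on a few dozen samples. A classifier built on all genes
overfits; a panel chosen gene-by-gene ignores the biology that genes act in
pathways. GSReduce selects small gene panels *through* gene-set structure:
first decide which sets are associated with the phenotype, then extract the
genes that carry that association. Two extraction routes are provided, and
they embody different philosophies about what makes a gene worth keeping.

# Set-level association

For gene $i$ the moderated statistic is
$d_i = (\bar{x}_d(i) - \bar{x}_c(i)) / (s(i) + s_0)$, where $s(i)$ is the
two-group pooled standard deviation
$\sqrt{(1/n_d + 1/n_c)\,(SS_d + SS_c)/(n_d + n_c - 2)}$ and $s_0 \ge 0$
prevents genes with near-zero scatter from dominating. The statistic for
set $j$ is $\mathrm{SAMGS}_j = \sum_{i \in j} d_i^2$: direction-agnostic,
order-invariant and additive over disjoint subsets, so a set scores high
whether its members move up, down or in mixed directions.

Significance comes from $B$ random shuffles of the phenotype labels
(`samGsPermutation`). Within each shuffle *everything* is recomputed —
group means, pooled SDs and, by default, $s_0$ itself — because the label
assignment changes the pooled SDs. Two conventions matter and are fixed
deliberately:

* **Add-one p-values.** In random mode $p = (1 + \#\{b : T^{(b)} \ge
  T^{obs}\}) / (B + 1)$, so no p-value is ever zero and the attainable
  minimum is $1/(B+1)$. In exhaustive mode (all $\binom{n}{n_d}$ label
  assignments, available when that count is at most 10,000) the p-value is
  the exact proportion, the observed assignment included.
* **$s_0$ by quantile.** The classical coefficient-of-variation tuning of
  the fudge constant is deliberately out of scope; the default is the 5th
  percentile (type-7 quantile) of the per-gene pooled SDs — deterministic,
  cheap, and close in spirit. A fixed-value override exists, as does a flag
  to freeze the observed $s_0$ across permutations
  (`recomputeS0 = FALSE`) for comparison with implementations that do so.

The default $B = 500$ balances p-value resolution ($1/501$) against cost;
"several hundred" is the field's habit for set-level screens. Sets pass at
raw permutation $p \le 0.05$ by default; a Benjamini–Hochberg mode
(`pAdjust = "BH"`) is available when collections are large. Sets smaller
than `minSize = 2` are dropped at restriction time because a singleton set
degenerates to a single $d_i^2$.

# Route 1: reduction to core subsets

Inside a significant set, members are ranked by ascending gene-level
permutation p-value (ties: larger $|d_i|$ first, then gene id — ties are
common at small $B$, and the rule keeps builds deterministic). Peeling the
top $k$ genes leaves a residual whose set statistic has permutation p-value
$c_k$, evaluated on the *same stored permutation draws* — this makes the
whole reduction deterministic given the original run and costs nothing.
The core subset is the first $k$ genes at the smallest $k$ with
$c_k > \text{cutoff}$; if no $c_k$ exceeds the cutoff the entire set is
kept (exhaustion). The $c_k$ sequence is not monotone in general — the
peeling order follows gene p-values, which need not follow $d_i^2$ — and
the implementation only ever asks for the *first* crossing.

The cutoff doubles as the method's tuning parameter: for each value on a
grid (0.05 to 0.50 in steps of 0.05) the union of core subsets is fed to a
plain linear SVM (unit cost, features standardized) and the training
misclassification error is recorded. The winning cutoff minimizes error,
with ties going to the smaller panel and then the smaller cutoff. The final
model is the same plain SVM on the winning union.

# Route 2: penalized selection within significant sets

The reduction route keeps a gene only if its *individual* statistic is
strong enough to sit above the peeling frontier. The alternative is to let
the classifier decide: pool the deduplicated membership of the significant
sets and fit a linear SVM with a smoothly clipped absolute deviation (SCAD)
penalty on each coefficient,

$$\min_{w, b} \sum_i \big(1 - y_i(w^\top x_i + b)\big)_+ + \sum_j p_\lambda(w_j),$$

$$p_\lambda(w) = \begin{cases}
\lambda |w| & |w| \le \lambda \\
-\dfrac{|w|^2 - 2\alpha\lambda|w| + \lambda^2}{2(\alpha - 1)} & \lambda < |w| \le \alpha\lambda \\
(\alpha + 1)\lambda^2 / 2 & |w| > \alpha\lambda .
\end{cases}$$

SCAD behaves like the LASSO near zero (exact sparsity) but is constant for
large coefficients, so strong markers are not shrunk once selected. The
shape default $\alpha = 3.7$ is the standard choice. Gene membership
matters only through admission to the candidate pool — a gene in ten
significant sets enters once, and a true marker in *no* set can never be
selected, a structural property the test suite asserts.

## Fitting: LLA over a smoothed hinge

SCAD is nonconvex; the fitter uses local linear approximation (LLA):
starting from $w = 0$, each outer iteration solves the convex problem with
per-coefficient weights $p'_\lambda(|w_j^{(t)}|)$ — so the first iteration
is exactly the L1-penalized fit at the same $\lambda$ — and the true
objective is non-increasing across iterations by the majorization argument
(the fitted model records the trace; the tests assert monotonicity).

The weighted-L1 subproblems are solved by cyclic coordinate descent on a
*huberized* hinge: the hinge's kink is replaced by a quadratic on
$(1 - \delta, 1)$ with $\delta = 0.5$, giving the loss a
$1/\delta$-Lipschitz derivative so each coordinate admits a quadratic
majorizer and a closed-form soft-threshold update (compiled kernel, exact
zeros, monotone descent; an R reference implementation of the same solver
is kept and cross-checked in the tests). Smoothing at this scale leaves the
loss within $\delta/8$ of the hinge and is the established trick for
coordinate-descent SVMs; solving the subproblems as exact linear programs
was rejected because it needs an external LP solver and offers no
statistical benefit here.

Numerical defaults, all overridable: outer tolerance $10^{-4}$ on the max
coefficient change (or a relative objective decrease below $10^{-8}$ —
LLA can hop between near-equivalent sign patterns without either being an
improvement), at most 50 outer iterations (a cap breach returns the last
iterate with a warning and `converged = FALSE`), inner tolerance
$10^{-7}$, hard-zero threshold $10^{-6}$ on $|w_j|$. Features are
standardized internally because the penalty is scale-sensitive; constant
genes are centered but not scaled. $\lambda$ is tuned by stratified 5-fold
cross-validation over $2^{-8}, \dots, 2^{14}$ on pooled misclassification
error, ties broken toward the larger (sparser) $\lambda$. During tuning the
solver is warm-started along the $\lambda$ path (largest to smallest);
the warm start only seeds the solver of the first — convex — subproblem,
and a safeguard re-solves from zero if it ever fails to improve the
objective. At near-zero $\lambda$ the hinge minimizer is not unique (any
separator is optimal), so solutions there legitimately depend on the
starting point.

## Class beliefs

Both routes emit beliefs through a Platt sigmoid
$P(\text{diseased} \mid f) = 1/(1 + e^{Af + B})$ fitted on the training
decision values with smoothed targets $(n_+ + 1)/(n_+ + 2)$ and
$1/(n_- + 2)$, so separable training data do not drive the slope to
infinity. Beliefs are strictly inside $(0, 1)$, sum to one, and are
monotone in the decision value.

# Evaluation metrics

`errorRate` calls the argmax belief (exact ties to the first class — a
deterministic rule that sigmoid beliefs essentially never trigger). `gbs`
is $\frac{1}{2n}\sum_i\sum_k (Y_{ik} - p_{ik})^2$: 0 perfect, 0.25 for
uniform two-class beliefs, 1 anti-perfect. `bcm` is implemented as the mean
diagonal of the belief confusion matrix — for each represented class, the
average belief assigned to that class by its own samples, macro-averaged.
The metric's original challenge definition is prose, not a formula, so this
literal reading is flagged here: per-class weighting is an interpretation.
`aupr` ranks samples per class by belief and sums precision at each
positive (the average-precision convention; trapezoidal interpolation is
known to overestimate PR area), macro-averaged over classes with at least
one positive; tied beliefs are broken by sample order with a warning.
Average precision carries a positive $O(1/n)$ bias under random ranking,
which is why the "random beliefs give 0.5" check in the tests runs at
$n = 100$.

# The synthetic generator

`simulateExpression` draws log-expression as correlated Gaussians: every
gene in at least one set loads on its first containing set's shared
standard-normal factor, $x = \sqrt{\rho}\,F + \sqrt{1-\rho}\,\varepsilon$
(unit marginal variance by construction), scaled by $\sigma$; marker genes
get an additive shift $\delta$ in diseased samples only. The presets in
`overlapScenarios()` share a universe of 210 genes, twenty 10-gene sets,
30 samples per class, $\rho = 0.2$, $\sigma = 1$ and $\delta = 2$ — sample
sizes and effect sizes typical of the microarray case-control studies this
method targets, and a within-set correlation modest enough that a set's
signal is not a single latent factor. The four presets differ only in
where the five markers sit: in three sets at once, in exactly one, in
none, or nowhere shifted at all (pure null).

What the generator does *not* emulate: heavy-tailed noise, probe-level
artifacts, batch structure, variance heterogeneity between genes, and
set-size diversity. Passing tests on these data therefore demonstrate the
algorithms' internal correctness and their qualitative behavior
(sensitivity to marker/set membership, null calibration), not performance
on real arrays.

# Design choices made where the design was open

* **Probe collapse** keeps, per gene, the probe with the largest absolute
  difference of group means on the log2 scale (the standard reading of
  "largest fold change" for log-transformed data), ties to the
  lexicographically smallest probe id. Missing values are a hard error —
  imputation is someone else's job, done before this package.
* **Exhaustive mode** exists because at $n \le 12$ or so, random
  permutations waste resolution; the enumeration cap (10,000) keeps it from
  being selected accidentally on large data.
* **Stored-permutation reuse** for $c_k$ (rather than fresh draws) makes
  reduction deterministic and matches the single-pass description of the
  procedure; gene ordering is computed once and not refreshed after each
  removal.
* **Seed fan-out**: every pipeline derives stage seeds from the global seed
  through a stable string hash (`deriveSeed`), so adding a stage never
  shifts another stage's stream.

# Known limitations

* When several markers are mutually redundant for classification — e.g.
  five genes all shifted by $2\sigma$, where four of them already give
  near-floor error — cross-validated misclassification cannot distinguish
  the full marker set from a subset, and the sparser-model tie-break then
  prunes legitimately informative genes. The modified route recovers *the
  classifying signal* reliably in this regime, but recovery of *every*
  redundant marker is not guaranteed; panels intended as biological
  inventories rather than classifiers should be read with this in mind.
* The reduction route's cutoff is tuned on training error, which saturates
  at zero on separable data; the panel-size tie-break then does the real
  work.
* BCM and AUPR per-class weighting is an interpretation (macro-averaging);
  see above.
* Only two-class phenotypes, linear decision rules, and log-scale input
  are supported; count data should be transformed upstream.

# Problem sizes used by the test and acceptance suites

The suites run entirely on simulated data: tiny exhaustive cases
($n = 6$), oracle comparisons at $G \le 20$, $n \le 12$; null calibration
over 200 replicate datasets at $B = 199$; selection-recovery studies at
$n = 40$–$60$, $G = 21$–$210$, 20 seeds. These sizes are chosen so the
whole verification cycle runs in minutes on a laptop while keeping every
statistical check adequately powered.
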