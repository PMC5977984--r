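---
title: "Methods: circulating miRNA biomarker discovery and SVM response prediction"
author: "miRResponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA biomarker discovery and SVM response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRResponse)
```

# The problem and the model

Two-arm pharmacotranscriptomics at clinical scale is brutally small:
a discovery cohort of six responders and six non-responders, tens of
thousands of features, and the goal of a handful of circulating miRNAs
whose levels predict response before treatment. `miRResponse` chains five
analyses so that each stage constrains the next, and every stage is
testable against planted synthetic ground truth.

## Moderated differential screening

With two or three residual degrees of freedom per feature, per-feature
variance estimates are so unstable that the ordinary t-test is dominated
by its denominator. The random variance model assumes per-feature
variances are exchangeable draws from an inverse-gamma prior; equivalently
the observed pooled variance satisfies $s^2 a b \sim F(d, 2a)$ with
$d = n_1 + n_2 - 2$. We fit $(a, b)$ by maximum marginal likelihood
(deterministic Nelder–Mead on the log scale, fixed start $a=b=1$, relative
tolerance $10^{-12}$) and form

$$\tilde\sigma^2 = \frac{d\,s^2 + 2/b}{d + 2a}, \qquad
  t = \frac{\bar x_1 - \bar x_2}{\tilde\sigma\sqrt{1/n_1 + 1/n_2}},$$

with $d + 2a$ degrees of freedom. As $a \to 0$ and $2/b \to 0$ this
reduces exactly to the pooled t-test (a frozen test asserts agreement to
$10^{-9}$). The fit refuses degenerate inputs: all-zero or exactly
constant variances abort with a fit error rather than returning an
$a \to \infty$ prior, because in that regime the moderated test silently
becomes a fold-change ranking with fictitious degrees of freedom.

Significance gates are deliberately the simplest defensible reading of
standard practice: $|\log_2 \mathrm{FC}| > 0.5$ **and** $P < 0.05$, both
strict. BH q-values are always computed and reported; gating on them is a
config option (`fdrMode = "gate"`), off by default, because at $n = 6+6$
with genuine effects of 1.5 log2 units the raw-p gate is the operative
criterion and a hard q-gate mostly just interacts with the feature count.
Thresholds sit in `runConfig()` (`log2fcMin`, in log2 units; `pMax`).

Hierarchical clustering uses $1 - r$ (Pearson) distance with average
linkage — the expression heat-map convention — delegated to
`stats::hclust`, whose deterministic tie handling we adopt rather than
re-implementing agglomeration for a bespoke tie rule. Correlation distance
for an exactly constant feature is undefined and raises an error.

## Target intersection and the co-expression network

Predictions from two independent programs are intersected as plain sets of
(miRNA, gene) identifier pairs — identifiers are case-sensitive exact
strings, and no alias mapping is attempted (annotation aliasing is
non-deterministic across database versions and out of scope). The
co-expression edge rule has three clauses, each toggleable:
$r < 0$ (Pearson, computed across **all** samples pooled — the network
describes the discovery cohort as a whole, not either arm), correlation
test $P < 0.05$, and opposite DE direction. The conjunction is the
conservative reading of "negatively correlated with its dysregulated
target"; dropping clauses only adds edges, so the default errs toward
specificity. Degree, the miRNA ranking criterion, is the bipartite degree;
the gene-gene interaction network below is kept separate, so miRNA edges
never inflate gene topology.

## Interaction-network topology

The combined-score median is computed over the **full** interaction table,
before restricting to DE genes (configurable via
`medianAfterRestriction`): the median models the score distribution of the
database, not of the DE subset, and computing it first makes the filter
independent of the screening stage. Comparisons are strict everywhere the
word "higher" appears: score $>$ median, and hub genes have degree,
betweenness and closeness all strictly above their medians — a regular
graph therefore has no hubs, which is the intended degenerate behavior.

Relative betweenness uses the prefactor $2/(n^2 - 3n + 2)$, i.e. the
fraction of unordered vertex pairs a node can mediate; closeness is the
inverse farness $1/\sum_y d(y, i)$, summed over the node's component on
disconnected graphs (a fully isolated node gets 0 — the least surprising
extension of a formula that assumes connectivity). Edge betweenness is
reported unnormalised, in path-count units, because only the ranking
feeds the key-interaction call; ties at the maximum are all kept. These
are delegated to igraph's Brandes implementation; the test suite pins the
conventions with hand-derived cases (path centre 1, star centre 1,
$K_4$ all zero, bridge score 9 on twin 3-cliques) and with exhaustive
simple-path-enumeration oracles on 100 random connected graphs of
$n \le 8$, at $10^{-9}$.

Markov clustering is implemented in the package (no R implementation was
available to delegate to): column-stochastic transition matrix with unit
self-loops, expansion by matrix power (default 2), inflation by
elementwise power and column renormalisation (default 2), pruning below
$10^{-5}$ with renormalisation, iterated to a $10^{-8}$ maximum-change
tolerance within 100 iterations. Modules are read from the limit matrix:
attractors are nodes with positive diagonal mass, attractors with
overlapping support merge, and each node joins the module holding the
largest share of its column mass (ties to the smaller module id, for
determinism). Non-convergence is a warning plus `converged = FALSE`,
never an error, so a long-tailed graph still yields a usable partition.
Module enrichment is the one-sided hypergeometric tail $P(X \ge k)$ with
BH adjustment across all (module, set) pairs.

## Panel assembly

The biomarker rule is: take the endpoint genes of the `topKEdges`
highest edge-betweenness interactions (default 2, ties included), and for
each anchor gene select the incident miRNA with the smallest DE p-value —
"most significantly dysregulated" read as smallest p, with larger
$|\log_2\mathrm{FC}|$ then identifier as deterministic tie-breaks. The
panel de-duplicates miRNAs across anchors and its size is emergent, not
forced. Anchor genes with no upstream miRNA in the co-expression network
are reported and skipped; only a panel with zero members is an error.

## The classifier

The SVM is LIBSVM's C-classification with the RBF kernel
$K(x_i, x_j) = \exp(-\gamma\|x_i - x_j\|^2)$, responder mapped to $+1$,
predicted class the sign of the decision value (0 mapped to $+1$).
Defaults $C = 1$ and $\gamma = 1/(p \cdot \widehat{\mathrm{var}})$ (the
"scale" heuristic over the scaled training values) follow the standard
practical guidance for this toolchain; both are config slots. Feature
scaling (z-score with the population-SD convention, divisor $n$) is
estimated inside each training fold only — at twelve samples, scaling on
the full matrix before CV is a real leakage channel, so the pipeline never
does it.

Cross-validation is stratified (per-class round-robin over shuffled
indices) so every training set contains both classes at $n = 6 + 6$,
repeated five times by default with fresh seeded fold draws. Metrics are
pooled per repeat: confusion counts summed over folds, AUC computed from
the pooled held-out decision values; across-repeat means and SDs are
reported, and per-fold rows are kept for inspection. AUC is the
tie-corrected Mann–Whitney probability (mid-ranks); zero-denominator
metrics are `NaN` with a warning, never silently 0. AUC pairs on the same
samples are compared with the two-sided DeLong test; two perfect curves
yield $p = 1$ with an explicit warning that the comparison is
uninformative. Clinical covariates enter ROC comparisons as raw univariate
scores, sign-oriented so their AUC is $\ge 0.5$, with the orientation
reported.

# The synthetic generator

`syntheticSpec()` encodes the study conditions the package is designed
for, and its defaults are fixed once:

* 6 responders vs 6 non-responders (discovery-cohort scale); a validation
  cohort is drawn with the same `populationSeed` and a different `seed`,
  which reuses the per-feature baselines and noise scales (they are
  feature properties) while drawing new samples.
* 30 miRNAs and 60 genes — two orders of magnitude below array scale, but
  large enough that the variance-prior fit (which needs $\ge 20$
  features) and the decoy machinery are exercised; the null-calibration
  studies use 2000 features.
* 2 planted miRNAs with $|\Delta| = 1.5$ log2 units of opposite sign;
  unit coupling $\beta = 1$: a true target equals its baseline minus
  $\beta$ times its miRNA's centred value plus noise, which yields both
  the negative sample-level correlation and the opposite group-level fold
  change the edge rule demands.
* noise SD 0.3 log2 units as the typical scale, with per-feature
  variances drawn as $1/\sigma_i^2 \sim
  \Gamma(\mathrm{varShape},\ \mathrm{rate} = \mathrm{varShape}\cdot
  \sigma_e^2)$, `varShape = 4`. Microarray noise is heteroscedastic, and
  exchangeable inverse-gamma variances are exactly the regime the RVM
  screen is built for; exactly constant noise would make the prior fit
  degenerate by construction.
* decoy fraction 0.5: half as many decoy prediction pairs as true pairs,
  each planted in exactly one of the two tables so the intersection
  removes all of them.
* interaction modules of sizes 4 and 3 — the true-target cliques of the
  two planted miRNAs (module $j$ is the target set of planted miRNA
  $j$) — joined by one bridge between the first gene of each module.
  Community and bridge edges draw scores in (0.55, 0.9), an equal number
  of background edges among non-target genes draw (0.2, 0.45), so the
  global median always separates them and the strict filter keeps exactly
  the planted structure, with the bridge the unique edge-betweenness
  maximum. Tying modules to miRNA target sets is what makes end-to-end
  recovery well defined: the bridge endpoints anchor distinct planted
  miRNAs.
* `delta = 0` is allowed and produces a null cohort with no group effect
  anywhere — the configuration used for type-I-error calibration.

All generation is a pure function of the spec and its seed (Mersenne
Twister with inversion sampling, pinned explicitly), so every fixture in
the test suite is reproduced bit-for-bit at test time; the shipped
`inst/extdata/worked_example/` files are the `seed = 20` cohort at
8 miRNAs / 12 genes and are verified against regeneration in the tests.

What the generator does **not** emulate — and what green tests therefore
do not certify about clinical data: probe-level artifacts and
normalisation, batch and platform effects between discovery (microarray)
and validation (qPCR) assays, correlated miRNA co-regulation, indirect
(non-target) anti-correlations, annotation ambiguity between prediction
databases, and class imbalance beyond what the validation split
introduces. On real cohorts the panel should be treated as a candidate
set for orthogonal (qPCR) confirmation, as the workflow intends.

# Problem sizes and determinism

The test suite runs the flagship recovery study at 50 seeds of the
default cohort (recovery of the exact planted panel in $\ge 90\%$ of
seeds; in practice 100%), the permutation-null CV study at 200 cohorts,
the type-I calibration at 2000 features, and the centrality oracles at
100 random graphs of $n \le 8$ — sizes chosen so the whole suite stays in
the tens of seconds while every stochastic bound retains a comfortable
margin. `scripts/acceptance.R` recomputes the headline quantities from
scratch under a caller-supplied seed.

One reading deserves a note: with $\Delta = 1.5$ and noise SD 0.3, a
single planted miRNA already separates the arms by five standard
deviations, so single-miRNA CV AUCs saturate at 1.0 and the panel model
cannot *strictly* exceed them. The meaningful, and tested, claim is that
the panel model's AUC is at least every single-miRNA AUC — the panel
never loses to any of its members.

# Known limitations

* The RVM prior fit needs $\ge 20$ positive, non-constant variances; the
  shipped 8-miRNA worked example is therefore an I/O and selection
  fixture, not a screening benchmark.
* MCL module reading assumes the iteration reached (or neared) a doubly
  idempotent limit; heavily weighted or near-bipartite graphs may need
  more iterations or a different inflation.
* DeLong comparisons are uninformative when both curves are perfect —
  common at these synthetic effect sizes — and are flagged, not hidden.
* The pipeline consumes already-normalised log2 matrices; upstream
  normalisation is deliberately out of scope.
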