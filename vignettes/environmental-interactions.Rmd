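---
title: "Environmental interactions and epistasis: models and methods"
author: "envepi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental interactions and epistasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envepi)
```

# The problem

Cells rarely face one environmental change at a time. When two stimuli —
say, a temperature shift and a carbon-source switch — are applied
concurrently, the response of each protein or transcript need not be the
sum of its responses to the individual stimuli. By analogy with gene
interaction, two stimuli *interact environmentally* when they affect the
same readout, and they show *environmental epistasis* when their effects
are not independent: the concurrent response deviates from the sum of the
single-stimulus responses.

envepi implements this framework for a 2x2 factorial design: a baseline
condition, each stimulus alone (A, B), and both together (AB), with
replicate log2 fold changes relative to the baseline as the response. The
motivating application is quantitative proteomics of budding yeast under a
heat stimulus and a glycerol (respiratory) carbon-source stimulus, but
nothing in the machinery is specific to those stimuli or to proteins.

# The per-feature factorial model

For each feature we model replicate log2 fold changes by condition means
(the *cell-means* parameterization):

$$y_{cr} = \beta_c + \varepsilon_{cr}, \qquad c \in \{A, B, AB\},
  \qquad \varepsilon_{cr} \sim N(0, \sigma^2)$$

Because the response is a fold change against the baseline, the baseline
mean is identically zero and this model is exactly the saturated
main-effects + interaction factorial model refit to condition means. We
deliberately report the *concurrent-condition mean* $\beta_{AB}$ rather
than the interaction contrast of a dummy-coded factorial: the
classification rules below compare the direction and significance of the
AB response with each single-stimulus response, and the epistasis test
forms its own contrast explicitly. Estimates are condition means, the
residual variance is pooled across the three conditions
($s^2 = SS_{within}/(n-3)$), $se_c = s/\sqrt{n_c}$, and the overall
3-degree-of-freedom no-intercept F statistic
$F = [\sum_c n_c \hat\beta_c^2/3]/s^2$ tests all three means jointly
zero. Unbalanced replicate counts (e.g. the 3/4/3 test-condition design of
chemostat compendia re-analyses) are supported; `df_resid` is always
$n - 3$.

Overall p-values are Benjamini–Hochberg adjusted across features; the
responder gate is $q \le 0.05$. Coefficient-level calls use the raw
per-condition p-values with a strict $p < 0.05$, matching the asymmetric
conventions of the interaction-class definitions (a *non*-responder has
$q$ *greater* than the cutoff). Both thresholds are arguments throughout.

Degenerate inputs: a feature whose replicates are numerically identical
has $s^2 = 0$; rather than fail, the fit uses the convention $p = 0$ for a
nonzero estimate and $p = 1$ for a zero one and flags the feature
(`zero_variance`), so noiseless synthetic data flow through the pipeline.

# Interaction classes

Each responder's state is a triple over {significantly up, significantly
down, unchanged} for (A, B, AB). The rules, evaluated in order:

1. **NER** (non-specific environmental response): all three significant,
   same direction.
2. **A-dominant**: A and AB significant and concordant; B either not
   significant or opposed to AB.
3. **B-dominant**: the mirror image.
4. **Suppression**: AB not significant while at least one single stimulus
   is — a response abolished by the second stimulus.
5. **Discordant**: AB significant but matched in direction by neither
   single stimulus.

Evaluating NER before dominance resolves their only overlap
(all-significant, all-concordant satisfies both dominance clauses).
Exhaustive enumeration of the 27 states (`pattern_table()`) yields 2 NER,
4 per dominance class, 8 discordant, 8 suppression patterns, plus the
all-unchanged state; these counts are a structural property of the rules
and are asserted in the tests. A responder that matches no rule — possible
because the joint F can be significant when no single coefficient is — is
reported `UNCLASSIFIED` with a warning; a coherent data set should have
none.

# The environmental epistasis test

Independence of the stimulus effects is tested additively on the log2
scale:

$$t = \frac{(\hat\beta_A + \hat\beta_B) - \hat\beta_{AB}}
           {\sqrt{se_A^2 + se_B^2 + se_{AB}^2}}$$

with a two-sided p-value and the call *epistatic* iff $p \le 0.05$. The
test runs on every feature, responder or not. By default the reference
distribution uses the feature's residual df ($n-3$): the three standard
errors share one pooled variance, so under additivity the statistic is
exactly t-distributed, and the type-I error on an additive null is nominal
(the acceptance suite measures it at 10,000 features). A
Welch–Satterthwaite df built from the per-condition df is available via
`df_method = "satterthwaite"` for users who prefer not to pool.
Multiplicative, minimum or log definitions of epistasis are out of scope;
only the additive contrast is implemented.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. Each feature receives a class (largest-remainder rounding of
the requested mix), a pattern drawn uniformly from the class's admissible
patterns, and true means in $\{0, \pm\text{effect\_size}\}$; replicates
add $N(0, \text{noise\_sd}^2)$. Defaults are three replicates per
condition, effect size 1.0 (a two-fold change), noise 0.2 — the replicate
scatter typical of isobaric-tag fold-change data — and a class mix equal
to the frequencies observed in the motivating proteomics study
(41:30:121:175:41:58 over 466 proteins). The epistatic flag is *computed*
from the means, never sampled; suppression features have the concurrent
mean exactly 0, and non-responders are all-zero. A separate additive null
(`simulate_additive_null()`) draws single-stimulus means from
Uniform(−1, 1) — the magnitude distribution of real effects is unknown, so
this is a convention, stated once here — and sets the concurrent mean to
their exact sum.

What the generator does *not* emulate: missing values and the
complete-case filter they force, reporter-ion ratio compression,
correlated replicate structure, or heavy-tailed noise. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under clean factorial assumptions, not robustness to every artifact of
real proteomics data.

# The coexpression network

The network chain is fixed: probabilistic quotient normalization →
generalized log → per-feature standardization → sparse partial-correlation
estimation → edge thresholding.

* **PQN** corrects per-sample dilution via the median quotient against the
  feature-wise median reference. PQN presumes positive intensities; on
  signed fold-change data the quotients are guarded (features with
  |reference| ≤ 1e-8 are excluded) and the step can be disabled
  (`use_pqn = FALSE`), which we recommend for strongly signed matrices.
* **glog**, $g(x) = \ln\!\big((x + \sqrt{x^2+\lambda})/2\big)$, is defined
  for negative arguments and tempers outliers; $\lambda = 1$ and the
  natural log base are conventions.
* **The estimator** solves the joint symmetric lasso regression
  $$\min_\rho \tfrac12 \sum_i w_i \big\| x_i - \sum_{j \ne i} \rho_{ij}
    \sqrt{d_j/d_i}\, x_j \big\|^2 + \lambda \sum_{i<j} |\rho_{ij}|$$
  by cyclic coordinate descent (convergence when the largest coefficient
  change falls below 1e-6; warning and best iterate otherwise), with
  weights and scale factors iteratively set to the estimated residual
  precisions $d_i = n/\|r_i\|^2$ over three outer iterations. Two limits
  anchor correctness and are tested: at $\lambda = 0$ with $p < n$ the
  fixed point is exactly the sample partial-correlation matrix obtained by
  inverting the sample covariance, and for $p = 2$ the off-diagonal is the
  sample correlation. The default penalty is
  $\sqrt{n}\,\Phi^{-1}(1 - \alpha/(2p^2))$ with $\alpha = 0.1$, the
  canonical family-wise exclusion level for this estimator class.
* **Edges** join pairs whose |partial correlation| exceeds the mean
  absolute off-diagonal value of the estimated matrix (zeros included,
  strict inequality). Reading the mean-of-matrix rule on absolute values
  avoids sign-dependent edge loss; a fixed threshold is available as a
  config switch. Isolated nodes remain in the node table; the connected
  count is reported separately.

Diagnostics: the degree distribution is fit by discrete maximum likelihood
over $P(k) \propto k^{-\alpha}$ (a log-log frequency regression is
reported only as the historically common, biased comparator); hubs are the
top 1% of nodes by degree with ties broken by feature id; hub stability is
the mean pairwise Jaccard index between hub sets re-estimated across a
tuning grid (0.7x, 1x, 1.3x by default — a single-network grid reports 1.0
by convention); hub significance is a two-sided Wilcoxon rank-sum test of
hub versus non-hub degrees. The published analysis this mirrors did not
state what its Jaccard and Wilcoxon compared; both interpretations here
are labelled as such. Edge tallies partition the edge set twice — by
endpoint epistasis status (both / neither / mixed) and by interaction
class (within / between) — and each partition must sum to the edge count.

On a 10-node chain-graph Gaussian (tridiagonal precision, partial
correlations 0.4) at $n = 500$, the default-penalty estimate recovers
every true edge with the correct sign, and the mean-threshold rule returns
the chain with at most a trace of shrinkage leakage (an occasional weak
distance-2 edge, always weaker than every true edge). Simulation sizes
throughout the test and acceptance suites — 10,000-feature null
calibration, 500-feature recovery, $n = 500$ chain graphs, 5,000 power-law
draws — were chosen as the smallest sizes at which the stochastic
assertions are stable to reseeding.

# Growth kinetics

Doubling time is $1/\text{slope}$ of the log2(OD)-vs-time regression over
the log-growth phase. The log phase is located automatically: among all
sliding windows of fixed duration (default 90 min) with at least 10
points, take the steepest window whose $R^2 \ge 0.98$. The floor excludes
lag and plateau; an exactly flat window is a perfect zero-slope fit and
yields the non-growing flag rather than an error. Noiseless curves are
recovered essentially exactly across doubling times 60–240 min and lags
0–60 min. Under measurement noise the max-slope selection is slightly
anticonservative (it prefers upward-fluctuating windows); at noise sd 0.01
on log OD the bias is a few percent, which the tests document rather than
hide. Window length, point minimum and $R^2$ floor are all arguments.

Stimulus effects are differences of mean doubling time versus control,
with the effect's standard error propagated from replicate scatter in both
groups. The additivity test compares the observed concurrent effect with
the sum of single-stimulus effects, combined standard error
$\sqrt{\sum sd_i^2}$, Welch df propagated from the components, and
Bonferroni correction for the comparison family (default 11, the family
size of the motivating 8-condition growth design). The control group
appears in every effect, so the component effects are not strictly
independent; the Welch composition is the documented approximation. Any
number of single stimuli ≥ 2 is accepted, so three-stimulus designs test
identically.

# Known limitations

* Coefficient-level calls are unadjusted by design fidelity to the
  framework being implemented; with many features some per-condition calls
  are false positives, which propagates a few percent of class confusion
  (quantified by the recovery tests).
* The epistasis test inherits the pooled-variance assumption; strong
  heteroscedasticity across conditions would argue for the Satterthwaite
  switch.
* The partial-correlation estimator is pure R; it is comfortable to a few
  hundred features and small sample counts, not to transcriptome-scale
  matrices.
* PQN on signed data remains a pragmatic convention, not a principled
  normalization; inspect `pqn_factors` before trusting it.
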