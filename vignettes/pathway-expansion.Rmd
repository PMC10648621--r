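---
title: "Pathway-exploiting and pathway-expanding survival networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-exploiting and pathway-expanding survival networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsurv)
```

## The model

`pathsurv` fits a three-layer neural survival model whose first layer is
constrained by curated gene-pathway memberships. With expression
$x \in \mathbb{R}^{1 \times G}$, first-layer weights
$W_1 \in \mathbb{R}^{G \times P}_{+}$ (element-wise non-negative),
output weights $W_2 \in \mathbb{R}^{P \times 1}$ and a binary mask
$M \in \{0,1\}^{G \times P}$ encoding the prior memberships, the risk score is

$$ f_W(x, M) = \tanh\!\big(\tanh\big(x \, (W_1 \odot M)\big) \, W_2\big), $$

one bounded scalar per sample. Each pathway node aggregates its member genes;
non-negativity of $W_1$ keeps the node interpretable as a (weighted) pathway
activity rather than an arbitrary contrast. Training minimizes the negative
log Cox partial likelihood

$$ \ell(W) = -\sum_{i:\,\delta_i = 1} \Big[ f_W(x_i) -
   \log \sum_{j:\,T_j \ge T_i} e^{f_W(x_j)} \Big], $$

with the inclusive risk set $T_j \ge T_i$ (Breslow convention for ties). The
sum form above is what the optimizer sees; `neg_log_partial_likelihood()`
exposes an `average` switch for reporting per-event values, off by default.

## Two training phases

**Exploitation (pretraining).** The network is trained under the prior mask
$M$ with an added penalty $\lambda \cdot \mathrm{Std}(W_1 \odot M)$ - the
population standard deviation pooled over all prior entries - encoding the
assumption that genes within a curated module carry comparable importance.
Non-prior entries of $W_1$ are structurally zero in this phase: the masked
gradient vanishes there, which the test suite asserts by finite differences.
A per-pathway variant of the penalty is available
(`std_penalty(per_pathway = TRUE)`) but pooling is the default: the penalty is
read literally as the spread of one masked weight matrix, and pooling also
avoids a degenerate zero penalty for single-gene pathways.

**Exploration (training phase).** The first layer is opened to all genes (the
all-ones mask $E$) and the non-prior entries are penalized by
$\mu \lVert W_1 \odot (1 - M) \rVert_1$. The package handles this term
proximally rather than by subgradient: each epoch applies the Adam update and
then soft-thresholds the non-prior entries with the per-coordinate threshold
$\mu \cdot \mathrm{lr} / (\sqrt{\hat v} + \varepsilon)$, where $\hat v$ is
Adam's bias-corrected second-moment estimate. This is the exact proximal step
of the L1 term under Adam's diagonal metric, and it matters: Adam moves every
coordinate by roughly the learning rate regardless of gradient magnitude, so
a flat threshold of $\mu \cdot \mathrm{lr}$ would exactly cancel the largest
possible step and no new link could ever establish, while a plain subgradient
never produces exact zeros. With the preconditioned proximal step, links whose
(smoothed) gradient magnitude stays below $\mu$ are driven to exact zero and
links with genuine support grow - which is what makes the binary occurrence
indicator $W_1(i,j) > 0$ well-defined without any epsilon tolerance.

A non-negativity projection follows every update in both phases.

**Initialization.** Prior entries of $W_1$ start uniform on $(0, 0.1)$,
non-prior entries at exactly 0, and $W_2$ uniform on $(0, 1/\sqrt{P})$.
Starting $W_2$ non-negative is deliberate: with $W_1$ clamped to the
non-negative orthant, a pathway whose output weight begins negative while the
pathway truly increases risk can be driven into a dead state - its $W_1$
column is crushed to zero before $W_2$ can cross sign, after which all
gradients through the node vanish. We observed this in roughly half of
single-pathway runs under a symmetric initialization. A genuinely protective
pathway can still learn a negative $W_2$ by passing through the
small-magnitude region while its $W_1$ column stays positive.

**Defaults.** Full-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning
rate 0.05, 100 epochs per phase, $\lambda = \mu = 1$. No early stopping and no
schedules: budgets are fixed, and a single integer seed fixes initialization,
fold assignment and resampling, making every run exactly reproducible.

## Pathway expansion

`run_ensemble()` refits the two-phase model on (by default) 100 random 90%
subsamples, giving binary occurrence matrices $O^{(k)}(i,j) = 1[W_1^{(k)}(i,j) > 0]$
and the occurrence-probability matrix $S = \frac{1}{K}\sum_k O^{(k)}$.
`select_expanded()` sorts all $G \times P$ entries of $S$ and keeps exactly

$$ n^\ast = \lfloor (1 + \alpha) K + \tfrac12 \rfloor $$

gene-pathway pairs, where $K$ is the number of prior pairs and $\alpha$
(default 0.2) controls the expansion size - so the supplement is roughly
$\alpha K$ pairs. Ties at the cut are broken deterministically: larger
ensemble-mean fitted weight, then lower gene index, then lower pathway index.
$K$ counts gene-pathway *pairs* (ones of $M$), not distinct genes, since $S$
is a matrix and the threshold indexes its sorted values. Prior pairs are not
force-included; in practice they sit near $S = 1$, and
`select_expanded()` reports any prior pair that falls below the cut.
Selections are nested in $\alpha$. Per-run seeds are `seed + k` and are
recorded alongside the subsample indices.

## Validation analyses

**Recoverability testing** (`recoverability_test()`) removes one prior
gene-pathway pair at a time, refits a resampled ensemble, and asks how often
the removed link re-establishes with positive weight. The distribution of
these leave-one-out recovering probabilities is compared with the occurrence
probabilities of genuinely non-prior pairs (averaged per pair across the
leave-one-out experiments) by a two-sample Kolmogorov-Smirnov test
(asymptotic p-value; recovering probabilities are discrete, so the exact
method is not attempted). The desk-scale default is 20 runs per left-out gene
- the distributional separation, not the individual probabilities, is the
quantity of interest - and a `panel` argument restricts the left-out pairs
when the full sweep is unnecessary. The rank of a left-out gene is computed
within its pathway's candidate pool (all pairs absent from the modified
mask), 1 being the highest occurrence probability.

**Single-gene survival analysis** (`single_gene_km()`) splits samples at the
median expression of one gene (values strictly above the median form the
high group; ties at the median go low), estimates Kaplan-Meier curves per
group, and tests the difference by the log-rank test. The split depends only
on expression ranks, so any monotone transform of the gene leaves the result
unchanged.

## The synthetic generator

`generate_synthetic()` produces data with the structure the model assumes,
plus a known ground truth for testing the expansion machinery: i.i.d.
standard-normal expression (emulating z-scored, variance-filtered data);
pathways whose *true* membership includes a few planted "hidden" genes that
the prior mask omits; pathway activities defined as the mean expression of
the true members, scaled to unit variance so that `effect_size` reads as a
log-hazard ratio per activity standard deviation; log-risk
$\mathrm{effect} \cdot \sum_j a_j + \mathcal{N}(0, \mathrm{noise}^2)$;
exponential event times with rate $e^{\text{log-risk}}$ (Weibull shape 1.5
available); and exponential censoring whose rate is tuned by bisection so the
realized censored fraction lands within 0.1 of the target.

Defaults: 300 samples, 150 genes, three pathways of 10 prior + 2 hidden
members, effect 1.5, residual noise SD 0.5, 30% censoring. The effect size
and structure give a true-risk concordance near 0.88 - comparable to the
training-set concordances the model family reaches on real cohorts - and the
noise SD and censoring target are chosen as ordinary values for observational
cohorts. What the generator does *not* emulate: gene-gene correlation (real
co-expression makes pathway members redundant and selection easier to
stabilize per pathway but harder to attribute per gene), heavy-tailed or
count-scale expression, non-proportional hazards, and informative censoring.
Passing tests on this generator therefore demonstrate the mechanics and the
qualitative behaviors of the method, not performance on any real cohort.

## Numerical choices

- Log-sum-exp in the partial likelihood is max-shifted; the risk-set sums are
  reverse cumulative sums with tie groups sharing their first position.
- Concordance defaults to 0.5 credit for tied risks (the common convention);
  `ties = "strict"` scores ties zero, reproducing the printed formula
  verbatim. Summaries can report the 0-100 scale via `percent = TRUE`.
- The variance filter uses the sample standard deviation with a strict
  `> threshold` comparison; z-scoring uses the full matrix (the conventional
  order of operations, though it lets test folds influence the scaling - a
  known leakage caveat of that convention).
- Occurrence uses strict `W1 > 0` with no tolerance, which the proximal step
  makes meaningful.
- Cross-validation is a standard seeded K-fold partition (default 10, i.e. a
  9:1 ratio with every sample tested once); the expansion ensemble resamples
  90% subsets instead of partitioning. A training fold with no events is
  re-drawn once, then refused.

## Known limitations

- At desk scale the per-gene signal of a hidden pathway member is weak
  (univariate z around 2-3 against a 400-gene noise floor of the same order),
  and with the sum-form likelihood the fixed penalty weight $\mu = 1$ sits
  far below the gradient noise scale, so each resampled fit activates many
  spurious links alongside the true ones. The occurrence ranking then
  recovers planted genes only partially - an exact L1-path method (e.g. a
  linear Cox lasso tracked along its regularization path) separates the same
  planted genes cleanly on the same data. The ensemble's distributional
  signal is robust (left-out prior genes are recovered far more often than
  non-prior genes, with KS p-values around 1e-8 at desk scale), but exact
  recovery of every planted pair at a fixed small $\mu$ is not guaranteed.
- The bounded $\tanh$ output compresses risk differences between extreme
  patients; after long training the output layer saturates and gradient
  information concentrates on mid-risk samples. This caps the efficiency of
  the exploration phase's gene scores relative to an unbounded linear score.
- With a single pathway the model has one hidden unit; although the
  initialization avoids the dead-unit trap, such configurations remain
  fragile and at least two pathways are recommended.
- The expansion applies no multiplicity correction across pathways; the
  selection is a ranking device, and supplement genes are hypotheses to be
  validated, not significance calls.
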