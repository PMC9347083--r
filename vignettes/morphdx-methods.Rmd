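---
title: "morphdx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphdx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`morphdx` implements a multi-diagnostic classification pipeline for
structural-MRI morphometry. The input is a table of per-subject regional
measures of the kind a FreeSurfer-style surface reconstruction produces —
volumes, surface areas, cortical thickness means and SDs, curvature and
folding indices — together with subject metadata: age at scan, sex, dataset
and acquisition-protocol tags, the clinical diagnosis at scan time, and the
diagnosis at the most recent follow-up visit (12 to 36 months later). The
follow-up diagnosis is the ground truth: a subject scanned as MCI who later
progressed to AD is trained and scored as AD. This deliberately includes
*all* diagnostic transitions — MCI to AD progression, MCI to HC reversion,
HC to MCI and HC to AD onset — because a deployed classifier cannot filter
its intake by a future it is supposed to predict, and excluding
hard-to-predict transitions inflates apparent performance.

The decision is over the ordered severity scale HC < MCI < AD.

## Graph-theory features

Each subject's regional volumes define a morphometric similarity graph.
The edge weight between regions $i$ and $j$ is the symmetric ratio

$$\mathrm{Ratio}_{ij} \;=\; \frac{2}{\,v_i/v_j + v_j/v_i\,} \in (0, 1],$$

equal to 1 exactly when the volumes agree and invariant to a common
rescaling of both volumes. The weighted matrix is binarized at thresholds
0.3, 0.5, 0.7 and 0.9 (edge kept when the ratio **meets** the threshold;
the inclusive rule keeps equal-volume pairs connected even at threshold
1.0), and four node-wise metrics are computed per threshold: degree,
clustering coefficient (0 by definition for degree < 2), betweenness
centrality, and eigenvector centrality. With $n$ node volumes this yields
$4n$ features per threshold.

Numerical conventions worth stating explicitly, because toolboxes differ:

* **Betweenness** is normalized to $[0,1]$ by $(n-1)(n-2)/2$, so features
  remain comparable when the node count is configured away from its
  default. Shortest-path ties are counted with multiplicity (Brandes
  accounting), via igraph.
* **Eigenvector centrality** is the non-negative principal eigenvector of
  the adjacency matrix at unit Euclidean norm, computed by shifted power
  iteration on $A + I$. The shift makes the iteration convergent on
  bipartite graphs (whose spectra are symmetric about zero) without
  changing the eigenvectors. An edgeless graph has no dominant direction;
  its centrality is defined as all-zero and a warning is emitted rather
  than an error, since heavily thresholded subject graphs can legitimately
  be empty. On graphs whose dominant eigenvalue is degenerate (equal-sized
  disconnected dominant components) the iteration returns the non-negative
  mixture the uniform start vector converges to; the test suite checks the
  eigenpair property there rather than a particular basis choice.

## The ensemble per binary task

For each binary task (HC vs MCI, HC vs AD, MCI vs AD) seven algorithms are
tuned independently: linear SVM, decision tree, random forest, extremely
randomized trees, LDA, logistic regression, and logistic regression trained
by stochastic gradient descent. All expose class probabilities and
per-feature importances (absolute weights for the linear models, impurity
importance for the trees).

Tuning is a small evolutionary search — 10 generations of 10 individuals,
30% per-gene mutation, 50% crossover, tournament size 3, elitism of one —
over a genome of (selector metric, selector percentile, algorithm
hyperparameters). Fitness is the mean Matthews correlation coefficient
across 5 stratified CV folds of the training set. Within every fold the
preprocessing (min–max scaling to $[0,1]$, then top-percentile selection by
mutual information, ANOVA F, or chi-square) is fitted on the fold's
training part only; the chi-square scorer is valid because it only ever
sees the scaled, non-negative training block. Percentile 0 would select
nothing, so the search space is $\{10, 20, \ldots, 100\}$.

The seven tuned candidates are ranked by `mean(fold MCC) − sd(fold MCC)`
(sample SD, divisor $n-1$), selecting for folds that are both good and
stable. Candidates scoring **strictly above the mean** of the seven are
refit on the full training set and combined; if no candidate clears the
mean (all tied), the single best is used, with ties broken by the fixed
algorithm order above. When graph-theory features are enabled, 28
additional candidates (7 algorithms × 4 thresholds, each trained on its
threshold's GT block only — sources are never mixed within one learner)
compete: any GT candidate ranking above the worst selected voter replaces
it, iterating in descending GT score, leaving the voter count unchanged.

Voting is **soft**: the ensemble probability is the mean of member
probabilities. Soft voting was chosen over hard majority because the
multiclass combiner consumes a probability per binary task; a hard vote
would throw away the very quantity the stacker needs. Labels use a 0.5
threshold with exact ties resolved to the less severe class.

Two implementation notes. First, libsvm's Platt-scaled probabilities can
come out *inverted* relative to the decision function when the internal
calibration CV degenerates (small cost values on nearly separable data);
the linear-SVM wrapper detects this on the training data and flips the
probabilities once at fit time. Second, no pre-installed R package provides
an SGD-trained logistic classifier, so the package ships a small one: log
loss with L2 penalty $\alpha$, 100 shuffled epochs, with either the
`optimal` schedule $\eta_t = 1/(\alpha(t_0+t))$, $t_0 = 1/\alpha$, or an
`adaptive` schedule that starts at $\eta_0 = 0.1$ and divides by 5 when an
epoch fails to improve the penalized loss.

Hyperparameter grids are deliberately standard desk-scale ranges: SVM and
logistic-regression cost $C \in \{0.01, 0.1, 1, 10, 100\}$; tree depth
$\{3, 5, 10, \infty\}$, forest size $\{100, 300\}$, minimum leaf
$\{1, 5, 10\}$; LDA covariance estimator $\{\text{moment}, \text{mle}\}$
(the moment/ML choice stands in for a shrinkage toggle, which MASS's LDA
does not expose); SGD $\alpha \in \{10^{-4}, 10^{-3}, 10^{-2}\}$ and the
two schedules. They live in `default_grids()` and are configuration, not
constants.

## Multiclass stacking

Each subject is mapped to the 3-vector of higher-class probabilities
$(P(\mathrm{MCI}\mid \mathrm{HCvMCI}),\ P(\mathrm{AD}\mid \mathrm{HCvAD}),\
P(\mathrm{AD}\mid \mathrm{MCIvAD}))$ and a linear maximum-margin one-vs-one
classifier over that 3-dimensional representation produces the final
diagnosis. The margin parameter C is tuned by 5-fold stratified CV on
multiclass MCC and the combiner is refit on the whole training set.
Prediction is by one-vs-one majority vote with ties broken by the
accumulated signed margins.

Aggregated interpretability: each binary's importance vector (summing to 1)
is weighted by the mean *absolute* coefficient its probability receives
across the three one-vs-one decision functions, and the weighted sum is
renormalized. Absolute values were chosen because a combiner coefficient's
sign encodes which side of a pairwise decision a binary supports, not
whether its features matter; averaging across the three decision functions
reduces three coefficients per binary to one weight. The grouped report
(`grouped_importance()`) sums shares by anatomical group or by measure
type, in percent.

## Constrained test sets

Test sets are built so that training-set imbalances cannot leak into test
metrics: per transition type, a round-half-up 30% goes to test; within each
diagnosis the test M/F counts differ by at most one; and pairwise
differences of test mean age between diagnosis groups are brought within
1.0 year by greedy swaps. The matching algorithm is deliberately simple and
auditable: after the stratified draw, the diagnosis group whose test mean
age deviates most is nudged toward the grand mean by swapping its most
age-extreme test subject with the best-matching training subject *of the
same diagnosis, sex and transition type* (so the other constraints are
preserved by construction), up to 1000 passes. If the tolerance cannot be
met the split fails loudly, reporting the closest achieved gap — silent
degradation would defeat the purpose of the constraint. A mean-difference
tolerance was chosen over a test-statistic criterion because it is
monotone under single swaps and independent of group size.

## Evaluation

* Binary MCC with the zero-marginal convention (0, the common choice when a
  row or column of the confusion matrix is empty); multiclass MCC in the
  covariance form, which reduces exactly to the binary formula at $k=2$.
* Balanced accuracy = mean per-class recall, reported in percent.
* Predictive values by Bayes' rule at a configurable prevalence. Clinical
  first-visit prevalence defaults (HC 42.0%, MCI 18.6%, AD 26.3%) give
  positive-class prevalences of 0.307 / 0.385 / 0.586 for the three binary
  tasks; 50% prevalence gives the "standardized" values.
* ROC AUC is the rank-based (Mann–Whitney) estimator with ties counted
  half; the multiclass variant macro-averages one-vs-rest AUCs over
  per-class scores derived from the one-vs-one probability representation.
* Uncertainty by percentile bootstrap over subjects, 2000 resamples;
  resamples that lose a true class are skipped and counted. Classifier
  comparison uses paired-index resampling when the two share a test set,
  with $p = 2\min(\Pr(\Delta\le 0), \Pr(\Delta\ge 0))$ clipped to
  $[2/B, 1]$.
* Clinical applicability combines a user-supplied quality-of-evidence grade
  (1–4, a study-design judgment the software cannot make) with an effect
  grade obtained by converting AUC to an odds ratio through Cohen's d
  ($d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, $\log \mathrm{OR} = d\pi/\sqrt{3}$)
  and a configurable cutoff table (defaults 1.5 / 2.5 / 5, so OR ≥ 5 is
  grade 4).

## The synthetic cohort generator

Because the real multi-site cohorts are access-controlled, the package
ships a generator that reproduces the *statistical shape* the pipeline
assumes, so every stage is testable. Feature values follow

$$x = \mu_f\,(1 - e_{g(f)}\, s_{dx})\; \pi_{p,f}\; \delta_{d,f}\;
(1 + \beta\,(\mathrm{age}-70))\;\varepsilon,$$

with baseline scales $\mu_f$ drawn once per feature on positive,
measure-type-appropriate scales; group atrophy effects at full AD severity
of 10% (hippocampus), 5% (temporal), 3% (cingulate, frontal) and 1%
elsewhere, applied at severity 0 / 0.5 / 1 for HC / MCI / AD; transition
subjects at the mean of their baseline and final severities, so they are
genuinely ambiguous, mirroring the observation that transition cases are
harder; per-protocol and per-dataset multiplicative factors
$\pi, \delta \sim N(1, 0.03)$ and $N(1, 0.02)$ drawn once per (tag,
feature); an age slope $\beta = -0.2\%$/year about age 70 (a mild,
realistic atrophy gradient — neither the generator's consumers nor its
tests are sensitive to its exact value); and multiplicative lognormal noise
with a 5% coefficient of variation and unit mean (volumes and areas are
positive and right-skewed, so multiplicative noise is the natural choice).
Demographics default to a typical multi-site dementia cohort: ages
HC 72.4 ± 6.6, MCI 73.1 ± 7.5, AD 74.6 ± 7.9 years; class-specific sex
ratios; transition rates per final class of 26/211 (MCI→HC), 16/188
(HC→MCI), 83/171 (MCI→AD) and 1/171 (HC→AD).

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: inter-regional covariance beyond the
shared severity factor, scanner- and site-specific artifacts beyond a
per-feature multiplicative offset, heavy-tailed measurement failures,
missing data, and diagnosis-label noise. Tests on this generator verify
that the machinery is correct and that effects of the configured size are
recoverable; they say nothing about the effect sizes present in any real
cohort.

## Problem sizes used in the shipped tests

The data model defaults to the full inventory (694 features, 209 graph-node
volumes), and all layout arithmetic is tested at that scale. Training-based
tests run on reduced cohorts chosen as the package's own desk-scale study
conditions: the end-to-end HC-vs-AD acceptance runs use 40 subjects per
class with 80 features (16 nodes) across 10 seeds; protocol-discrimination
runs use 100 per class with 60 features; the full multi-protocol multiclass
experiment uses 200 per class with 100 features; bootstrap coverage uses
200 replications of a 200-subject test set at 2000 resamples. Noise,
offsets, demographics and transition rates stay at the defaults above
throughout. The end-to-end HC-vs-AD check runs under an explicit
strong-effect condition — atrophy concentrated in the hippocampal columns
at 20% of full severity (per-feature Cohen's d around 3), other groups at
their defaults — because that check asks whether a clearly learnable,
anatomically localized signal is in fact learned and attributed to the
right region, not what the pipeline squeezes out of a marginal one; a
24-subject test set quantizes MCC too coarsely to grade marginal signals
reliably.

## Known limitations

* The evolutionary search is restarted per algorithm and per feature
  source; nothing is shared across tasks, which is transparent but not the
  cheapest possible search.
* Probability calibration of the base learners is inherited from the
  underlying implementations (Platt scaling for the SVM, empirical leaf
  frequencies for trees); the soft vote averages heterogeneous
  calibrations.
* The stacker consumes only the three binary probabilities; it cannot
  recover information a binary ensemble discarded.
* `balance_sources()` down-samples; with many sources or very skewed
  source-by-diagnosis tables it can discard a substantial fraction of
  subjects, and it errors rather than extrapolating when a cell is empty.
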