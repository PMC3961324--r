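---
title: "Precision-recall curves for weighted test data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-recall curves for weighted test data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpr)
```

## The evaluation problem

A binary classifier assigns a score $s_i$ to each test data point; sweeping
a threshold $t$ over the scores and predicting "foreground" whenever
$s_i \ge t$ produces a series of confusion matrices, summarized by the ROC
curve (true positive rate against false positive rate) or the
precision-recall (PR) curve.  In many applications the test labels are not
certain: each point $i$ instead carries a non-negative *foreground weight*
$w_{fg,i}$ and *background weight* $w_{bg,i}$.  These soft labels may be
class-membership probabilities, measured signal strengths in the two
conditions, or multiplicities of indistinguishable points; hard labels are
the special case $(w_{fg}, w_{bg}) \in \{(1,0), (0,1)\}$.

With weights, the confusion matrix at threshold $t$ accumulates weight
rather than counts:
$TP(t) = \sum_{s_i \ge t} w_{fg,i}$, $FP(t) = \sum_{s_i \ge t} w_{bg,i}$,
and complementarily for $FN$ and $TN$.  Precision $TP/(TP+FP)$, recall
$TP/R_{fg}$ (with $R_{fg} = \sum_i w_{fg,i}$), and the ROC coordinates all
carry over unchanged.  The `wpr_sample` object holds the scored, weighted
points; `supporting_points()` computes the full threshold sweep in one
pass of cumulative sums over the score-sorted points, one confusion matrix
per distinct score value plus a sentinel above the maximum score that
anchors $TP = FP = 0$.

Two conventions are fixed package-wide rather than configurable, so every
module agrees: a point is predicted foreground iff its score is *greater
than or equal to* the threshold (the choice only matters when a threshold
coincides exactly with a score), and tied scores merge into a single
threshold step — no confusion matrix exists "inside" a tie group.

## Interpolation between supporting points

Linear interpolation between adjacent ROC points is exact, because both
coordinates are linear in the interpolated confusion matrix; `auc_roc()`
is therefore a plain trapezoidal rule, valid for weighted and unweighted
data alike.  PR curves are different: interpolating the confusion matrix
linearly between two supporting points $A$ and $B$ (with $TP_A < TP_B$)
makes the false positives a linear function of the true positives,
$FP(TP) = FP_A + s\,(TP - TP_A)$, $s = (FP_B - FP_A)/(TP_B - TP_A)$, so
precision as a function of recall $p = TP/R_{fg}$ is the hyperbola

$$\mathrm{prec}(p) = \frac{p}{a\,p + b}, \qquad
  a = 1 + s, \qquad b = \frac{FP_A - s\,TP_A}{R_{fg}}.$$

For hard-labeled data, the classical remedy inserts intermediate confusion
matrices at unit steps of $TP$ (*discrete-TP*) or of $FP$ (*discrete-FP*)
and applies the trapezoidal rule.  The unit step is meaningful because it
corresponds to one data point; for weighted data there is no natural step
size, which is why `auc_pr_discrete_tp()` and `auc_pr_discrete_fp()`
refuse real-valued confusion matrices (an explicit `force` flag admits
integer multiplicity weights, where the unit step is again a data point).

The package's central method avoids steps altogether: the hyperbola can be
integrated in closed form over each segment,

$$\int_{p_A}^{p_B} \frac{p}{a\,p+b}\,dp \;=\;
  \frac{1}{a}\left(p_B - p_A - \frac{b}{a}
  \Big(\ln(a\,p_B + b) - \ln(a\,p_A + b)\Big)\right),$$

with natural logarithms, reducing to $(p_B - p_A)/a$ when $b = 0$
(constant precision).  `auc_pr_continuous()` sums these areas over all
recall-increasing pairs of supporting points; equal-$TP$ pairs span no
recall and contribute nothing, but the later (larger-$FP$) point becomes
the anchor of the next segment, which preserves the curve's vertical
drops.  Because the formula uses only ratios of accumulated weights, it
applies to weighted data directly — that is the point of the package.

Numerical choices: the $b = 0$ branch triggers at
$|b| \le 10^{-12}\max(1, |a\,p_B|)$, because the logarithmic form loses
all significant digits as $b \to 0$ while the limit is exact; cumulative
sums over at most tens of thousands of double-precision weights keep
round-off far below the $10^{-12}$ reproducibility contract asserted in
the tests; and curve files are serialized with 17 significant digits so
they round-trip doubles exactly.

### Relations between the interpolations

Where a segment of the continuous curve is linear, all interpolations
coincide: vertical segments ($TP_B = TP_A$) and horizontal segments, which
arise exactly when $TP/FP$ is equal at both endpoints ($b = 0$).  All
intermediate points of both discrete interpolations lie *on* the
continuous curve — the discrete curves are polygonal chords of the same
hyperbola — so the discrete areas converge to the continuous one as
segments get finer, and the interpolation with more intermediate points
hugs the continuous curve most closely.  These accordance and containment
properties are asserted exactly (to $10^{-12}$) in the test suite.

### The zero-recall end of the trapezoid

Precision at $TP = FP = 0$ is the undefined ratio $0/0$; the continuous
integral handles recall $0$ as a one-sided limit of the first
recall-increasing segment's hyperbola, which is $1/a$ when that segment
starts at $FP = 0$ and $0$ when background mass sits above the first
foreground score ($b > 0$).  For the discrete trapezoids the package
assigns the zero-recall anchor exactly this limiting precision, so that
all three methods integrate the same recall range $[0, 1]$.  The
alternative of dropping the anchor would silently remove the recall
interval up to the first intermediate point — a systematic bias of order
$\mathrm{prec}/R_{fg}$ that would dominate every small-sample comparison
between the methods; with the limit anchor, observed discrete-vs-continuous
differences measure interpolation shape only.

## Attainable extremes and the random baseline

For fixed weights, AUC-PR depends on the scores only through the ordering
of the data points.  The maximum is attained exactly when points are
ranked by non-increasing foreground confidence, and the minimum in the
reverse order.  The implemented sort key is $w_{fg}/(w_{fg}+w_{bg})$,
monotone-equivalent to the odds $w_{fg}/w_{bg}$ but well defined for pure
foreground points.  Points with equal ratio lie on one constant-precision
hyperbola, so their mutual order is irrelevant; ties are kept stable by
input index and the irrelevance is asserted by test rather than assumed.
No closed form exists for the extreme values; `auc_pr_extremes()` scores
the two extreme orderings and integrates.  For unweighted data the
maximal ordering separates the classes, so the maximum is $1$; as soon as
one point carries both foreground and background mass, the full-recall
precision falls below $1$ and so does the maximum.  The minimum is always
strictly positive: even the worst ordering ends at the common curve point
(recall $1$, precision equal to the class ratio).  `normalized_auc_pr()`
rescales any AUC-PR by these bounds.

Random guessing is represented by an ensemble: `random_baseline()` draws
$m$ i.i.d. uniform score vectors (almost surely tie-free, matching the
idea of a random score-based classifier), computes the continuous AUC-PR
of each, and summarizes by median and quartiles under the standard
linear-interpolation quantile convention.  The ensemble median sits near
the class ratio $R_{fg}/(R_{fg} + \sum w_{bg})$ for weighted and
unweighted data, making the class ratio the chance level of AUC-PR.

## What the simulators emulate

**Binned Gaussian scores** (`simulate_scores()`): foreground scores
$N(\mu, 1)$ with $\mu \sim N(1.64, 1)$ redrawn per replicate, background
scores $N(0, 1)$, class ratio 1:10 (defaults 10 vs 100 points).  The
center 1.64 pairs with the 1:10 ratio through the Gaussian quantile
function; drawing $\mu$ with spread 1 spreads the per-replicate AUC
values roughly uniformly instead of piling them up, so interpolation
differences are probed across the whole AUC range.  Scores are then
discretized to `n_bins` equal-width bins over the pooled per-replicate
range, bin midpoints becoming the scores — the binning rule is the
package's own concrete choice for "sampling scores from a limited number
of bins", and it bounds the number of distinct scores (hence supporting
points) by `n_bins`.  `interpolation_difference_experiment()` runs this
model and tabulates per-replicate $|$AUC-PR(discrete-TP) $-$
AUC-PR(continuous)$|$; with 10 foreground points and 10 bins the maximum
over 1,000 replicates is of order 0.03 with nine tenths of the mass below
about 0.01, and it shrinks by more than an order of magnitude at 1,000
foreground points or 1,000 bins.  The package default of 1,000 replicates
keeps one experiment at a few seconds; the count is a config field.

**Beta-mixture soft labels** (`simulate_weights()`): foreground weights
from $0.9\,\mathrm{Beta}(1.2, 8) + 0.1\,\mathrm{Beta}(8, 1.5)$,
$w_{bg} = 1 - w_{fg}$, for 10,000 points.  The mixture is the package's
choice of a bimodal weight histogram — most points lean clearly to one
class, a minority is ambiguous — calibrated so that hard-thresholding
$w_{fg}$ at 0.5 yields a class ratio near 1:9.
`build_good_permuted_bad()` then draws one pool of class-conditional
Gaussian scores (foreground mean at the Gaussian quantile matching the
hard class ratio) and assigns them within each hard class sorted by
$w_{fg}$ (*good*), randomly (*permuted*), or reversed (*bad*).  The three
classifiers share the multiset of (score, hard label) pairs, hence
identical unweighted ROC and PR curves, while weight-aware curves order
them good $>$ permuted $>$ bad — the demonstration that weights add a
dimension that hard-label evaluation cannot see.  Because scores are
sorted per class, even the good classifier stays below the unconstrained
maximum.

**Logistic soft labels and border stability** (`logistic_weighting()`,
`stability_experiment()`): a continuous signal (an intensity-like Gaussian
bulk with a small high-signal component) is soft-labeled with a logistic
function equal to 0.5 at the hard threshold, and a panel of signal-plus-
noise classifiers is evaluated at two borders, mean $+1$ sd and mean
$+2$ sd of the signal.  The correlation of AUC-PR across the two borders
is higher for the weighted than for the hard-labeled evaluation — the
weighted measure degrades gracefully when the (always somewhat arbitrary)
border moves.  The two borders are closer together than in large-scale
intensity datasets because at a few hundred points per dataset a
four-standard-deviation cut would leave no foreground.

All simulators are bit-reproducible given their config and seed.

## What the tests do and do not show

The synthetic generators produce exchangeable Gaussian or beta-distributed
data with exactly the stated class ratios; real score distributions are
heavier-tailed, ties are structured rather than induced by binning, and
real soft labels need not be complementary ($w_{fg} + w_{bg} \ne 1$ is
supported by the data model, and exercised with general non-negative
weights in the property tests, but not by the headline simulations).
Passing tests therefore validate the *computations* — exact segment areas
against quadrature, rank statistics, extreme orderings against stochastic
search — and the *qualitative* claims (ordering, convergence, stability),
not the numeric values any particular real dataset would produce.

Known limitations: multi-class problems, confidence bands on curves,
average-precision-style approximations and partial AUCs are out of scope;
the discrete interpolations are deliberately unavailable for non-integer
weights; and the extreme orderings are exact only up to the stated tie
convention, which the tests show to be inconsequential for the areas.

## Problem sizes used in the packaged experiments

The packaged tests and the acceptance script run the interpolation
comparison at 1,000 replicates (10 vs 100 points, 10 bins) plus 100
replicates at 1,000 vs 10,000 points; the good/permuted/bad study on 20
seeds of 10,000 points; the stochastic-search check of the extremes with
5,000 random orderings plus all adjacent transpositions on 20-point
samples; and the stability study on 25 datasets of 400 points, sizes the
package adopts as its standard desk-scale experiment set.
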