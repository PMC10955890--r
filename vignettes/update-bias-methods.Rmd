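---
title: "Modelling self-evaluation updating after social feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-evaluation updating after social feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(feedbackbias)
```

## The scientific problem

In a judged public-speaking task, participants rate 40 performance
attributes on a 0--10 visual-analogue scale at several time points: before
the speech (pre-speech self-efficacy, y1), right after it (post-speech
self-evaluation, y2), and again after receiving fictitious judges'
feedback (post-feedback self-evaluation, y4, and post-feedback
self-efficacy, y5). Each attribute also carries the judges' score itself
(y3), which is experimenter-controlled: half the items receive neutral
feedback (scores 4--6) and half positive feedback (7--10), drawn from a
fixed composition (4x6, 5x7, 6x7, 7x5, 8x7, 9x6, 10x2).

The question is whether positive feedback is incorporated into
self-beliefs more strongly than neutral feedback, and whether individual
differences in that *positive update bias* relate to symptom dimensions
such as social anxiety, depression and low self-esteem.

## The model

For each subject $s$ and item $q$, the five scores are modelled jointly as
multivariate normal with a subject-level mean vector and a covariance
matrix that depends on the feedback condition:

$$ y_{1:5,s,q} \sim \mathcal N(\mu_s, \Sigma_{\text{Pos},s}) \quad
   \text{if } y_{3,s,q} \ge 7, \qquad
   y_{1:5,s,q} \sim \mathcal N(\mu_s, \Sigma_{\text{Neu},s}) \quad
   \text{otherwise.} $$

Each covariance decomposes as
$\Sigma_s = \mathrm{diag}(\tau_s)\,\Omega_s\,\mathrm{diag}(\tau_s)$ with
$\Omega_s$ a correlation matrix. The y3 component of $\mu_s$ is fixed — the
judges' scores are known by design — at the per-condition schedule means
implied by the printed composition (5.05 neutral, 8.25 positive). The
per-subject update-bias indices are correlation contrasts:

$$ \text{self-evaluation update bias} =
   \Omega_{\text{Pos},s}(y_3,y_4) - \Omega_{\text{Neu},s}(y_3,y_4), \qquad
   \text{self-efficacy update bias} =
   \Omega_{\text{Pos},s}(y_3,y_5) - \Omega_{\text{Neu},s}(y_3,y_5). $$

A rival model splits conditions by the sign of the prediction error
(PE = y3 − y2) instead of by absolute feedback valence; observations with
PE exactly zero are modelled with a covariance built from the element-wise
average of the two conditions' $\tau$ and $\Omega$. The two models are
compared by 10-fold cross-validated ELPD with the two-standard-error
preference rule.

Ratings are modelled unstandardized on the 0--10 scale, as continuous and
unbounded normals. This is a deliberate simplification — a censored or
Beta-CDF likelihood would respect the bounded discrete scale but is
computationally disproportionate — and the synthetic-data generator
quantifies its cost: with discretization switched on, the
Kolmogorov–Smirnov distance between discretized and continuous marginals
stays below 0.1 for scales $\tau \ge 1$.

## Priors and sampling

The posterior is sampled with a fully conjugate Gibbs sampler written in
C++ (RcppArmadillo). The hierarchy is chosen so that every full
conditional is exact:

* subject precision matrices
  $\Sigma_{s,c}^{-1} \sim \mathcal W(\nu_0, (\nu_0\Lambda_c)^{-1})$ with
  $\nu_0 = 7$, so each subject's covariance is partially pooled toward a
  condition-level scale $\Lambda_c$ with prior weight equivalent to 7
  pseudo-items (against 20 real items per condition);
* group scales $\Lambda_c \sim \mathcal W(7, \mathrm{diag}(2.25)/7)$,
  i.e. a weak prior centred on a score SD of 1.5 on the 0--10 scale;
* free subject means pooled as
  $\mu_{s,j} \sim \mathcal N(\eta_j, \sigma_j^2)$ with
  $\eta_j \sim \mathcal N(5, 25)$ and
  $\sigma_j^2 \sim \text{Inv-Gamma}(2, 2)$.

A uniform-over-correlations prior with half-normal scales would be the
other natural choice; we prefer the conjugate family because the exact
block updates mix fast (no step-size tuning, no divergences by
construction) and because at 40 items per subject the likelihood dominates
either prior. The τ/Ω decomposition is recovered from each Σ draw
deterministically, so the bias indices are exact functions of the draws.

Two sampling profiles are provided. The `"paper"` profile mirrors the
study configuration: 4 chains, 1500 warmup iterations, 10,000 post-warmup
iterations thinned by 4 (10,000 retained draws). The `"ci"` profile used
throughout the test suite runs 4 chains with 500 warmup and 500 retained
draws each. Convergence is checked with split-chain R-hat (< 1.1) and
effective sample size; the study's ESS floor of 1000 corresponds to 10% of
the 10,000 retained draws, and the same 10% fraction is applied at reduced
settings. In the PE-split model the fixed y3 means are the per-label
empirical means, because PE-sign labels do not coincide with the schedule
conditions. Zero-PE observations enter the subject-mean update through the
averaged covariance but are excluded from the two conditions' scatter
updates; this keeps the sampler exact and makes the averaged-covariance
rule an explicit modelling statement rather than a prior-only hint.

Group-level bias is summarized by taking, on every posterior draw, the
median of the per-subject bias values; the 95% highest-density interval of
that distribution (shortest contiguous window on the sorted draws) must
lie above zero to establish a group-level positive bias.

## The feedback-assignment algorithm

The generator assigns the fixed score composition to items in a partially
randomized way: a uniformly random 20/20 condition split and a random item
order, with each item receiving a uniformly random score from the
remaining inventory of its condition subject to the prediction-error band
[−2, +4]. When no in-band score remains (extreme expectations), the next
smallest error is taken, preferring the positive direction on ties (+5
over −3, keeping the feedback positively biased). At most four items may
have PE = 0; the whole split is redrawn (up to 1000 times) if the cap
binds, and an error naming the binding constraint is raised when no split
can satisfy it (e.g. when every item's expectation equals a plentiful
score). Expected scores are rounded to the nearest integer before PE
bookkeeping, since "feedback equals expectation" is an exact event on the
VAS grid. Trial order is drawn by rejection sampling, which is exactly
uniform over orderings with no more than two consecutive same-condition
trials.

The paper's task description does not say how condition labels were
matched to items; the uniform re-drawn split is our choice, and the
retry cap is diagnostic rather than load-bearing.

## The synthetic cohort

Because the study data are not public, every downstream stage is exercised
on synthetic cohorts with known ground truth. The generator conditions on
y3 — each subject's schedule fixes the judges' scores, and (y1, y2, y4,
y5) are drawn from the 4-dimensional conditional normal given y3
(Schur-complement conditioning) — so condition labels are exact and
recovery is well-posed. Population defaults are anchored to the study
scale: means (5.28, 4.97, 5.62, 5.85) for the four free scores, scales
around 0.9--1.4, and a base correlation matrix with moderate couplings
among the self-ratings and anchored feedback couplings
$\Omega(y_3,y_4) = \Omega(y_3,y_5) = 0.45$ in the neutral condition.
The planted biases shift the positive-condition cells; the anchor at 0.45
keeps the whole planted range $[-0.3, 0.5]$ inside the positive-definite
cone of the base matrix (extreme biases on *both* cells at once are
geometrically impossible for any fixed base — if $\Omega(y_3,y_4)$
approaches 1, y4 behaves like y3 and the remaining cells are forced).
Subjects are jittered around the population: correlations on the Fisher-z
scale (SD 0.05) with projection to the nearest valid correlation matrix,
means normally (SD 0.5), scales log-normally (SD 0.1). The recorded ground
truth is always the realized matrix difference, so truth is exact even
when projection nudges a cell.

What the generator does *not* emulate: bounded discrete ratings (unless
`discretize = TRUE`), item-level heterogeneity (attributes are
exchangeable), order effects, and any dependence of y2 on the schedule
(expected scores used to build each schedule are drawn around the
subject's y2 mean, not equal to the sampled y2). Passing recovery tests on
this cohort therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to real-data violations of them.

The questionnaire battery (12 scales) is generated from two latent
factors — social sensitivity and self-negativity — plus scale-specific
noise, with self-esteem loading negatively on self-negativity and the
SPSRQ reward scale left mostly unique (mirroring a battery in which one
scale forms its own residual component). The self-negativity factor is
given a configurable correlation with the true self-efficacy bias
(default −0.29). This generator is a stand-in for testing the PCA stage;
the paper does not describe the scales' joint distribution.

## Problem sizes and numerical choices

The test suite and the acceptance script use these sizes, chosen to make
each check informative at desk scale:

* generator compliance: 1000 random task instances;
* parameter recovery: one 50-subject x 40-item cohort with true
  self-efficacy bias evenly spaced over [−0.3, 0.5], reduced (`"ci"`)
  sampling — at 20 items per condition the sampling noise of a
  correlation contrast is about 0.24, so the expected truth–estimate
  correlation is only slightly above the 0.7 requirement; this check is
  genuinely stochastic;
* null calibration: 20 cohorts (5 in the test suite) with zero true bias;
* model comparison: 10 cohorts of 20 subjects x 20 items generated under
  the valence model with a 0.5 self-efficacy gap, 10-fold ELPD per model
  with 2 chains x 250 retained draws per fold;
* oracle equivalences: conditional sampler vs a rejection-sampling
  covariance oracle at 50,000 conditional draws against roughly 60,000
  accepted unconditional draws (2% per-entry band); pointwise
  log-likelihood vs direct density evaluation at 1e−8; HDI vs an O(n²)
  exhaustive shortest-window search.

Numerical details: Wishart draws use the Bartlett decomposition through
R's RNG (so chains and results are reproducible from integer seeds, with
no global RNG state leaking between calls); near-singular updates add an
escalating ridge of at most 1e−4 before Cholesky factorization; correlation
projections clip eigenvalues at 1e−6; the HDI window size is
$\lceil 0.95 n \rceil$; ties in the varimax loading signs are resolved by
making each component's dominant loading positive.

## Design choices on open points

* **Cross-validation unit.** Folds hold out whole (subject, item)
  five-score vectors, stratified by condition within subject, so every
  training set retains both conditions for every subject; holding out
  whole subjects would require predicting subject-level parameters for
  unseen subjects, which the model does not define.
* **Point estimate.** Posterior means of the per-draw bias contrasts are
  used for downstream correlations (linear in the draws; medians differ
  negligibly here).
* **Nuisance control.** The PE imbalance
  $\Delta\text{PE} = \overline{\text{PE}}_{\text{pos}} -
  \overline{\text{PE}}_{\text{neu}}$ is regressed out of both the
  component scores and the bias indices before correlating (a
  `residualize` flag selects other conventions).
* **Multiple testing.** The component-bias table reports raw two-tailed
  p-values alongside Benjamini–Hochberg adjusted ones; decisions default
  to the raw values.
* **Mediation.** Case-resampling bootstrap (5000 replicates) with a
  percentile interval on $a\times b$; BCa corrections are deliberately
  out of scope.
* **Sparse PE labels.** PE-sign labels are data-driven; in small samples a
  subject may lack negative-PE items. Direct fits enforce at least two
  items per condition; per-fold training fits relax the floor and let the
  hierarchical prior carry sparse subject-conditions.

## Known limitations

The likelihood ignores the bounded discrete scale; the hierarchy pools
covariances through a single Wishart scale per condition rather than a
richer correlation-level hierarchy; empirical fold-wise refits use reduced
chain lengths; and the questionnaire generator is a two-factor stand-in.
None of these affect the exactness checks (density, HDI, rank statistics),
but recovery and model-preference rates should be read as properties of
the stated synthetic conditions.
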