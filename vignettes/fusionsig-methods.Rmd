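---
title: "Methods: deriving, scoring, and evaluating a fusion signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving, scoring, and evaluating a fusion signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionsig)
```

## Overview

`fusionsig` turns a fusion-labeled expression cohort into a reusable,
signed gene signature and applies that signature to score individual
samples of any other cohort for fusion-like pathway activity. This
vignette documents the statistical model at each stage, the choices we
made where more than one reasonable formulation exists, and what the
bundled simulation does — and does not — establish about behavior on
real tumor data.

## Signature derivation

For each gene the package fits, by maximum likelihood, the logistic
model

$$\mathrm{logit}\,P(\text{fusion}^+)
  = \beta_0 + \beta_1\,\text{expr} + \beta_2\,\text{age}
  + \beta_3\,\text{gleason},$$

and tests $\beta_1$ with a two-sided Wald test. Age (years) and Gleason
score adjust for the two clinical covariates most plausibly confounded
with both fusion status and expression. Genes are ranked by p-value, the
top $K$ kept (default $K = 700$; any value up to the number of
informative genes is accepted), and weighted as

$$w_g = \mathrm{sign}(\hat\beta_1^{(g)})\cdot
  \frac{-\log_{10} p_g}{\max_{g'} (-\log_{10} p_{g'})},$$

so all weights lie in $[-1, 1]$, the most significant gene is anchored
at $|w| = 1$, and the sign records the direction of regulation in
fusion-positive tumors.

Design choices worth making explicit:

* **Weight magnitude.** Only the range and sign of the weights are
  dictated by the signature's definition; the magnitude rule is ours.
  Normalized $-\log_{10} p$ is monotone in significance, reproduces the
  stated range exactly, and is self-normalizing (a lone gene gets
  $\pm 1$). P-values of exactly 0 are clamped to the smallest positive
  double before the log, with a warning; genes whose normalized weight
  is exactly 0 (p-value of 1) are dropped, because a zero weight is
  indistinguishable from absence.
* **Ranking criterion.** Genes are selected by the Wald p-value of the
  expression coefficient. A likelihood-ratio test would be an
  alternative; the Wald test is the standard single-coefficient choice
  and is validated in the test suite against an independent
  Newton–Raphson maximization of the binomial log-likelihood
  (agreement to 1e-6 on the p-value).
* **Gleason encoding.** Numeric (6–9) rather than categorical dummies:
  it is an ordinal severity scale and a single slope costs fewer
  degrees of freedom at modest cohort sizes.
* **Degenerate fits.** Constant expression, rank-deficient designs,
  non-convergent IRLS, and complete separation (fitted probabilities
  pinned at 0/1 together with an exploding standardized coefficient)
  are all flagged `informative = FALSE` and carry coefficient 0 and
  p-value 1. We deliberately do not fall back to penalized fits: that
  would silently mix two estimators across genes. Samples with missing
  age or Gleason are dropped per-fit with a logged count.
* **No multiple-testing correction.** Selection is by rank, not by
  threshold, so any monotone transform of the p-values — including
  BH/Bonferroni adjustment — would select the same genes.
* **Numerics.** IRLS convergence tolerance is 1e-12 on the relative
  deviance change (tighter than the `glm` default, so Wald statistics
  are stable to the last digits we test); standard errors come from the
  Fisher information evaluated at the final coefficients.

## Single-sample scoring

The scorer is a rank-based two-distribution running-sum statistic.
Within one sample, genes are ordered by descending expression (exact
ties broken by ascending gene id, a deterministic rule that makes
scores platform-independent). With magnitudes $v_i \in [0, 1]$ in
ranked order ($v_i = |w_i|$ for signature genes, 0 otherwise), define

$$F(k) = \frac{\sum_{i \le k} v_i}{\sum_i v_i}, \qquad
  B(k) = \frac{\sum_{i \le k} (1 - v_i)}{\sum_i (1 - v_i)},$$

and take $D(k^*) = F(k^*) - B(k^*)$ at the $k^*$ maximizing $|F - B|$
(smallest $k$ on ties). $D \in [-1, 1]$, positive when the weighted
genes crowd the top of the ranking. The named statistic this
reconstructs is published without a printed formula, so the package
treats the exact variant as a configuration detail of this module: the
implementation is isolated behind `running_sum_score()` and the variant
name is recorded in the score metadata rather than claimed as a
faithful reproduction.

**Permutation normalization.** Raw $D$ depends on signature size and
weight profile. Each observed pre-score is therefore divided by the
mean absolute pre-score of $M$ uniform random permutations of the
magnitude vector over the gene universe (default $M = 1000$; the
examples and tests use smaller $M$ since only the scale estimate
depends on it). Division by the mean absolute null — rather than a
z-score — is sign-preserving, maps 0 to exactly 0, and yields the
calibration property that null scores have mean absolute value about 1.

**Up/down combination.** The sample score is the normalized up-set
score minus the normalized down-set score: high means "up-genes high
AND down-genes low". Both sets share one permutation stream per
(sample, master seed), derived deterministically, which gives exact
antisymmetry — negating every weight negates every score bit-for-bit —
and byte-identical reruns at a fixed seed. Genes in the matrix but
outside the signature participate as background with magnitude 0;
signature genes missing from the matrix are dropped with a warning.

## Evaluation

* **Group comparisons** use the two-sided Wilcoxon rank-sum test: exact
  enumeration when the pooled size is at most 12 with no ties, normal
  approximation with tie and continuity correction otherwise. Sidedness
  is not dictated by the method; two-sided is the conservative default.
* **Classification** reports the Mann–Whitney AUC (pair counting, ties
  one half) and the threshold-sweep ROC curve.
* **Survival** stratifies at the score median — ties at the threshold
  go to the low group, a fixed deterministic rule — and compares groups
  with Kaplan–Meier curves and the standard log-rank chi-square
  (observed minus expected events, hypergeometric variances, 1 df). No
  follow-up horizon is applied; censoring is taken as given in the
  input. Cohorts with no events, or where one group contributes no
  events, are flagged degenerate rather than silently reported. The
  direction of a survival association (whether the high-score group
  does worse) is reported per stratum as the high group's
  observed-minus-expected event excess; it is a property of the cohort,
  not of the method, and in real fusion-negative versus fusion-positive
  strata it can point in opposite directions.
* **Correlations** are Spearman rank correlations with the t
  approximation for the p-value. Comparisons of immune-infiltration,
  mutation-burden, or copy-number covariates between fusion groups are
  realized generically: any numeric clinical column can be contrasted
  via the rank-sum test or correlated with the score. No infiltration
  inference is performed; such covariates are consumed precomputed.
* All p-values are reported unadjusted.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes:
two fusion groups with a latent pathway activity (1 in fusion-positive,
0 in fusion-negative samples), a block of signal genes shifted by
$\pm\,\delta \times \text{activity}$ on a log-intensity-like Gaussian
scale, independent clinical covariates, and right-censored survival
from an exponential proportional-hazards model with log-hazard
$\log h_0 + \gamma \times \text{activity}$.

Defaults: 2000 genes, 300 samples, 50% fusion-positive, 200 signal
genes (half up), effect size 1.5 noise-SD units, noise SD 1, age
$\mathcal N(62, 8^2)$ years, Gleason probabilities (0.25, 0.45, 0.20,
0.10) over 6–9 making Gleason 7 the most common grade as it is at
diagnosis, baseline hazard 0.05 and censoring rate 0.02 per abstract
time unit (about 70% observed events at $\gamma = 0$), and hazard
coefficient 1. These are intended as a realistic mid-size
expression-profiling cohort; the expression scale is deliberately
simple because the scorer consumes only ranks.

Two structural options mirror observed features of real cohorts: an
`activity_jitter` for continuous activity variation, and an
`erg_other_fraction` that relabels part of the fusion-negative group as
`erg_other` with activity 1 — emulating ERG fusions with partners other
than TMPRSS2, which produce fusion-like expression without the
TMPRSS2–ERG label. The prevalence of that subpopulation is not well
characterized, so it is exposed as a free parameter (default 0) rather
than fixed. Gleason is generated independently of fusion status because
the analysis treats it as a covariate, not a mediator.

What the generator does **not** emulate: count noise and
mean–variance coupling of sequencing data, batch and platform effects,
correlated co-expression modules, non-proportional hazards, and
informative censoring. Passing tests on simulated cohorts therefore
demonstrate the correctness and calibration of the algorithms under
the stated model — not the biological validity or portability of any
particular signature on real tumors, which depends on data the package
does not ship.

## Validation strategy and problem sizes

The test suite checks every computational core against an independent
oracle: the running-sum statistic against a brute-force loop over all
cut positions (exact equality, 1000 random instances up to 50 genes),
the permutation normalizer against a replay of the same seeded
permutation stream, the logistic Wald test against a Newton–Raphson
likelihood maximizer, the exact Wilcoxon p against full assignment
enumeration (all size splits up to pooled n of 10), the AUC against
exhaustive pair counting (n up to 30), and the log-rank chi-square
against a hand-computed four-sample value (49/17). Property tests cover
rank invariance under monotone transforms, exact antisymmetry,
pre-score bounds, null-score calibration, sample-order invariance of
derivation, and monotonicity of signal recovery in effect size.

Simulation studies use cohorts of 150–2000 genes and 60–400 samples
with 25–200 permutations per sample: large enough for the parameter
recovery, null-calibration (200 replicates), and prognostic-power (50
replicates) studies to be statistically meaningful, small enough to
keep the whole suite interactive. The permutation count only sets the
precision of the per-sample scale estimate, so reduced $M$ in the
replicate studies trades nothing but a little score noise.

## Known limitations

* The weight-magnitude rule and the exact running-sum variant are
  reconstructions of an under-specified published procedure; both are
  isolated behind single functions so alternatives can be swapped in,
  and score metadata records the variant used.
* Per-gene logistic fits ignore gene–gene correlation; the signature is
  a marginal-association signature, not a multivariate model, and no
  stability selection or cross-validation of $K$ is attempted.
* Scoring cost grows as samples × permutations × genes; at the default
  $M = 1000$, cohorts of several hundred samples take a few minutes.
* Survival evaluation is limited to two-group log-rank comparisons;
  Cox modeling with covariates is out of scope.
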