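---
title: "Decoding dual-format attentional templates: models and methods"
author: "attmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding dual-format attentional templates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attmvpa)
```

## The scientific problem

When observers prepare to attend to a visual feature — say, a leftward
rather than a rightward orientation — the brain holds an *attentional
template* of the target before any stimulus appears.  Two representational
formats are possible during this preparation period: a *sensory-like*
format, in which preparatory activity patterns resemble the patterns evoked
by actually perceiving the orientation, and a *non-sensory* format that
carries the task variable without resembling perception.  A third
possibility is that both coexist, with the sensory-like component held in a
*latent* (activity-silent) state that ordinary BOLD patterns do not betray,
but that a high-contrast task-irrelevant probe stimulus (a "ping") can
momentarily reactivate.

`attmvpa` implements the complete multivariate fMRI analysis stack with
which such a dual-format account can be tested, together with a
ground-truth simulator in which every component of the account is an
explicit, switchable parameter.  The package therefore supports two uses:
analyzing trial-by-voxel pattern data organized the way this task family
produces them, and validating the entire analysis chain by checking that it
recovers known ground truth — and stays silent when the ground truth is
null.

## The generative model

Each simulated subject has, per region of interest (ROI) $r$, a baseline
pattern $\mu_r$, a unit *sensory axis* $s_r$, and a unit *attention axis*
$a_r$ with $s_r \cdot a_r = 0$.  Orthogonality makes "non-sensory" literal:
activity along $a_r$ has zero projection on the axis that perception
engages, so the null hypothesis of the cross-task generalization test is
exactly true when the latent component is switched off.  Both axes are also
orthogonal to the uniform direction, so none of the modulations below moves
the ROI-mean response; this makes the dissociation between informational
connectivity and mean-BOLD connectivity structural.

With orientation sign $o \in \{-1, +1\}$ (leftward/rightward), trial
patterns are:

* preparation:
  $x = \mu_r + \eta_t\, o\, \beta_{att}\, a_r
       + \mathbb{1}[\mathrm{ping}]\, \lambda_r^{(t)} o\, \beta_{sens}\, s_r
       + \varepsilon$
* stimulus selection:
  $x = \mu_r + \eta_t\, o\, \beta_{att}\, a_r
       + o\, (\gamma_T - \gamma_D)\, \beta_{sens}\, s_r + \varepsilon$
* perception (single gratings):
  $x = \mu_r + o\, \beta_{sens}\, s_r + \varepsilon$

with noise $\varepsilon \sim N(0, \Sigma_r)$ where
$\Sigma_r = \mathrm{diag}(d) + WW^\top$ is heterogeneous-diagonal plus
rank-3 shared components.  The low-rank part matters: it makes Mahalanobis
distance genuinely different from Euclidean distance, so the covariance
handling of the distance and classifier code is actually exercised.

The remaining machinery encodes the three cross-cutting effects the
pipeline is supposed to detect:

* **Ping gating.**  $\lambda_r \in [0, 1]$ is non-zero only in the ROIs
  that host a latent sensory-like template (defaults: V1 and EVC) and the
  term it scales contributes only in the Ping session.  The ping is
  modeled as a gain on a pre-existing sensory axis, not as a new axis:
  reactivation of a latent trace, not creation of one.
* **Trial-gain coupling.**  $\eta_t = 1 + g z_t + \xi_{t,r}$, where $z_t$
  is shared across ROIs within a trial and $\xi_{t,r}$ is ROI-private.
  $g \ge 0$ is the single knob behind informational connectivity.
* **Behavior coupling.**  The effective ping gain on trial $t$ is
  $\lambda_r^{(t)} = \lambda_r \max(0,\, 1 + \pi_s + u_t)$ with a
  subject-level propensity $\pi_s$ and a trial-level fluctuation $u_t$,
  and reaction times are
  $RT_t = rt_{0,s} - b_{rt} (\pi_s + u_t) + \text{noise}$.  With
  $b_{rt} > 0$, subjects (and trials) with stronger reactivation respond
  faster — the generative counterpart of the observed negative
  AMI–RT correlation and the strong/weak modulation contrast.

### Design metadata

The default `sim_config()` mirrors the study design: two sessions of 20
subjects with 14 completing both, four ROIs (V1, EVC, IPS, PFC) of 100
voxels, six attention runs and three perception runs per subject, 80%
long-delay trials, and a 2-s TR.  With 40 attention trials per run and a
near-threshold accuracy of 0.75, the filtering rules leave roughly 72
long-delay correct trials per attention condition.  Short-delay trials are
generated with no preparation signal of interest; they exist so the
filtering path is exercised on realistic input.  Correctness is Bernoulli
at a subject-level accuracy; incorrect trials likewise exist to be
filtered.

### Calibration of the effect sizes

Single-trial pattern SNR is not recoverable from published summary
statistics, so the default amplitudes were calibrated once against the
macroscopic benchmarks of the task family and then frozen:
attention decoding around 0.70–0.80, cross-task generalization at chance
without the ping and around 0.65–0.73 in V1/EVC with it, selection-period
generalization around 0.75 everywhere, subject-level AMI positive in
essentially all Ping-session subjects, and an inter-subject AMI–RT
correlation near $-0.5$.  The defaults (`effect_params()`):
$\beta_{sens} = 1.6$, $\beta_{att} = 1.1$, $\lambda_{V1} = 0.6$,
$\lambda_{EVC} = 0.5$, $\gamma_T = 1.0$, $\gamma_D = 0.3$, unit noise
scale, $g = 0.3$, $b_{rt} = 0.08$ s.

## The analysis stack

**Preprocessing.**  Per run: linear detrend, discrete-cosine high-pass
regression at 0.01 Hz, and conversion to percent signal change by the
within-run voxel mean.  Trial patterns are the average of samples whose
acquisition onset falls in the half-open window `[onset + 4, onset + 6)` s.
With a 2-s TR this selects exactly one volume; a "2-s window" at a 2-s TR
cannot contain two complete samples, so the half-open sample-onset
convention is a documented package choice (and `window` is configurable).
Filtering keeps long-delay correct attention trials and correct perception
trials, after removing whole runs below 50% accuracy.  Z-normalization is
per voxel within each task-and-period group, pooling both orientation
conditions, using the population SD (denominator $n$) — an arbitrary but
fixed convention that the tests pin down.

**Decoding.**  Fisher linear discriminant with
$w = \hat\Sigma^{-1}(\hat\mu_1 - \hat\mu_2)$, where
$\hat\Sigma = (1-\alpha) S + \alpha\, (\mathrm{tr}\, S / V)\, I$ is the
shrinkage-regularized pooled within-class covariance.  The regularization
is a package choice: with 100 voxels and ~60 training trials per class the
raw pooled covariance is ill-conditioned, so the default is
$\alpha = 0.1$ with a configurable override, and oracle tests pin the
exact formula.  The bias places the boundary midway between projected
class means (the design is balanced); a decision value of exactly zero
goes deterministically to the first class.  Within-task decoding uses
leave-one-run-out cross-validation with trial-weighted pooling.
Cross-task generalization trains one classifier on all three pooled
perception runs and tests it on attention-task trials of one period, with
no cross-validation — training and test data come from different tasks.

**Geometry.**  The Mahalanobis distance from each attention trial to each
perceived-orientation distribution uses the reference mean per orientation
and a single covariance pooled over both perception conditions
(mean-centered within condition) with the same shrinkage rule — the
estimator is a package choice matching the FLD convention, since the
distance itself does not fix it.  Cell means build the 2×2
attended-by-perceived table, and
$\mathrm{AMI} = (D_{diff} - D_{same}) / (D_{diff} + D_{same})$.
Distances default to z-normalized patterns, consistent with the rest of
the MVPA stack, with raw patterns available through the same functions.

**Informational connectivity.**  Trial-wise AMI within the attention task
uses a leave-one-run-out scheme (references and covariance from the
remaining runs).  The per-ROI AMI series — long-delay correct trials
concatenated across runs in acquisition order, aligned by trial identifier
rather than position — are Pearson-correlated between ROI pairs and
Fisher-z transformed, clipping $|r|$ at $1 - 10^{-6}$ so self- and
degenerate correlations stay finite.  Whether the original series were
correlated per run and averaged, or concatenated then correlated, is not
decidable from the text; the package concatenates first and documents it.
The univariate control correlates spatial-mean response series instead.

**Inference.**  Permutation nulls shuffle training labels *within run*
(the package's choice: it preserves per-run class balance and avoids
degenerate folds) and evaluate against unshuffled test labels.  Group
nulls are element-wise means of subject nulls at each permutation index.
P-values use the add-one rule $(1 + \#\{null \ge obs\}) / (1 + n_{perm})$
so they are never exactly zero, and the 95th-percentile decision rule is
reported alongside.  Bonferroni adjustment across the four ROIs is applied
where a family of regions is tested.  Session comparisons are exported as
per-subject tidy tables; omnibus ANOVAs and Bayes factors are routine
statistics outside the package's scope.

## Validation studies and their problem sizes

The acceptance studies (`study_*()` functions, also behind
`scripts/acceptance.R`) run on one CPU in a few minutes each; the sizes
below are the package's reference choices.

* **Type-I calibration**: 500 signal-free experiments
  ($\beta_{att} = 0$, $\lambda = 0$), 4 subjects × 4 runs × 10 trials at
  12 voxels, 200 permutations each, measuring how often the group-level
  95th-percentile rule rejects.  This study exposes a real property of the
  shuffle-training-only scheme: it is *anti-conservative*, rejecting
  signal-free data at roughly twice the nominal 5% rate.  The mechanism is
  that the observed cross-validated accuracy has positively correlated
  folds — the true labeling serves as training labels in one fold and as
  test labels in another, so the same cross-run alignment terms enter two
  fold accuracies with the same sign — whereas shuffling only the training
  labels breaks exactly that coupling, so the null underestimates the
  variance of the observed statistic (by roughly 1.3–1.7× in these
  conditions, independent of run, trial, and voxel counts).  A fully
  exchangeable variant, in which the permuted labels are used both for
  training and for scoring the held-out predictions, calibrates exactly;
  the package nevertheless implements the scheme in its stated
  train-shuffled/test-unshuffled form because that is the procedure this
  analysis family uses, and quantifying its behavior honestly is precisely
  what the calibration study is for.  Users who need exact type-I control
  can build the exchangeable variant from `loro_decode()` plus their own
  label shuffle, as the calibration analysis itself does.
* **Dual-format recovery**: 20 cohorts at the full study-analog design
  (20 subjects/arm, 14 shared, 100 voxels, ~72 trials/condition).  For
  these cohort-level determinations the package uses one-sided one-sample
  t-tests of accuracy against chance across subjects with Bonferroni
  adjustment over ROIs — the standard group test for a simulation study
  at this scale, where re-running the full permutation machinery for
  every cell of every cohort would add nothing but runtime.  A cohort
  shows "the signature" when attention decoding is significant everywhere,
  preparation-period generalization is significant in V1/EVC of the Ping
  arm only, and selection-period generalization is significant everywhere.
* **Geometry recovery**: 15 single-subject replicates per condition at
  100 voxels; the interaction contrast $D_{diff} - D_{same}$ should be
  positive in at least 80% of replicates with the ping gain on, and near
  a coin flip with it off.
* **Connectivity coupling**: $g \in \{0, 0.3, 0.6\}$, 10 cohorts of 6
  subjects; the median cohort-mean V1–PFC informational connectivity
  should be nondecreasing in $g$ while the mean-BOLD control stays inside
  its $g = 0$ band.
* **Behavior coupling**: 20 Ping-arm cohorts of 16 subjects; with
  $b_{rt} > 0$ the inter-subject AMI–RT correlation should be negative in
  at least 80% of cohorts and strong-modulation trials faster than
  weak-modulation trials; with $b_{rt} = 0$ both effects sit in their
  null bands.

## What the simulator does and does not emulate

It emulates the statistical structure the analyses consume: session,
task, and period structure; run counts and within-run orientation balance;
delay probabilities and correctness for the filtering rules; correlated
voxel noise; a coupled trial gain; and behavior linked to the latent
template.  It does **not** emulate physiological noise spectra, motion
artifacts, retinotopic spatial structure, eye position, or hemodynamic
nonlinearities, and its voxel axes have no spatial smoothness.  Passing
recovery tests therefore show that the analysis chain is correct and
calibrated for data of this structure — not that real fMRI satisfies the
model.  Real-data idiosyncrasies (voxel selection from larger masks,
scanner drift beyond the drift model, serial dependence between trials)
are exactly the things a user must still check.

## Numerical and degenerate-input choices

Covariance estimates use Cholesky factorization; an exactly singular
unregularized covariance raises an error recommending shrinkage rather
than silently pseudo-inverting.  AMI with $D_{same} = D_{diff} = 0$ is an
error, not a silent zero.  Zero-variance voxels fail z-normalization with
their indices listed; zero-mean voxels are flagged and excluded during
percent-signal conversion.  Filtering that removes every trial is an
explicit error.  All randomness flows from one master seed through
deterministic child seeds (subject, session, stage), so every dataset,
null distribution, and pipeline manifest is bit-reproducible; `with_seed`
restores the caller's RNG state afterwards.

## Known limitations

* Only two-class linear decoding is provided — no multiclass, kernel, or
  searchlight variants.
* Voxel selection from larger ROI masks is deliberately not implemented;
  synthetic ROIs are generated at their final size, and how the original
  100 voxels per ROI were chosen is unknown.
* The representational-geometry module implements the configured
  pooled-shrinkage estimator only; crossnobis and whitened-correlation
  alternatives are out of scope.
* The mixed ANOVAs and Bayes-factor analyses that compare sessions are
  routine statistics the package exports tables for, not functions it
  provides.
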