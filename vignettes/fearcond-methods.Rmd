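---
title: "Models and methods behind fearcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearcond}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearcond)
```

`fearcond` implements, end to end, the computational core of a two-phase
differential fear-conditioning experiment in which conditioned stimuli are
either *viewed* or *imagined*: constrained trial-schedule generation,
skin-conductance response (SCR) scoring, trial-wise GLM pattern
estimation, ROI multivoxel cross-classification with two-level resampling
inference, and the accompanying group statistics. A synthetic-data
generator stands in for real participants so that every stage can be
exercised, calibrated and power-tested on data whose ground truth is
known. This vignette documents the models, the defaults and the design
decisions.

## The experimental design

Two phases are generated per participant. In the *imagery acquisition*
phase the shock (US) is paired with **imagining** the CS+; in the *visual
acquisition* phase with **viewing** it. Each phase comprises:

* **6 habituation/practice runs** of 8 trials: 2 CS+ imagine, 2 CS−
  imagine, 2 CS+ view, 2 CS− view, fully randomised, never reinforced
  (48 trials; each CS viewed 12× and imagined 12×).
* **6 acquisition runs** of 12 trials: for the conditioned modality 2
  reinforced CS+, 2 non-reinforced CS+ and 4 CS− trials; for the other
  modality 2 CS+ and 2 CS− trials. The CS+ of the conditioned modality is
  therefore reinforced on exactly 50% of its presentations (72 trials per
  phase).

Placement constraints are imposed constructively rather than by
rejection sampling, so generation cannot fail: every acquisition run
begins and ends with a conditioned-modality CS− trial; run 1 places a
reinforced CS+ at trial 2 (to establish the association early) and its
second reinforced trial in the second half of the run; every later run
places one reinforced trial per half. We define the "halves" of a
12-trial run as positions 2–6 and 7–11, excluding the fixed boundary
positions 1 and 12, and apply the one-per-half rule uniformly to every
run after the first rather than to a subset. The visual phase mirrors the
imagery rules with the roles of the modalities exchanged.

Trial timing is a 2 s auditory cue followed by a 4 s CS epoch. Runs fill
73 volumes (habituation) or 109 volumes (acquisition) at TR = 2 s, i.e.
146 s and 218 s. The inter-trial intervals are drawn uniformly and
rescaled so each run fills its stated duration exactly — a seeded uniform
fill, since nothing in the analyses depends on the ITI law beyond
adequate regressor separation. The US is treated as an instantaneous event
co-terminating with the CS epoch; its physical duration is metadata only.

**Analysis-trial exclusions.** Reinforced trials are never analysed (to
avoid a US confound), and the first and last conditioned-modality CS− of
each run are dropped (orienting response; trial-count balance). This
leaves 12 CS+ and 12 CS− analysis trials per modality per phase — exactly
balanced, which the decoding analyses require.

## The synthetic participant

`synth_config()` collects every generative knob. The generator emulates
the *statistical structure* the analyses assume, not biophysics.

**SCR traces.** A tonic level (default 2 µS, optional linear drift) plus
one event-locked response per trial and Gaussian sensor noise. The
response kernel is a sigmoid rise × exponential decay with a 1 s onset
latency and unit peak near 3 s — inside the 1–6 s scoring window and
qualitatively matching electrodermal morphology. Per trial the kernel is
scaled by the condition's mean amplitude (defaults: CS+ 0.4 µS, CS−
0.2 µS in the conditioned modality; 30% of the differential expressed in
the other modality, mimicking weak autonomic generalization) and omitted
entirely with probability `scr_zero_prob` (default 0.25, emulating
non-response trials). Simulation runs at 100 Hz rather than a
hardware-like 2000 Hz; the scorer is sampling-rate invariant (tested), so
the rate is a cost choice only.

**Multivoxel patterns.** Per participant, a random orthonormal triple
spans a shared threat axis and two modality-specific axes; the
discriminative direction of modality *m* is
$u_m = \sqrt{s}\,u_{\text{shared}} + \sqrt{1-s}\,u_m^{\perp}$, where
$s$ = `shared_fraction`, so the view and imagine directions overlap by
exactly $s$ (their inner product). Each analysis trial is
$x = \pm\frac{d}{2}u_m + \varepsilon$, $\varepsilon \sim
\mathcal N(0, I)$, with $d$ = `pattern_effect` in noise-SD units; the
optimal (Bayes) accuracy of within-modality decoding is $\Phi(d/2)$,
which the tests verify by Monte Carlo. The same participant latents are
reused across phases, which is what makes cross-phase transfer possible.
Defaults ($d = 0.8$, $s = 0.6$, 248 voxels — an anterior-insula-sized
ROI) produce modest, above-chance cross-classification. Participant
heterogeneity is a log-normal multiplier on $d$ (SD 0.3 on the log scale)
— multiplicative so that a null effect stays exactly null, keeping
type-I-error studies honest. Pattern noise is isotropic; correlated noise
is a possible extension, not a default.

**BOLD runs.** $Y = XB + E$ with $X$ the package's own trial-wise design
matrix, $B$ standard-normal (or user-supplied) true coefficients and $E$
AR(1) noise (marginal SD `bold_noise_sd`, lag-1 coefficient `ar1_coef`,
default 0.3). True coefficients are returned so estimation can be tested
as parameter *recovery*.

**Ratings.** A latent-normal model on the 7-point scale: latent mean 4
plus a participant intercept (SD 0.5), a CS+ shift (default 1.5 latent
units in the conditioned modality, 60% of that in the other modality —
self-reported fear generalizes more readily than SCR), cell noise (SD 1),
then rounding and clamping to 1–7.

Everything is a deterministic function of (config, participant, seed);
per-module seeds are derived from the global seed by hashing labelled
tags, so one integer reproduces the full experiment.

## SCR scoring

For a trial at onset $t_0$: baseline = mean conductance in
$[t_0, t_0 + 1)$; peak = maximum in $[t_0+1, t_0+6]$ (half-open baseline
and closed peak window, so no sample is counted twice); amplitude =
peak − baseline if that difference exceeds 0.02 µS, else 0 — so scored
amplitudes are either 0 or > 0.02 µS, never negative. Amplitudes are
square-root transformed per trial *before* averaging, and zero trials are
**retained** in condition means (magnitude-style averaging): sub-threshold
trials are scored as zero, not discarded. Condition means use analysis
trials only (no shock trials, no boundary CS−). No latency or rise-time
constraints beyond the 1–6 s window are imposed. A participant whose
amplitude is zero on every reinforced trial is flagged as a non-responder
(`is_nonresponder()`), mirroring the usual exclusion of participants with
no detectable shock response.

## Trial-wise GLM

The HRF is the canonical double-gamma: gamma-density response peaking at
6 s minus a 1/6-weighted undershoot peaking at 16 s, 32 s support, unit
peak (the family is conventional; these are the common default
parameters). Each analysis trial gets its own boxcar regressor (CS
duration, convolved at 0.1 s resolution, sampled at volume times) — a
*least-squares-all* beta-series model: one GLM per run with simultaneous
per-trial columns. Reinforced trials and boundary CS− trials are collapsed
into two nuisance regressors; an intercept (and optional polynomial
drifts) completes the design. With ~11 s mean ITIs the design is well
conditioned; rank deficiency is a hard error.

Estimation is OLS. A scanner-style prewhitening/high-pass pipeline is
deliberately not reproduced: the package's inferential targets (decoding
accuracies and resampling nulls) are insensitive to it at this scale, and
optional drift regressors cover slow trends. "Normalized parameter
estimates" is implemented as per-voxel z-scoring of trial betas within a
run — of the common normalization conventions, within-run z-scoring is the
one that removes run-level scale differences before pattern analysis, and
it is the package's default (`normalize = TRUE`).

## Cross-classification and two-level inference

The classifier is a linear maximum-margin (hinge-loss) SVM with fixed
cost $C = 1$ — no hyperparameter search. It is implemented as a dual
coordinate-descent solver in compiled code operating on precomputed Gram
matrices (bias absorbed by a +1 kernel offset): the two-level inference
refits the classifier hundreds of thousands of times, and a per-fit cost
of microseconds is what makes honest resampling tractable. The test suite
cross-checks accuracies against an independent SVM implementation
(`e1071`).

Feature selection (`select_features()`) is either the whole ROI (the
default for the insula-sized ROI) or the `k = 300` voxels with the
largest mean absolute training-set signal — computed on *training* trials
only so that no test information leaks; ties keep the lowest voxel index
for determinism.

Inference follows the permutation-within, bootstrap-between scheme:

1. **Participant level** — retrain on uniformly permuted training labels
   (test labels untouched) `n_perm` times, recording test accuracy.
2. **Group level** — each of `n_boot` bootstrap iterations draws one
   accuracy per participant (with replacement) and records the group
   mean.
3. The observed group mean accuracy is compared one-sidedly (above
   chance) to the group null with the add-one estimator
   $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{boot})$,
   which can never return 0.

Permutations are independent uniform shuffles, not exhaustive
enumeration. The one-sided comparison reflects that only above-chance
decoding is meaningful here. Reference scale is 10 000/10 000 iterations;
the packaged studies run at 500/500, which leaves the Monte-Carlo error
of $p$ near 0.02 — small against the effects probed. Calibration is
verified empirically: with a zero pattern effect and 8 participants the
group null's mean accuracy sits at 50% (the chance anchor) and the
procedure's type-I error at $\alpha = .05$, over 200 replicate
experiments at 500/500, lies in the nominal band. The strong-signal
regime used in the power checks is `pattern_effect = 6` with
`shared_fraction = 1` ("large" is a package choice: the smallest round
value at which within-modality decoding saturates above 90% despite the
24-trial training sets).

## Group statistics

**Paired t and Cohen's d.** $t = \bar{d}/(s_d/\sqrt n)$, two-sided $p$
on $n-1$ df, and the paired effect size $d = t/\sqrt n$. Zero-variance
differences with a nonzero mean raise a distinct infinite-t error rather
than returning `Inf`.

**JZS Bayes factor.** The default two-sided Jeffreys–Zellner–Siow Bayes
factor for the one-sample test on paired differences with a
Cauchy(0, $r$) prior on standardized effect size, $r = 0.707$ by default:
the marginal likelihood under the alternative, computed by adaptive
quadrature over the prior's inverse-gamma mixture representation
(`integrate` on $(0, \infty)$, relative tolerance $10^{-9}$), divided by
the point-null likelihood. The test suite checks it against an
*independent* oracle that integrates the noncentral-t sampling density
against the Cauchy prior directly — a different integral arriving at the
same number to $<10^{-3}$ relative error. A sensitivity grid over
$r \in \{0.5, 0.707, 1, 1.41\}$ is exposed via `bf_sensitivity()`.

**Repeated-measures ANOVA.** For the 2×2×2 within-subject design every
effect is a single ±1 contrast over the eight cells, so the decomposition
is computed exactly from per-subject contrast scores: with
$D_s = \sum_j c_j y_{sj}$,
$SS_\text{eff} = (\sum_s D_s)^2/(8n)$ and
$SS_{\text{eff}\times s} = \sum_s D_s^2/8 - SS_\text{eff}$, giving
$F = MS_\text{eff}/MS_{\text{eff}\times s}$ on $(1, n-1)$ df. This
reproduces `aov()` with the full `Error(subject/(A*B*C))` stratification
to machine precision (tested) and reduces to $F = t^2$ when only one
factor varies. Effect size is **classical** $\eta^2 =
SS_\text{eff}/SS_\text{total}$ (total over all within-subject sources),
not partial $\eta^2$: classical $\eta^2$ is the variant that can be very
small even for a large $F$ (because subject variance stays in the
denominator), which matches how such designs are conventionally reported;
partial $\eta^2 = F/(F + df_\text{err})$ is easily derived from the table
if wanted.

## Numerical and degenerate-input conventions

* Scored SCR amplitudes live in $\{0\} \cup (0.02, \infty)$; the floor
  comparison is strict (`> 0.02`).
* An all-equal ANOVA cell matrix yields $F = 0$, $p = 1$ (not 0/0).
* Decoding ties ($f = 0$) classify as CS−; permutation and bootstrap
  draws use R's seeded RNG, with sub-seeds derived per participant.
* The SVM solver iterates to a projected-gradient tolerance of
  $10^{-10}$ (cap 1000 sweeps); the Bayes-factor quadrature reports its
  error estimate and fails loudly on non-convergence.
* All schedule generation is constructive, so "constraint-satisfaction
  failure" is unreachable by design.

## Scale choices in the shipped studies

The packaged tests and the acceptance analysis run at desk scale, chosen
as the package's own trade-off between Monte-Carlo error and runtime: 8
synthetic participants, 500 permutations, 500 bootstrap iterations, 200
replicate experiments for calibration and 100 for power. The group-level
conclusions those studies support (chance anchoring, type-I calibration,
transfer monotonicity) are properties of the procedure, not of the
iteration counts; the reference iteration counts (10 000/10 000) are the
defaults of `participant_null()` and `group_bootstrap_null()`.

## What passing tests do and do not show

The generator shares with real data the design's trial bookkeeping, the
event-locked SCR structure, balanced two-class patterns with a
controllable shared subspace, AR(1) BOLD noise and ordinal ratings. It
does **not** emulate spatially correlated pattern noise, haemodynamic
nonlinearity, motion or physiological artefacts, electrodermal drift
beyond a linear term, or non-stationary learning within a run (the
conditioned response is stationary across trials). Green calibration and
power tests therefore validate the *pipeline's statistical machinery*
under its stated assumptions; they do not certify performance on any
particular real dataset.
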