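---
title: "Simulating and analysing a clinical psychoacoustic battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a clinical psychoacoustic battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audbat)
```

`audbat` implements the behavioural methodology of single-case
psychoacoustics in primary progressive aphasia (PPA): a 12-task battery of
pitch, rhythm and timbre tasks, adaptive threshold estimation, and the
statistical pipeline that compares small patient samples (8 SV, 6 NFV,
4 LV) with a control group (n = 28) at the group and at the individual
level. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The battery and its stimuli

Four tasks per domain. Pitch: change detection (p1) and change-direction
discrimination (p2) on pure-tone pairs (250 ms tones, difficulty in
semitones); local (p3) and global (p4) change detection in 4-tone
sequences, where a local change moves the third or fourth tone without
altering the contour of ups and downs and a global change flips the
altered transition. Rhythm (500 Hz, 100 ms tones): single
interval-duration discrimination (r1) and isochrony-deviation detection in
5-tone sequences (r2), both with reference inter-onset intervals (IOI)
drawn per trial from 300–600 ms and difficulty in % of the reference IOI;
metrical-pattern discrimination for strongly (r3) and weakly (r4) metrical
7-tone sequences in beats of 4 (XAB design, difficulty = displacement of
one onset in % of the beat). Timbre: frequency-modulation detection at
2 Hz (m1) and 40 Hz (m2) on a 500 Hz, 1000 ms carrier (difficulty = FM
depth as a fraction of the carrier); dynamic spectro-temporal ripple
detection (m3) and ripple-density discrimination (m4).

Ten tasks are adaptive two-alternative or three-alternative forced choice
(50 test trials); p3/p4 use a fixed-difficulty same–different design of 40
trials (20 "same", 20 "different", each of 20 references once per
condition), scored /40.

Several stimulus-level constants of the original battery are not publicly
documented: the exact reference-frequency inventory, the metrical pattern
set, and the ripple-synthesis constants. The package therefore labels
these as reconstructions: references are drawn near 500 Hz (±2 semitones),
sequence steps are 1.5–3 semitones (so that a 1-semitone local change can
never flip a contour step), the strongly metrical pattern places onsets on
a 16-slot grid containing every beat while the weakly metrical pattern is
syncopated, and ripples are sums of 40 log-spaced carriers (250–4000 Hz)
with a drifting sinusoidal spectral envelope. All of these are parameters,
not hard-coded behaviour, and waveform synthesis exists only for
inspection/export — the analysis operates on parametric trial descriptors.

## Adaptive engine

Responses are generated by a virtual observer with psychometric function

$$\psi(\delta) = \gamma + (1-\gamma-\lambda)\,
  \mathrm{logistic}\!\big(\beta(\log\delta - \log\alpha)\big),$$

with guess rate $\gamma$ = 1/2 (2AFC) or 1/3 (XAB/AXB), lapse rate
$\lambda$ (default 0.02) and slope $\beta$ (default 8, a typical value for
trained listeners on these dimensions). The two-down one-up rule tracks
the level where the probability of two consecutive correct responses is
1/2, i.e. $\psi = \sqrt{0.5} \approx 0.707$.

Choices the published procedure leaves open, and the defaults adopted:

- **Step schedule**: multiplicative, factor 2 until the second reversal,
  then $\sqrt{2}$ — the standard schedule for log-spaced difficulty
  dimensions. Floors, ceilings and starting levels are per-task fields of
  the battery definition.
- **Threshold rule**: geometric mean of the last six reversal levels;
  tracks with fewer than six reversals are flagged `converged = FALSE`,
  get an `NA` threshold, and are excluded from group statistics by the
  missing-value propagation of the analysis stages.
- **Practice phase**: repeated at the common starting level until five
  consecutive correct responses; every ten unsuccessful practice trials
  the level is eased by one initial step (the individual easing the
  protocol allowed for patients). Test trials then start at that level.

With the default observer ($\beta = 8$, $\lambda = 0$), 50-trial runs
estimate the 70.7% point with a relative bias well under 15% (the
acceptance suite measures 5–9% over 200 runs, depending on the seed); the residual bias is the
familiar small-sample overshoot of reversal-based estimators started above
threshold.

## Single-case statistics

The Crawford–Howell modified t-test treats the control mean and SD as
estimates: $t = (x^* - \bar x)/(s\sqrt{(n+1)/n})$, $df = n-1$. Its
defining property — the one the test suite checks by simulation — is an
exact 5% type-I rate at $\alpha = 0.05$ for patients drawn from the
control population, which an ordinary z-score against $n = 28$ controls
would not give. One-tailed p-values are oriented by a per-task deficit
direction registry (thresholds: higher = worse; p3/p4 scores: lower =
worse) and mapped to deficit-positive Z scores via $\Phi^{-1}(1-p)$, with
the corrected criterion $Z > \Phi^{-1}(1 - 0.05/12) = 2.64$. No continuity
correction is applied before the transform.

Covariate adjustment follows the frequentist regression form: candidate
covariates (age and fluid intelligence/CPM by default) are screened by
per-task multiple regression in controls, and any candidate significant
(two-tailed p < 0.05) for at least one task is used for *all* tasks —
the all-or-none rule of the original analysis. The adjusted statistic is
$t = (y^* - \hat y^*)/(s_e\sqrt{1+h^*})$ with leverage
$h^* = x_0^{*\prime}(X_0'X_0)^{-1}x_0^*$ and $df = n-k-1$. The cited
Bayesian variant of this procedure is out of scope. Missing patient scores
propagate as missing and are never imputed; the Bonferroni family stays at
12.

## Group statistics and the transform policy

Outcomes are screened for composite normality with the Lilliefors test
(Dallal–Wilkinson approximation) separately in controls and patients; a
task deviating in either group is log-transformed for both. The screening
level defaults to $\alpha = 0.01$: the policy runs 24 screening tests per
cohort, and at 0.05 roughly one spurious transform per cohort would be
expected, which would make the recovered transform set essentially never
match the generating one. 0.01 keeps the spurious-transform rate near 20%
per cohort while retaining power against genuinely log-normal thresholds;
it is a config parameter, not a constant.

Group contrasts are one-sided (patients worse) pooled-variance t-tests —
the original analysis does not state pooled vs Welch; both are available,
pooled is the default — Bonferroni-corrected across the 12 tasks. Subtype
comparisons use tie-corrected Kruskal–Wallis (at uncorrected 0.05,
following the original procedure) with Tukey–Kramer post hocs on rank
means using the studentized-range criterion and the Kramer unequal-n
correction. Correlation screens (symptom duration and hearing: Pearson;
digit span: Spearman) are two-tailed with multiplied-p Bonferroni
correction over the 12 tasks; factor–battery correlations are one-tailed
in the deficit-consistent direction, corrected by 12 × (number of
factors).

## Subtype classification

Pairwise linear SVMs on the 12 (transformed, per-fold z-scored) outcomes,
with a large finite cost (1000; for z-scored features with order-one
margins this reproduces the hard-margin solution exactly) degrading
gracefully, with a warning, when the training classes are not separated. Evaluation is
leave-one-out — chosen because a reported "2 or 3 of 10 misclassified per
iteration" implies per-case held-out evaluation — and significance comes
from a label-permutation test with add-one smoothing,
$p = (1 + \#\{A_{perm} \ge A_{obs}\})/(B+1)$. Feature weights
$w = \sum_i \alpha_i y_i x_i$ are reported from the full-data fit with a
magnitude ranking.

## Factor analysis

Principal-component extraction on the correlation matrix of the
14-variable neuropsychological battery, eigenvalue > 1 retention, varimax
rotation, regression-method factor scores ($Z R^{-1}\Lambda$, zero-mean
over the fitting sample). These are the conventional defaults of the
commercial package named by the original analysis; whether its printed
loadings are rotated is not stated, but their near-simple structure
suggests rotation, and rotation is the default here. The model is fitted
on controls and patients together, and patient scores are read off —
mirroring the original design. Factors are canonically oriented so the
mean loading is positive (higher score = better cognition); eigenvalues
and variance-explained percentages (100·λ/14) are reported from the
unrotated extraction, matching the usual "extraction sums" bookkeeping.

## The synthetic-cohort generator

`generate_cohort()` draws 28 controls and 18 patients (8/6/4). Its
defaults *are* the study conditions the analyses assume:

- **Thresholds.** Log-normal for {p1, r1, r2, m2, m3} with log-SD 1.1 —
  an order-of-magnitude spread between the best and worst listeners,
  typical of clinical psychoacoustic samples and strong enough that the
  normality screen detects the skew reliably; truncated-normal thresholds
  elsewhere; integer scores (mean 33/32, SD 3.5, max 40) for p3/p4.
- **Deficit profiles** (in control-SD units on the analysis scale):
  NFV with severe, near chance-level deficits on the two sequence tasks
  that dominate its discrimination from LV (p3 and r4, 4 SD) and milder
  deficits on p4, r2, r3 and m4 (1–1.5 SD); SV mildly affected on the
  pitch-sequence and metrical tasks (p3, p4, r3, r4, 1–1.5 SD); LV
  spared. The profile encodes the qualitative pattern reported for this
  population — NFV worst overall and on sequence/rhythm processing, a
  subset of SV cases mildly impaired, LV clinically silent on these
  tasks. The mild SV deficits also keep the patient-group distributions
  unimodal, without which the severe NFV deficits alone would trip the
  normality screen on tasks that the original data did not.
- **Covariates.** The control-side coupling between fluid intelligence
  (CPM) and the pitch-direction task p2 targets r = 0.45. Age is
  generated but has no true effect on any outcome (no age correlation is
  expected under the emulated conditions).
- **Neuropsychology.** The 14 test scores arise from two latent factors
  (semantic, repetition) with a block loading structure (≈0.8 on the own
  factor, two sentence-comprehension variables split across both), scaled
  to realistic integer score ranges. SV carries a −2.5 SD semantic-latent
  shift, NFV −2.5 and LV −1 on the repetition latent; digit span forward
  is driven by the repetition latent and missing for two random patients
  (clinical records are incomplete in practice).
- **Trial level.** `generate_trial_level()` turns each subject into a
  virtual observer whose α is the generated threshold (β = 8, λ = 0.02)
  and replaces outcomes by staircase estimates, so the whole chain
  stimulus → response → staircase → threshold → statistics can be
  exercised.

What the generator does *not* emulate: floor/ceiling compression of real
patient data beyond simple clipping, correlated deficits across tasks
within a patient (each task's deviation is independent given the group
profile), task order or fatigue effects, hearing-level influences, and
any real stimulus acoustics. Passing tests therefore demonstrate that the
*pipeline* behaves correctly under its own distributional assumptions —
calibrated false-positive rates, power against implanted effects,
recovery of generating structure — not that those assumptions exhaust
real PPA data.

## Calibration experiments and problem sizes

The acceptance suite fixes the following experiment sizes, chosen to give
stable Monte-Carlo estimates of each property: 200 staircase runs for the
convergence bound; 10^4 null single-case draws for the type-I rate
(Monte-Carlo SE ≈ 0.2%); 100 cohorts for transform-set recovery; 100
no-deficit pipeline runs for the family-wise error of the headline
analysis; 50 cohorts for the subtype-pattern checks. The "headline" of a
run is defined as the Bonferroni-corrected patients-versus-controls group
contrast — the claim such a study leads with. The subtype Kruskal–Wallis
tests are evaluated at uncorrected 0.05 by design, and the per-patient
single-case family expects ≈0.9 false corrected flags per null cohort
(18 × 12 tests), so neither can sit inside a ≥93%-clean budget; both are
still computed and reported on every run.

## Numerical and degenerate-input choices

Zero-difficulty trials are constructed as identical stimuli, flagged
undecidable, and answered at chance. Staircase levels are clipped to
per-task [floor, ceiling]; thresholds of non-converged tracks are `NA`.
Constant covariate candidates are dropped with a warning; collinear ones
(|r| > 0.999) are an error. A singular neuropsychological correlation
matrix is an error carrying the condition number; eigenvalues within 0.05
of the retention cut set `retention_stable = FALSE` with a warning. All
stochastic stages draw from named substreams of one root seed
(`child_seed()`), so every table, track and report is reproducible from
`(config, seed)` alone; no global RNG state leaks between stages.

## Known limitations

Sample sizes are fixed at the emulated study's (4 LV patients make
LV-involved classifications fragile by construction). The permutation SVM
test at its default 10^4 permutations is the slowest stage and is the
first thing to reduce for interactive use. The covariate-adjusted
single-case test is the frequentist form only. Metrical patterns and
ripple constants are reconstructions, so absolute thresholds for r3/r4
and m3/m4 should not be compared against published group means — only the
statistical machinery around them.
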