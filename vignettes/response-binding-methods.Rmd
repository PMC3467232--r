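---
title: "Measuring response binding in multi-day serial reaction time learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring response binding in multi-day serial reaction time learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtbind)
```

## The task and what the package measures

In a bimanual serial reaction time (SRT) task, eight spatial cues map onto
the eight non-thumb fingers and the cue order secretly cycles a fixed 32-item
sequence. Over ten daily sessions of nine 256-trial blocks (two random
training blocks, five sequence training blocks with an adaptive response
window, then one random and one sequence probe block at a fixed 600 ms
window), responses get faster and more accurate — but the interesting
question is *how*: do individually planned keypresses become temporally
bound into larger chunks, and which parts of the trial-by-trial planning
process change with learning?

`srtbind` implements the analysis chain for this question. All analyses use
only the two daily probe blocks, where the response window is constant, so
none of the measures are confounded by the adaptive window.

Four measurement layers build on each other:

1. **Learning metrics.** Sequence-specific speed is the z-score
   \((\mu_{Random} - \mu_{Sequence})/\sigma_{Random}\), which cancels
   generic (sequence-unspecific) speedup. Per-subject learning rates
   \(\lambda\) are OLS slopes over days 1–10, with a likelihood-ratio test
   choosing between a linear and a quadratic model; for the quadratic model
   \(\lambda = \beta_{lin} + \beta_{quad}\), so saturating learners are
   summarized by their net coefficient sum on the raw day basis (1..10,
   non-orthogonal — the sum is only meaningful on that basis).
2. **Post-error slowing.** The error response function (ERF) is the mean RT
   deviation from the block mean at lags 1–6 after an error; its lag-1 value
   is the post-error slowing (PES) magnitude.
3. **Chunk size from autocorrelation.** If successive response *plans* are
   coupled while execution noise is independent, the coupling surfaces as
   inter-trial autocorrelation of RTs. After dropping the first sequence
   cycle, imputing missing RTs at the mean, detrending and zero-meaning,
   the 31-lag ACF of the sequence probe is tested lag-by-lag against a
   cross-subject null built from the same day's random probes; the chunk
   size is the count of consecutive significant lags from lag 1.
4. **State-space model.** A scalar-state linear dynamical system of
   "response preparedness" \(x_t\) (ms): \(y_t = x_t + D\cdot K_t + r_t\)
   and \(x_{t+1} = A x_t + B\cdot Y_t + F e_t + q_t\), fitted per probe
   block by EM with an exact Kalman filter/RTS smoother. \(A\) (state
   memory) plays the role of the binding coefficient, \(F\) the post-error
   state delay, \(D\) per-key biases, \(B\) the per-key influence of the
   previous press, and \(Q, R\) the planning and motor noise variances.

## The binding toy model and its oracle

The conceptual model behind layer 3 is deliberately minimal: plans follow a
stationary AR(1), \(x_t = \mu_P + \alpha(x_{t-1} - \mu_P) + \mathcal N(0,
\sigma_P^2)\), and outputs add independent execution noise
\(y_t = x_t + \mathcal N(0, \sigma_E^2)\). Its ACF has the closed form

\[\rho(l) = \alpha^{l}\,\frac{\sigma_x^2}{\sigma_x^2 + \sigma_E^2},
\qquad \sigma_x^2 = \frac{\sigma_P^2}{1 - \alpha^2},\]

which `theoretical_acf()` exposes. This is the package's central oracle: the
simulator is validated against it, and it is used to *plant* a binding span
of known size when calibrating the chunk estimator. The canonical simulation
scale is \(\mu_P = 200\) ms, \(\sigma_P = \sigma_E = 10\) ms, 100 blocks of
1000 trials.

```{r}
theoretical_acf(0.75, 10, 10, 1:3)
acf_sim <- binding_acf(simulate_binding(binding_config(0.75, seed = 1)),
                       n_lags = 3)
round(acf_sim$mean_rho, 3)
```

When comparing the simulated mean ACF to the closed form, the 1/n-normalized
estimator's expectation is lower than \(\rho(l)\) by approximately
\((1 + 2\sum_k \rho(k))/n\); the test suite compares against this corrected
expectation rather than pretending the estimator is unbiased.

## Numerical and inferential choices

**ACF normalization.** The biased (1/n) autocovariance estimator is used at
all 31 lags: it keeps \(|\rho| \le 1\), is the common signal-processing
default, and its small-sample bias is accounted for where it matters (see
above). `acf31()` refuses series shorter than 63 trials.

**Chunk test sidedness and direction.** The per-lag test is two-sided at a
Bonferroni-corrected \(\alpha/31\), but a lag only counts toward the chunk
when \(\rho(l) > \mu(l)\): a *negative* autocorrelation is evidence of
alternation, not binding. The t statistic
\((\rho(l)-\mu(l))/\sigma(l)\) is referred to \(n_{subjects}-1\) degrees of
freedom — a per-subject statistic against a cross-subject null is
nonstandard, so a normal-reference fallback (`reference = "z"`) is provided.
The null is built per day, and the tested subject's own random-probe profile
is included in it (the contribution of one subject in 23 is negligible and
keeps the null identical for all subjects).

**Bootstrap correlations.** Day-wise correlations between RT variability and
learning rates report a bootstrap SD (1000 resamples of subjects) as the
error bar. The significance flag, however, uses the exact correlation t
reference (\(t = r\sqrt{(n-2)/(1-r^2)}\), df \(= n-2\)) with Bonferroni
correction over the 10 days: a one-sample t-test *of the bootstrap
distribution* is badly anti-conservative (bootstrap replicates are not
independent draws from the null), and with 23 subjects even using the
bootstrap SD as the SE of r inflates the family-wise error to roughly three
times its nominal level. The exact reference keeps the family-wise
false-positive rate at \(\alpha\) under an exchangeable null, which the test
suite verifies by simulation.

**Learning-rate model selection.** The LR test is applied per subject at
\(\alpha = 0.05\), uncorrected — the correction question only arises post
hoc, and the choice is surfaced in the fitted object. A numerically perfect
linear fit short-circuits the test (the LR statistic is meaningless at
machine-zero residuals). Accuracy is modeled as raw percent correct.

**Median split.** Values strictly above the median are "high"; the median
element itself (odd n) and ties join "low". Deterministic, documented,
arbitrary.

**Repeated-measures ANOVA.** The standard within-subject decomposition, each
effect tested against its subject-by-effect interaction, no sphericity
correction by default (a Greenhouse–Geisser flag exists). The implementation
is checked against `aov()` with `Error(subj/...)` strata to 1e-10.

## The state-space model: estimation details

The E-step is an exact scalar Kalman filter plus RTS smoother (implemented
in C++; the R-level brute-force joint-Gaussian evaluation in the test suite
verifies means, variances, lag-one covariances and log-likelihood to 1e-8).
The M-step solves the closed-form regression updates for \((A, B, F)\)
jointly from the state equation's expected sufficient statistics, and
\((D, R)\) from the output equation; the log-likelihood is non-decreasing at
every iteration, which every fit asserts implicitly through the tests.

Choices where the model is underdetermined:

- **B input.** The state update uses the *binary* previous-press one-hot
  \(Y_t\), read literally from the model definition. Predictors that never
  occur in a block (keys never pressed, error-free blocks) are dropped and
  their coefficients held at zero.
- **Missing responses.** Default `missing = "skip"`: the filter propagates
  through omitted trials without an observation update, which avoids biasing
  \(R\) downward; `missing = "mean"` reproduces mean-imputation for
  comparability.
- **Identifiability.** The state mean trades off against \(D\), so `y` is
  centered per block and \(D\) is reported as per-key deviations plus the
  block mean.
- **Initial state.** \(x_1 \sim N(0, 10\,Q_0)\), fixed (not estimated):
  a weak prior whose influence on a 256-trial block is negligible, and
  keeping it fixed preserves the EM monotonicity guarantee exactly.
- **Error timing.** \(F\) multiplies the error flag of the *previous* trial:
  an error at trial \(t\) delays the state entering trial \(t+1\).
- **Initialization.** \(A = 0.5\), \(B = 0\), \(F = 0\), \(D\) = per-key
  mean RT, \(Q = R =\) half the residual variance; convergence when the
  relative log-likelihood improvement drops below 1e-6 (default cap 200
  iterations).

## What the synthetic cohort emulates — and what it does not

No raw data accompany this design, so the package ships a generative
stand-in, `subject_config()` / `simulate_cohort()`, whose defaults define
the study conditions used throughout the tests:

- 23 subjects, 10 days, nine 256-trial blocks per day in the canonical
  order, sequence blocks cycling the printed 32-item sequence from a random
  circular offset, random blocks pseudo-random without immediate repeats.
- Baseline RT ~400 ms (between-subject SD 25 ms), with a *sequence-specific*
  linear improvement of ~9 ms/day applied to sequence blocks only, so
  random-probe RTs stay flat and the z-score isolates sequence learning.
  With motor noise ~20 ms and plan noise ~15 ms this yields \(\lambda_{RT}\)
  near 0.35 z/day.
- Plan-level AR(1) binding in sequence blocks whose coefficient follows the
  saturating ramp \(0.75\,(1 - e^{-(d-1)/2.2})\): zero on day 1,
  asymptoting by the end of the first week, mirroring where the chunk-size
  measure saturates. Random blocks are always unbound.
- Post-error slowing injected into the latent plan with geometric decay
  (factor 1/2) over 4 post-error trials, sequence blocks only, amplitude
  ramping linearly across days to ~15 ms on day 10 — the "end of training"
  delay magnitude.
- Cue-independent Bernoulli errors with the quadratic-saturating daily rate
  \(0.045 + 0.28\,((10-d)/9)^2\) (accuracy ~71% on day 1 plateauing at
  93–95% in week 2). Because the accuracy curve is exactly quadratic in day,
  the per-subject LR test selects the quadratic model for nearly all
  simulated subjects, as intended.
- Adaptive windows on the five training sequence blocks (\(\mu + \sigma\)
  of the previous block, reset to 600 ms below 200 ms or under 75%
  accuracy); censoring above the window produces the missing RTs the
  preprocessing has to handle. Late responses record the cued key with a
  missing RT; error trials press a uniformly random non-cue key.

The generator does *not* emulate: awareness-driven strategy shifts, cue- or
transition-dependent error structure, within-day fatigue or warm-up beyond
the first-cycle exclusion, eye or hand kinematics, or chunk-boundary
layout (plans are homogeneously AR(1)-coupled; the estimator's consecutive
count is therefore calibrated against *span*, not against boundary
structure). A green test suite consequently shows the estimators are
correct and calibrated *under these assumptions* — it cannot show that real
subjects satisfy them.

## Calibration of the chunk estimator

Two properties are demanded. Under the exchangeable null (all subjects
unbound), the family-wise probability of reporting a chunk at all must stay
at or below \(\alpha\); 200 cohort replicates verify this. And a *planted*
binding span must be recovered: the binding coefficient is chosen from the
closed form so that the theoretical ACF exceeds the Bonferroni-corrected
threshold exactly through lag 7 —

```{r}
nt <- 1000; ns <- 23
thr <- qt(1 - 0.05 / 31 / 2, ns - 1) / sqrt(nt)
alpha_pl <- exp(log(thr) / 7.5)
c(alpha = alpha_pl, rho7 = alpha_pl^7, rho8 = alpha_pl^8, threshold = thr)
```

— and the modal estimate over 50 simulated cohorts must be 7. The planted
subject's profile is averaged over 100 blocks so that its Monte-Carlo error
is small relative to the threshold margins; the dominant remaining noise is
the null SD estimate from 23 subjects.

At the study's own scale (224 analyzed trials per probe, motor noise
comparable to plan noise), per-subject day-10 chunk estimates are much
smaller than the asymptotic binding span because the per-lag threshold
\(t_{crit}\,\sigma(l) \approx 0.24\) is high relative to the attenuated ACF.
That is a property of the measure, not a bug: chunk size grows with
training, but its absolute value is conservative.

## Problem sizes used by the test and acceptance runs

Simulation sizes were chosen to make every Monte-Carlo comparison decisive
at 3-SE tolerances while keeping a full run in the tens of seconds: the
binding oracle at the canonical 100 × 1000 scale; chunk-null calibration
with 200 cohort replicates of 24 × 224 trials; planted-span recovery over
50 seeds; state-space recovery over 20 seeds of 25 pooled 256-trial blocks
(6400 trials per fit); and the qualitative cohort contrasts on the full
23-subject generator at days 1 and 10.

## Known limitations

- The chunk estimator cannot localize chunk boundaries or detect
  heterogeneous chunk sizes; it summarizes binding as a single span.
- The state-space model is scalar-state and linear; switching dynamics or
  per-finger states are out of scope.
- The per-subject-vs-cohort-null t reference has no exact finite-sample
  justification (hence the documented z fallback).
- Reported \(D\) absorbs the block mean; comparisons of \(D\) across blocks
  therefore mix bias and overall speed.
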