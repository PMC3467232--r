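# srtbind

Analysis toolkit for multi-day serial reaction time (SRT) sequence
learning, centered on the question of **response binding**: as a secretly
repeating 32-item cue sequence is practiced over ten daily sessions, do
individually planned keypresses become temporally coupled into larger
chunks, and which components of trial-by-trial response planning change
with learning?

The package is written for researchers analyzing (or simulating) long-format
trial tables from an eight-key bimanual SRT protocol: nine 256-trial blocks
per day, ending in one random and one sequence probe block at a fixed 600 ms
response window, to which all analyses are restricted.

## What it computes

* **Sequence-specific learning.** Probe-block z-scores
  (µ_Random − µ_Sequence)/σ_Random, and per-subject learning rates λ from
  linear vs quadratic OLS over days, selected by likelihood-ratio test
  (λ = β_lin, or β_lin + β_quad for saturating learners).
* **Post-error slowing.** The error response function (ERF): mean RT
  deviation from the block mean at lags 1–6 after each error; its lag-1
  value is the PES magnitude.
* **Chunk size from inter-trial autocorrelation.** After dropping the first
  sequence cycle, mean-imputing missing RTs, detrending and zero-meaning,
  the 31-lag ACF of each sequence probe is tested lag-by-lag against a
  cross-subject null (mean µ(l), SD σ(l) of the same day's random-probe
  ACFs) with t = (ρ(l) − µ(l))/σ(l), Bonferroni-corrected for 31
  comparisons; chunk size = number of consecutive significant lags from
  lag 1 with ρ > µ.
* **The binding toy model.** A stationary AR(1) over internal plans with
  independent execution noise, y_t = x_t + ε_t, whose ACF has the closed
  form ρ(l) = α^l σ_x²/(σ_x² + σ_E²), σ_x² = σ_P²/(1 − α²) — simulator and
  analytic oracle (`simulate_binding()`, `theoretical_acf()`).
* **A state-space model of response preparedness.** A scalar-state linear
  dynamical system in ms units,
  x_{t+1} = A·x_t + B·Y_t + F·e_t + q_t,  y_t = x_t + D·K_t + r_t,
  fitted per probe block by EM with an exact Kalman filter/RTS smoother
  (`fit_lds()`, returning a classed model object with the usual
  `print`/`summary`/`coef`/`logLik`/`fitted`/`residuals`/`predict`/
  `simulate`/`plot` methods).
* **Inference utilities** implemented and verified against base-R oracles:
  one-sample t, tie-corrected Spearman correlation, Bonferroni adjustment,
  and one-/two-way repeated-measures ANOVA.
* **A synthetic cohort generator** (`subject_config()`, `simulate_cohort()`)
  emulating the full task — adaptive response windows, censored RTs,
  day-growing plan binding, post-error slowing, quadratic-saturating
  accuracy — for calibration and testing when no raw data are available.

## Worked example

Simulate one synthetic subject through the 10-day protocol and run the main
analyses:

```r
library(srtbind)

cfg <- subject_config(subject = "S01", seed = 42)
trials <- simulate_subject(cfg)

m <- probe_metrics(trials)
m[3:6] <- round(m[3:6], 2)
m[m$day %in% c(1, 5, 10), ]
#>  subject day seq_rt_z accuracy_pct rt_sd_seq rt_sd_rand
#>      S01   1     0.26        65.23     24.82      24.34
#>      S01   5     1.72        91.02     28.48      25.48
#>      S01  10     3.16        93.75     29.10      26.96

fit_learning_rate(m$seq_rt_z, m$day)
#> Across-day learning rate
#>   model: linear (LR test p = 0.1258)
#>   lambda = 0.3465  (beta_linear = 0.3465, beta_quadratic = -)

sp <- probe_block(trials, "S01", 10, "sequence_probe")
error_response_function(sp$rt_ms, !sp$correct)
#> Error response function (16 errors)
#>  lag1  lag2  lag3  lag4  lag5  lag6
#>  7.23  2.36 11.58 -3.58 -9.53 -1.31

fit_lds_block(trials, "S01", 10)
#> Response-preparedness state-space model (EM fit)
#>   256 trials, 73 EM iterations (converged), logLik = -1186.43
#> Response-preparedness LDS parameters (ms units)
#>   A (state memory)     : 0.7989
#>   F (error correction) : 10.513 ms
#>   ...
```

Reading the output: sequence-probe responses start indistinguishable from
random probes (z ≈ 0.26) and end ~3 SDs faster; accuracy saturates in the
90s while the z-score keeps growing linearly (λ_RT ≈ 0.35 z-units/day, the
LR test finds no quadratic component). On day 10 an error slows the next
response by ~7 ms and the fitted state-space model shows strong state
memory (A ≈ 0.8) with a ~10 ms error-corrective delay — the trial-by-trial
signature of bound responses.

`run_pipeline()` orchestrates the same stages (plus chunk estimation) over
a whole cohort and writes CSV tables and a manifest;
`chunk_table(trials)` gives per-subject/day 31-lag ACFs and chunk sizes.

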