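# pitchsync

Tools for studies that link **auditory predisposition to verbal memory under
auditory–motor coupling**: psychophysics of "missing fundamental" (MF) pitch
perception, pedal-timing metrics from ergometer light-barrier recordings, and
hierarchical Bayesian regression models of recall performance — plus a
synthetic-study generator with known ground truth so the whole chain can be
validated by parameter recovery.

## The scientific problem

People differ in how they perceive the pitch of harmonic complex tones whose
fundamental is physically absent: *fundamental pitch perceivers* (FPP) hear
the (missing) periodicity frequency F0, *spectral pitch perceivers* (SPP)
hear a sounding harmonic, typically the lowest one at F_SP = n_min·F0. A
paired two-alternative test in which F0 and F_SP move in opposite directions
(with the top harmonic fixed, to suppress edge-pitch cues) yields the **pitch
perception index**

    δ_P = (n_SP − n_F0) / (n_SP + n_F0)  ∈ [−1, +1],

where n_SP and n_F0 count responses consistent with spectral and fundamental
pitch. The study design this package supports crosses that individual trait
with a 2×2 within-subject vocabulary-learning experiment (stimulation
condition: isochronous vs. self-initiated pacing while cycling × testing day:
immediate vs. 24 h recall, 40 items per test), with pedal timing summarized
as mean speed (Hz), the coefficient of variation of instantaneous speed
(CV = sd(1/d)/mean(1/d)), and the inter-beat deviation from the 1 s half-SOA
target (IBD = mean|d − SOA/2|; identically zero under self-initiated pacing).

Recall counts are modeled as Binomial(40, p) with logit(p) built from: a
subject random intercept and correlated random slopes for condition and day;
fixed condition×day and session-order effects; a penalized thin-plate spline
smooth of pitch index with one *difference smooth* per condition×day cell (a
smooth 3-way interaction), or a fully linear variant; a monotonic
(simplex-weighted) effect of the number of foreign languages; smooths of
musical training and typical sleep; and a subject-centered sleep×day effect.
Motor metrics get their own models (Gaussian with known observation SE for
speed; Gamma log-link for CV and IBD). Posteriors are summarized with
medians, 66/90/95% highest-density intervals, the probability of direction
pd ∈ [0.5, 1] (two-sided p ≈ 2(1−pd); evidence ratio ER = pd/(1−pd)),
response-scale marginal means and contrasts, finite-difference slopes,
predictor-half splits, Bayesian R² and the intra-class correlation via
posterior-predictive variance decomposition.

Everything runs on an in-package Hamiltonian Monte Carlo sampler with
analytic gradients, dual-averaging step-size adaptation and a warmup-
estimated diagonal metric; convergence is checked with rank-normalized
split-R̂ and bulk/tail effective sample sizes.

## Worked example

```r
library(pitchsync)

# 1. the MF test battery and the pitch index
battery <- build_battery(order_seed = 1)
battery
#> <test_battery> 162 pairs (324 unique sounds), order_seed = 1, ISI = 0.40 s
pitch_index(n_sp = 120, n_f0 = 42)$delta_p
#> [1] 0.4814815

# 2. a synthetic 47-subject study with known truth, motor metrics included
bundle <- gen_study(n_subjects = 47, seed = 42, n_revolutions = 300)
bundle
#> <study_bundle> 47 subjects, 188 study rows, 28294 pedal events, seed 42

# 3. fit the linear-variant memory model and summarize
res <- run_study_analysis(bundle$study_table, models = "memory_linear",
                          chains = 4, iterations = 1500, seed = 42)
res
#> <report_bundle> models: memory_linear | 4 chains x 1500 iterations, seed 42
#>   memory_linear: Bayesian R2 0.83 [0.81, 0.85], max Rhat 1.006
res$report$memory_linear$day_contrast
#> day2 - day1: median -1.217, 90% HDI [-2.245, -0.120], pd 0.961 (ER 24.6)
res$report$memory_linear$condition_contrast
#> isochronous - self_initiated: median 0.371, 90% HDI [-0.581, 1.337], pd 0.734 (ER 2.8)
res$report$memory_linear$icc
#> icc(subject_id): median 0.703, 90% HDI [0.557, 0.825], pd 1.000 (ER Inf)
```

The day contrast reads: subjects recall about 1.2 words fewer on the day
after learning than immediately after (on the 0–40 count scale), a direction
the posterior supports with pd ≈ 0.96; the condition contrast is weak and
uncertain, as generated; the ICC says roughly 70% of predictive variance is
attributable to stable subject differences. `recovery_experiment()` repeats
generate–fit–summarize cycles and tabulates bias, 90% HDI coverage and pd
sign agreement against the generating truth.

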