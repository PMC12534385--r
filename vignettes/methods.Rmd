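---
title: "Models and methods in pitchsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pitchsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchsync)
```

This vignette documents the scientific and numerical choices behind the
package: the stimulus model, the motor metrics, the Bayesian regression
engine, the synthetic-study generator, and what the validation suite does and
does not establish.

## Missing-fundamental stimuli and the pitch index

A missing-fundamental (MF) complex is a sum of consecutive harmonics
`n_min … n_min + N − 1` of a fundamental `F0` that itself carries no energy
(`n_min ≥ 2`). Its pitch is ambiguous: listeners report either the
periodicity pitch at F0 or a spectral pitch at a sounding harmonic, taken
here as `F_SP = n_min · F0` (an amplitude-weighted spectral-centroid
definition is available in `spectral_pitch()`).

Component levels follow a spectral roll-off of −5 dB per harmonic order,
referenced to the lowest sounding harmonic, plus a log-linear attenuation of
−3 dB from 1 to 3 kHz and a further −17 dB from 3 to 15.9 kHz. Two readings
of that attenuation are possible; we adopt the cumulative one (−20 dB total
at 15.9 kHz) and hold the value constant above 15.9 kHz. The level reference
(relative to the first sounding harmonic, not absolute SPL) is likewise a
package choice, since only relative levels matter for the synthesized
spectra. Component phases are all-zero sine phases: deterministic waveforms
with easily testable spectra. Tones last 0.6 s with 10 ms linear fades,
synthesized at 44.1 kHz and peak-normalized to −3 dBFS; a minimal 16-bit PCM
writer exports them.

The test battery pairs two complexes so that F0 and F_SP move in opposite
directions while the top harmonic frequency is identical in both members
(suppressing edge-pitch cues). The canonical battery presents 324 unique
sounds once, in 162 pairs. The original stimulus grid is not recoverable, so
`default_battery_design()` ships a documented grid — 9 log-spaced F0 values
(100–400 Hz) × n_min 2–7 × N 2–4 = 162 cells, each paired with a member one
harmonic order higher at `F0·m/(m+1)` (m the top order), which preserves the
top harmonic exactly and moves F_SP upward whenever F0 moves down. The grid
is configurable; the pairing invariants, checked for every pair, carry the
design. Pair order and within-pair order are a plain seeded shuffle — the
original's unstated pseudo-randomization constraints are not reproduced — and
are identical for every run with the same seed.

A response ("first/second tone higher") classifies as *fundamental* if it
matches the sign of the F0 change and *spectral* if it matches F_SP; exactly
one matches by construction. Counts enter
`δ_P = (n_SP − n_F0)/(n_SP + n_F0)`; zero classified responses is an error,
not 0/0.

## Pedal-timing metrics

Crossing times come either directly as timestamps or from 100 Hz photocell
voltage traces via upward threshold crossings with linear inter-sample
interpolation; a refractory window (default 0.25 s, about a quarter of a
revolution at the 1 Hz target) suppresses double edges, and the default
threshold is the midpoint of the trace's range. Only complete revolution
durations `d_i` between consecutive crossings are used. Mean speed is
`mean(1/d_i)`; CV is the sample (n−1) standard deviation of `1/d_i` over its
mean — the (n−1) convention is the package's choice, the source convention
being unstated. IBD is `mean|d_i − SOA/2|` under isochronous stimulation
(SOA 2 s, so a 1 s pedaling target). Under self-initiated stimulation the
sounds are triggered by the pedaling, so the deviation is *defined* as zero
rather than computed; whether a variable-SOA residual could be evaluated in
that mode is not decidable from the study description, and the definitional
reading is adopted.

## The regression engine

Three likelihoods cover the study's outcomes: binomial-logit for recall
counts out of 40; Gaussian-identity for mean speed, optionally with a known
per-observation standard error added in quadrature to the residual scale
(`Var = σ² + se²`); Gamma-log for the positive, right-skewed CV and IBD.

Design-matrix constructs:

* **Orthonormal factor coding** (`orthonormal_contrasts`): columns
  orthonormal and orthogonal to the intercept, so equal priors imply equal
  marginal priors on all pairwise level differences and effects read as
  classical main effects.
* **Penalized thin-plate smooths** (`tprs_basis`, via `mgcv::smoothCon` with
  the sum-to-zero constraint absorbed), used in mixed-model form
  (`mgcv::smooth2random`): the null-space (linear) column joins the fixed
  effects, the penalized columns become an iid coefficient block scaled by
  its own standard deviation. **Difference smooths** implement
  smooth-by-factor interactions as a shared reference smooth plus one
  deviation smooth per factor-cell, each built from (and sum-to-zero
  constrained over) its cell's observations. The cell smooths and their
  linear columns overlap softly with the reference smooth; the regularizing
  SD priors keep this identified in practice, at some cost in sampling
  efficiency.
* **Monotonic ordinal effects** (`monotonic_encoding`): effect at level x is
  `β · Σ_{i≤x} ζ_i` with simplex weights ζ (reference-softmax transform,
  Dirichlet(1) prior), 0 at the lowest level and β at the highest.
* **Grouped random effects**: non-centered, `b_j = diag(τ) L z_j` with
  half-normal(1) scales τ, an LKJ(2) prior on the correlation Cholesky L
  (canonical-partial-correlation transform), and standard-normal z.

Priors default to normal(0, 2.5) on population-level coefficients — the
package expects covariates on roughly unit scale, which the generator
produces — half-normal(1) on all SDs, and a normal intercept prior centered
on the empirical link-scale response mean (data-derived location, overridable
via `prior_set(intercept_location=)`). The full original prior specification
is not public; these are declared defaults, not reconstructions.

### Sampling and diagnostics

`sample_posterior()` runs Hamiltonian Monte Carlo on the unconstrained scale
(log-SDs, softmax simplexes, tanh partial correlations; all Jacobians
included) with analytic gradients — unit-tested against finite differences —
dual-averaging step-size adaptation targeting 0.8 acceptance, a diagonal
metric estimated from the middle warmup window, and trajectory lengths
jittered over a range to avoid resonance. Two numerical choices matter for
geometry: all non-intercept design columns are centered (decorrelating the
intercept from predictor means), and both smooth-coefficient and
group-effect blocks are non-centered (removing the scale funnels that
otherwise stall the chains when an effect is weak). Default trajectories of
20–60 leapfrog steps handle the strong posterior correlation between
between-subject covariate effects and the subject intercepts; simple models
mix well with 5–15 (the recovery experiment uses that shorter range).

Default configuration: 4 chains × 3000 iterations, half warmup, seeded per
chain from the master seed; identical configuration and seed reproduce
identical draws. Diagnostics are rank-normalized split-R̂ and bulk/tail ESS
(current standard definitions, implemented in-package); any R̂ > 1.05 raises
an explicit flag and warning. Non-finite log-posterior states are rejected
within a trajectory, and a run that ends with non-finite draws aborts.

### Posterior summaries

`hdi()` is the shortest contiguous window over the sorted draws containing
`⌈mass·n⌉` samples, ties resolved toward the lower window; tiered 66/90/95%
intervals are reported because extreme-tail intervals are numerically
unstable at practical draw counts (the finite-sample windows are therefore
only approximately nested). `pd()` is the larger of the shares of draws
above/below zero, zeros split evenly; `ER = pd/(1−pd)` with pd = 1 mapping
to `Inf`, never an error. Response-scale machinery — marginal predictions
over reference grids (group effects set to zero unless a group is named),
contrasts (labeled `pd_resp` vs `pd_link`), finite-difference slopes
(central, step 1% of the observed range, one-sided and flagged at the
support boundary), and median/mean predictor-half splits (both supported;
median is the default, and the two coincide for symmetric predictor grids) —
turns smooth effects into interpretable quantities. Bayesian R² uses the
model-implied residual variance per draw; the ICC simulates the posterior
predictive with freshly drawn vs. removed group effects, so its Monte-Carlo
estimate can be slightly negative.

## Study pipeline

`screening_filter()` excludes pseudoword scores strictly above 20 of 40
(20 is kept). `build_session_schedule()` encodes the session skeleton: 350
lead-in tones (650 Hz, 50 ms), two blocks of the same 40 items with the
second in a new seeded order, a 7-minute break, two-tone repeat cues, and
2 s SOA onset stamps in the isochronous condition;
`build_study_schedules()` allocates 80 unique items disjointly across the
two sessions. `prepare_study_table()` derives the modeling covariates:
subject-mean/centered sleep, log CV split into between- and within-subject
components, and log IBD with the isochronous values copied onto the same
subject's self-initiated rows (IBD as a subject trait); the copy rule is
re-asserted before any fit. The three motor-covariate models and the three
motor-outcome models follow the structures described in the README;
covariates that the original analysis dropped for lack of explained
variability (gender and age in the memory models, time of day) are left out
of the defaults. `run_study_analysis()` orchestrates the fits and emits a
deterministic report (fixed-effect summaries, contrasts, smooth summaries,
R², ICC, full diagnostics) plus a manifest with seeds, sizes and a content
hash. Battery designs, model specifications and generator truths serialize
to YAML (`write_battery_design_yaml()`, `write_model_spec_yaml()`,
`write_truth_yaml()`); reports export as CSV.

## The synthetic-study generator

The generator *defines the study conditions* and shares the fitting model's
linear-predictor builder (one code path, asserted by a construction test).
Defaults, chosen once from the study-scale anchors and not tuned thereafter:
47 subjects; pitch index from a moment-matched Beta on [−1, 1] with mean
0.36, SD 0.33 (left-skewed, as observed); a day-2 deficit of about −0.9
words and a session-2 gain of about +1.6 words converted to the logit scale
at the ~20% baseline recall rate (−0.14 and +0.25); a weak condition effect
(+0.07); a 3-way pitch×condition×day interaction matching the reported
linear-model coefficient (≈0.17 on the coding scale); random-effect SDs 0.7
(intercept) and 0.12 (slopes). Pedaling uses lognormal revolution durations
(positive support, multiplicative jitter): speed bias +10% over the 1 Hz
target under isochronous and +5% under self-initiated stimulation, with
dispersion 0.045 vs 0.08 — lower variability under isochronous pacing — and
about 1560 revolutions per 26-minute session. Sleep is ~N(7.2, 0.6) per
subject with 0.5 h nightly variation; languages Binomial(5, 0.5) (mean 2.5);
musical training zero-inflated Gamma. The MF observer answers spectrally
with probability `logit⁻¹(θ + 0.8·difficulty)`, θ the logit of the rescaled
pitch index and difficulty the standardized mean n_min of the pair — higher
sounding harmonics favor spectral listening. A possible real association
between pitch index and musical training is *not* built in: the generator
treats the trait as independent of the covariates, which is the conservative
choice for recovery testing.

What the generator does not emulate: item-level word difficulty, serial
position and fatigue within a session, drop-out, reporting error in sleep,
drift in pedaling over a session, or any genuine pitch–training confound.
Passing recovery tests therefore establishes that the estimation chain is
consistent and calibrated *under the assumed data-generating process*, not
that the models are correctly specified for real data.

## Validation scales and known limitations

The test suite uses deliberately scaled problem sizes: recovery runs 20
replicates of 47 subjects at 4 chains × 600 iterations with the reduced
condition/day/session model (the generating model), which keeps a replicate
under ~20 s while still yielding ≥80% nominal-coverage checks; oracle
comparisons (conjugate posterior mean, grid-search MLE) use 1500-iteration
fits; pipeline determinism tests use 8–12 subjects and a few hundred
iterations. Full-scale analyses (3000 iterations, all eight models) are what
`run_study_analysis()` defaults target.

Known limitations: the HMC sampler uses fixed-range trajectory lengths, not
dynamic termination, so very ill-conditioned posteriors may need a longer
`leapfrog_range`; difference smooths are softly identified against the
reference smooth; the published headline estimates cannot be reproduced
without the original human dataset, so the package's empirical claims are
confined to what its own tests and the acceptance script compute; and the
models are fit independently, without the cross-outcome correlation
structure of a joint multivariate fit.
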