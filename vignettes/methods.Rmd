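---
title: "Joint drift-diffusion and spectral-slope modeling of perceptual decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint drift-diffusion and spectral-slope modeling of perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In the random-dot-motion task, an observer reports the net direction of a
noisy dot field whose difficulty is controlled by coherence (the fraction of
dots moving together). Choices and reaction times in this task are well
described by the drift-diffusion model (DDM): relative evidence accumulates
at a mean rate (the *drift rate*, v) between two absorbing boundaries
separated by a distance (*boundary separation*, a), starting halfway between
them when the two directions are equiprobable, with a *non-decision time*
added for encoding and motor latency. A recurring finding in computational
psychiatry is that obsessive-compulsive (OCD) symptom scores measured
dimensionally (Padua Inventory) correlate negatively with drift rate,
specifically for easy (high-coherence) decisions, while worry scores (PSWQ)
do not — suggesting a perceptual evidence-integration deficit specific to
OCD-like symptomatology.

In parallel, EEG/MEG work has tied evidence integration to ramping spectral
power during deliberation: gamma-band power (32–100 Hz) ramps up at
posterior and lateral sites, while beta-band power (12–28 Hz) ramps down
parieto-occipitally, both more steeply for easier decisions. This package
implements the complete analysis machinery needed to ask whether the slope
of band-limited power *mediates* the symptom–drift association: if OCD
scores predict beta-slope and beta-slope predicts drift, the symptom
coefficient should attenuate once the slopes enter the drift regression.

Because no participant data ship with the package, a synthetic-data module
generates cohorts with a known ground truth, and every stage is validated by
parameter recovery rather than by reference to a stored dataset.

## Model

### Wiener first-passage-time likelihood

The simple DDM (no trial-to-trial parameter variability) admits a
closed-series likelihood for an observed (choice, RT) pair: the density of
first passage through the lower boundary at decision time $t$ is

$$ f(t \mid v, a, w) = \frac{1}{a^2}
   \exp\!\left(-v a w - \tfrac{v^2 t}{2}\right)
   f_1\!\left(\tfrac{t}{a^2}, w\right), $$

where $w$ is the relative start point (fixed at 0.5 throughout) and $f_1$
is the standard density for a unit boundary and zero drift, evaluated by
switching between its small-time and large-time series expansions with an
absolute truncation tolerance of 1e-12 (Navarro & Fuss 2009). The
upper-boundary density follows by reflection ($v \to -v$, $w \to 1-w$).
Within-trial noise SD is fixed at 1 — the usual identifiability convention.
The same code path returns the analytic gradient with respect to drift,
boundary and non-decision time; the gradient is verified against central
finite differences in the tests. RTs at or below the non-decision time get
log-density $-\infty$ by contract, so the sampler rejects rather than
errors.

### Hierarchical regression structure

For subject $s$ and condition $c$ (six coherence levels, ascending),

$$ \mathrm{drift}_{s,c} = \mathrm{drift}_c + \mathrm{drift}_s
 + \mathrm{drift}_{c,\mathrm{padua}}\,\mathrm{padua}_s
 + \mathrm{drift}_{c,\mathrm{worry}}\,\mathrm{worry}_s
 + \mathrm{drift}_{c,\gamma}\,\gamma_{s,c}
 + \mathrm{drift}_{c,\beta}\,\beta_{s,c}, $$

and the boundary is defined analogously. Symptom scores are z-scored across
subjects; the per-band aggregate-power slopes $\gamma_{s,c}, \beta_{s,c}$
are z-scored across subjects within each condition. Four variants are
supported: `behavior_only`, `symptoms`, `neural`, and `full`, dropping or
keeping the two covariate blocks. Subject deviations
$\mathrm{drift}_s \sim N(0, \sigma_{\mathrm{drift}})$ and
$\mathrm{boundary}_s \sim N(0, \sigma_{\mathrm{boundary}})$ pool partially
across subjects, and each subject has one non-decision time shared across
conditions, drawn from a group Gaussian.

A separate pair of regressions ties the slopes themselves to the symptom
scores, per band:

$$ \mathrm{slope}_{s,c} = b_{c,0} + b_{c,\mathrm{padua}}\,\mathrm{padua}_s
 + b_{c,\mathrm{worry}}\,\mathrm{worry}_s + \varepsilon_{s,c}, $$

with condition intercepts pooled hierarchically
($b_{c,0} \sim N(b_{\mu 0}, b_{\sigma 0})$).

### Priors and reparameterization

All priors are broad. Condition-level locations and every regression
coefficient are sampled on a "primed" offset-from-first scale —
$x_1 = x'_1$ and $x_c = x'_1 + x'_c$ for $c \ge 2$ — which reduces posterior
correlation between conditions; reported parameters are always the natural
ones. Primed locations and coefficients get $N(0, 20)$ priors, except the
first boundary location, $N(1, 20)$, biased positive because boundary
separation must be positive. The non-decision group mean has a $N(0.5, 1)$
prior (seconds) and its group SD a half-$N(0, 1)$; the subject-effect SDs
have half-$N(0, 20)$ priors. Reaction times are in seconds throughout —
the non-decision prior only makes sense on that scale. These priors are
dominated by the likelihood at the study's data sizes; the tests include a
recovery suite confirming calibration.

### Sampling

No Stan-family engine is assumed: the package ships its own No-U-Turn
sampler (slice variant, Hoffman & Gelman 2014) with dual-averaging
step-size adaptation and a diagonal metric adapted over expanding warmup
windows, operating on the analytic joint gradient. Positive parameters are
sampled as logs with the Jacobian included; subject effects are
non-centered; the non-decision time is mapped through a scaled logit so it
stays inside $(0, \min \mathrm{RT}_s)$ per subject, which keeps the
geometry smooth near its natural upper bound. The default configuration is
4 chains with 1,000 warmup and 3,000 retained iterations, matching the
study conventions; convergence is summarized by split R-hat (threshold
1.05) and effective sample size, and a failed threshold flags the fit
rather than aborting it so reduced-scale runs remain inspectable. The
engine itself is validated on a correlated-Gaussian target with known
moments.

## The EEG path

**Multitaper power.** Spectrograms use DPSS tapers computed from the
standard symmetric tridiagonal eigenproblem, a 250 ms window and ±8 Hz
half-bandwidth smoothing; the time-half-bandwidth product 2 yields 3
tapers. Frequencies of interest are 32–100 Hz (gamma) and 12–28 Hz (beta)
in 4 Hz steps; with a 500 Hz sampling rate the 125-sample window resolves
these exactly. Output power steps along a 50 ms grid (the slope statistic's
increment; the finer grid choice is free and documented here), and windows
that would cross the epoch edge are dropped, not zero-padded, to avoid
edge-biased baselines.

**Normalization.** Power is log-transformed and z-scored per subject,
condition, channel and frequency against the 200 ms pre-stimulus baseline,
pooling the stratum's trials and baseline time points; band power is then
the unweighted mean across the band's frequencies. Multiplicative channel
gains cancel exactly under this scheme (tested).

**Electrode weighting.** A multi-level Bayesian logistic regression
predicts trial difficulty — hard (0; coherences 0.025, 0.05) versus easy
(1; 0.45, 0.7), middle conditions excluded — from band power at all
electrodes, evaluated at each subject's median hard-trial RT snapped to the
power grid. Channel predictors are standardized before fitting; group-level
coefficients get weakly informative $N(0, 2.5)$ priors; per-subject
coefficients pool toward per-channel group means. Two open design points
were resolved as follows: subjects get hierarchical intercepts, and the
pooling SD is a *single* parameter shared across channels — with cohorts of
this size, per-channel pooling SDs are essentially unidentified and create
dozens of funnel geometries for no inferential gain. Subjects with a single
label class are dropped with a warning.

**Aggregate, slope, projection.** The whole posterior of group-level
channel coefficients weights the normalized power (intercepts excluded;
power divided by the training scale so the standardized-scale coefficients
apply), producing an aggregate time course per draw, subject, condition and
time after trial-averaging — exact, because the aggregate is linear in
power. The slope statistic is the mean of consecutive 50 ms increments
over 300–800 ms, which telescopes to $(y(800) - y(300))/10$; per-draw
slopes are reduced to marginal medians per subject and condition before
entering the regressions, matching the two-stage (approximately Bayesian)
design — a joint fit of the weighting, slopes and DDM in one model is
deliberately not attempted. The scalp projection computes, per subject,
$XY$ with each column normalized by $Y^\top_{\cdot j} Y_{\cdot j}$ — the
through-origin least-squares slope of each channel on the aggregate — then
averages over subjects and takes the median over draws. A frontal-exclusion
helper removes the 16 frontal channels (Fp1–F8) so every stage can be
re-run as an ocular-artifact robustness check.

## The synthetic-data generator

The generator realizes the exact structure the analysis assumes, with all
ground truth recorded:

* **Cohort.** Padua scores fill four pre-screening bins (0–16, 17–33,
  34–50, 51+; default 19/18/15/15 of 67). Worry scores come from a Gaussian
  copula with correlation 0.45 to Padua and a Beta(3, 1.7) marginal on the
  16–80 PSWQ range, skewed toward the upper end. The joint distribution of
  the two scores is a free choice of the generator, not an estimate of any
  sample.
* **Behavior.** Per trial, direction is a fair coin; choice and RT are
  simulated by Euler–Maruyama integration (1 ms steps, noise SD 1) with a
  Brownian-bridge correction for within-step boundary crossings, which
  removes the $O(\sqrt{dt})$ first-exit bias — without it, absorption
  probabilities are visibly off at the tested tolerances. Default truth:
  drift 0.5–4.5 increasing in coherence, boundary 1.6–1.4 mildly
  decreasing, non-decision time $N(0.35, 0.05)$ s, subject SDs 0.3 (drift)
  and 0.15 (boundary), and a planted OCD effect of −0.3 on drift in the two
  easiest conditions only — the qualitative headline pattern.
* **Band power.** Per-channel per-trial power is baseline-z noise plus a
  linear post-stimulus ramp whose slope is the product of a smooth channel
  effect map (positive posterior/lateral for gamma, negative
  parieto-occipital for beta, small opposite-sign frontal lobes) and the
  subject/condition true slope, itself drawn from the slope regression with
  planted $b_{c,\mathrm{padua}} = -0.3$ for beta and 0 for gamma. The ramp
  continues through the epoch (no post-response plateau) — a deliberate
  simplification.
* **Raw oscillations.** For end-to-end testing of the multitaper stage
  only: band-limited carriers whose squared envelope ramps at the planted
  rate, plus broadband noise.

What the generator does *not* emulate: volume conduction, eye blinks,
autocorrelated 1/f background, post-response dynamics, RT-power coupling
within trial. Passing recovery tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not robustness to real-EEG
violations of them.

## Mediation comparison

The full-versus-reduced test summarizes the *change* in a coefficient
(e.g., the OCD effect on drift) between the model with and the model
without the candidate mediators. The two fits are independent, so change
draws are formed by index-pairing after a random permutation — valid for
independent posteriors, and the construction used here in the absence of a
described alternative. Condition contrasts (easy vs hard, OCD vs worry) are
draw-wise differences summarized by medians and central 95% credible
intervals; "significant" is a 95%-probability reporting flag and never a
control-flow branch, and no multiple-testing correction is applied across
the six conditions, matching the per-condition reporting convention (a
documented caveat, not an endorsement).

## Numerical choices and edge cases

* WFPT series tolerance 1e-12 (absolute, on the normalized density); the
  small/large-time switch follows the standard term-count rule and the
  tests confirm smoothness through the switch region.
* Boundary-inclusive RT filtering: "faster than 250 ms" and "slower than
  10 s" are read as strict exclusions, so equality is retained
  (configurable). Incorrect-trial RTs stay in the likelihood (both
  boundaries are modeled); the correct-trials-only restriction applies to
  descriptive summaries alone. The filter runs once, upstream of both the
  behavioral and EEG analyses.
* Sample SDs use the n−1 denominator everywhere.
* Non-absorbed simulated trials (10 s cap) are flagged censored; the
  generator assigns them the cap RT and a random choice — at the default
  truth this affects a vanishing fraction of hard trials.
* Degenerate inputs error early and name the offender: zero-variance
  covariates, zero baseline SD (with the stratum), missing grid points,
  channel mismatches, single-class subjects (dropped with a warning).
* Seeds: every stage seed is derived from one master seed; equal
  configuration implies byte-identical results.

## Problem sizes

The full study conditions are 67 subjects × 720 trials. The package's own
test suite exercises the machinery at reduced sizes chosen to keep the
default run fast while leaving each statistical property detectable: e.g.,
recovery over 20 replicate cohorts of 8 subjects × 16 trials/condition,
planted-coefficient recovery at 40–60 subjects, and a 12-subject ×
40-trials/condition cohort for the full-model convergence check, which the
acceptance script runs at the full 4 × (1,000 + 3,000) MCMC configuration.
The planted-contrast replication count in the test suite (3) is smaller
than ideal (10); the property is inherently about a 40–60-subject design,
so the replicates are few but full-sized.

## Known limitations

* The logistic weighting stage reports group-level coefficients only; the
  per-subject coefficient draws are integrated over, not stored.
* The two-stage design (weights → slopes → regressions) propagates slope
  point summaries (marginal medians), not full slope posteriors, into the
  drift regression — uncertainty in the neural covariates is understated,
  exactly as in the two-stage convention it reproduces.
* The sampler uses a diagonal metric; strongly correlated posteriors
  (e.g., drift–boundary trade-offs at very low trial counts) mix more
  slowly than they would under a dense metric.
* HDF5 interchange is not provided; tensors live in memory with CSV
  import/export for tables.
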