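---
title: "Methods: circadian function statistics and hierarchical sleep models"
author: "cfikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian function statistics and hierarchical sleep models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cfikit` couples two analyses that are usually run separately: scoring of
epoch-level wrist actigraphy into non-parametric circadian rhythm statistics
and the composite circadian function index (CFI), and Bayesian hierarchical
modelling of population-level sleep quotas across cultures. This vignette
records the modelling assumptions, the defaults and why they were chosen,
the numerical edge cases, and what the bundled simulators do and do not
emulate.

# Non-parametric circadian rhythm analysis

## Binning

IS and IV are computed on day-aligned binned series. The default is hourly
bins (`binsPerDay = 24`), the convention in the non-parametric actigraphy
literature; `binRecording()` accepts any divisor of the epochs-per-day, down
to raw epoch resolution, because source studies differ and the choice is not
always reported. Partial leading and trailing days are trimmed before
binning, with the day boundary at the local midnight of the recording's
start time; the formulas assume complete balanced days, and mixing partial
days into the bin-of-day means would bias IS.

Missing data policy: a bin whose epochs are 50% or more missing is treated
as missing; with the default `impute = "none"` any missing bin is an error
(named by day and bin-of-day), and `impute = "profile"` substitutes the
bin-of-day mean across days with a logged warning. Recordings whose overall
missing fraction exceeds `maxMissingFrac` (default 0.2) are rejected
outright — imputing a fifth of a week of data would manufacture stability
that is not in the signal.

## The statistics and their edge cases

IS is the ratio of the variance of the average 24-h profile to the total
variance; it is undefined (0/0) for a constant series, which is an error
rather than a silent 0 or 1. IV is the normalized mean squared successive
difference, computed across day boundaries in temporal order. It is near 0
for a smooth sinusoid, near 2 for white noise, and can legitimately exceed 2
for anti-correlated series (a strict alternation attains 4); the composite
therefore clips the inverted value, below.

M10 and L5 are computed on the average 24-h profile with circular
wrap-around, scanning every window start; ties take the earliest start.
Window widths must be whole numbers of bins (10/24 and 5/24 of a day), which
every multiple of 24 bins satisfies. RA = (M10 − L5)/(M10 + L5), with
RA = 0 by convention for an all-zero profile — a flat zero signal has no
amplitude to report. Negative activity is an error at this stage; counts
cannot be negative, so a negative value indicates an upstream bug, not a
dim rhythm.

## The composite index

IV is inverted and normalized as `clip(1 − IV/2, 0, 1)`, mapping a perfect
sinusoid (IV ≈ 0) to 1 and noise-level fragmentation (IV ≥ 2) to 0, and

CFI = (IS + IVinv + RA) / 3,

exactly the arithmetic mean, so CFI inherits the [0, 1] range, with 0
meaning absence of circadian rhythmicity and 1 a robust rhythm. The
descriptions of this inversion in the source literature are not perfectly
consistent (one reading has higher inverted values meaning *more*
fragmentation); the form implemented here is the one under which the
composite's stated anchors — noise at 0, perfect sinusoid at 1 — hold.

`npcra()` refuses recordings shorter than six complete days by default,
reflecting the suggested minimum of six consecutive nights for stable
NPCRA statistics; `allowShort = TRUE` downgrades the refusal to a warning
for exploratory use.

# The actigraphy simulator

`simulateRecording()` generates a rectified cosine with mesor, amplitude and
acrophase (counts and hours), plus three separately controllable degradation
axes chosen to map one-to-one onto the three CFI components:

- **day-to-day phase jitter** (`phaseJitterSdHours`): each day's acrophase
  is perturbed by Gaussian noise; misaligned days depress IS specifically;
- **fragmentation** (`fragmentationRate`): a two-state process toggles, with
  the given per-epoch probability, between scaled-up (×1.35) and scaled-down
  (×0.65) activity, creating the hour-scale bursts and lulls that raise IV;
- **nocturnal floor** (`nightFloor`): counts added inside the nocturnal
  half-cycle, raising L5 and depressing RA.

Additive Gaussian noise (`noiseSd`) is rectified at zero, since counts are
non-negative. Everything is deterministic given `seed`. The fragmentation
factors 1.35/0.65 are deliberately mild: strong multiplicative switches at
low toggle rates create day-scale structure that destroys IS, which belongs
to the jitter axis, not the fragmentation axis.

## Cohort presets and their calibration

`groupPreset()` defines per-subject parameter distributions for a
*non-industrial* preset (stabler, higher-contrast rhythms) and an
*industrial* preset (more jitter, fragmentation, noise and nocturnal
activity). The hyper-parameters were calibrated once by simulation through
the package's own `npcra()` pipeline so that default cohorts reproduce the
descriptive moments the package targets — non-industrial mean CFI ≈ 0.70,
industrial mean ≈ 0.63 with sd ≈ 0.07 — and then frozen; they are
calibration constants, not tuning knobs. The published non-industrial
spread ("s.d. = 0.01" alongside a 0.44–0.93 range) is arithmetically
impossible, so the non-industrial preset carries a realistic spread
(≈ 0.06–0.08) instead.

What the simulator does **not** emulate: seasonality and photoperiod
(latitude enters the study tables but not the activity generator),
light/temperature channels, naps and split sleep, weekday/weekend structure,
and device-specific count transfer functions. Passing calibration tests
therefore shows the pipeline recovers the moments of *this* generative
family, not that field recordings from any device will score identically.

# Hierarchical sleep models

## Structure and priors

The population-level model is Gaussian on per-study mean outcomes with fixed
effects for society scale (industrial is the reference level), z-scored mean
age and z-scored % male, and a country random intercept; the subject-level
CFI model has fixed effects only (society scale, z-scored age, a male
indicator). Intercept priors are informative and outcome-specific —
N(8, 1) h for duration, N(85, 10) for efficiency, N(0.58, 0.1) for CFI —
reflecting consensus reference values for healthy adult sleep and previously
observed CFI ranges. Slopes get N(0, 2·sd(y)) and the group-level and
residual sds half-N(0, 2·sd(y)): weakly informative, dominated by even a
54-row table.

Covariate scaling deserves a flag: age and % male are z-scored before
fitting because coefficient magnitudes of a few tenths of an hour are
implausible per-year or per-percentage-point and consistent with
standardized predictors. This is an assumption about how such tables are
conventionally fitted, recorded here and echoed in parameter names
(`age_z`, `pct_male_z`).

The Gaussian likelihood is retained for the bounded outcomes (efficiency %,
CFI in [0, 1]) to keep the model in its conventional form; posterior
predictive draws can fall outside the bounds and this is a reportable
diagnostic, not an error. The study-table simulator correspondingly clips
outcomes into their physical ranges, affecting a negligible tail mass at the
default truths.

## Computation

Posteriors are drawn with JAGS: 4 chains, 4000 post-warmup iterations each
(16 000 draws), 2000 warmup, fixed seed per chain derived from the
user-supplied seed. The JAGS `glm` module is loaded so the linear-model
block is updated jointly; with single-site Gibbs the society contrast and
the country intercepts — which are strongly coupled when society scale is
constant within country — mix an order of magnitude more slowly, and the
group-level sd can stall near zero in small tables. Convergence is enforced,
not reported: any monitored parameter with split-R̂ above 1.01 aborts the
fit with the offending parameter named. There are no divergent-transition
diagnostics because the sampler is not Hamiltonian.

Summaries are equal-tailed percentile intervals at 89% and 95% (not HDIs;
for near-symmetric marginals the difference is cosmetic, and percentile
intervals are permutation-invariant and quantile-exact), the posterior mean
and sd, the percentage of draws below zero, and a directional support label:
none (≤ 85), weak (85–90], support (90–95], strong (> 95), right-closed so
that exactly 95% is "support" and anything above is "strong".

## Model comparison

`compareModels()` scores candidate fixed-effect subsets by leave-one-out
expected log predictive density. The default is importance sampling on the
full-posterior pointwise log-likelihoods with weights truncated at
w̄·√S (the truncation bounds the estimator's variance at modest bias);
`method = "exact"` refits per left-out row, feasible at meta-table sizes,
and predicts held-out rows through their country's posterior intercept (or
a fresh draw from N(0, τ) for an unseen country). Differences are reported
with standard errors computed from the pointwise elpd differences;
antisymmetry is structural.

## Spatial diagnostic

`moransI()` screens values (typically country random-intercept posterior
means) for spatial autocorrelation: inverse great-circle (haversine)
distance weights, zero diagonal, row-standardized by default, with pairwise
distances floored at 1 km so coincident coordinates cannot yield infinite
weights. The null expectation is −1/(n−1) exactly; inference is a two-sided
permutation test (default 9999 seeded permutations), whose p-value lives on
the grid (k+1)/(M+1) and is therefore never exactly zero. The weight scheme
is a design choice — none is canonical for irregular country-level data —
and is exposed in the configuration.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design: 54-row
(duration) and 38-row (efficiency) tables for recovery, 20 replicate tables
for interval-coverage checks with 2-chain scaled-down MCMC, cohorts of 93
and 200 subjects at 7 days × 1-min epochs for calibration, and ≤ 15 units
for the Moran oracles. Every stochastic step — simulation, MCMC, permutation
— takes an explicit seed, and seeded runs are bit-reproducible; generator
functions restore the caller's RNG state.

# Known limitations

- Single-table parameter recovery at the published truths has substantial
  seed-to-seed scatter (the posterior sd of the society coefficient is
  ≈ 0.3–0.4 h at 54 studies with society nested in countries); recovery
  checks are therefore stated within posterior-sd tolerances, and coverage
  is assessed across replicates rather than from one table.
- The CFI model treats subject sex as a binary indicator; tables that only
  report % male cannot be used at the subject level.
- No meta-analytic weighting by within-study variance: study means enter
  unweighted, with the country random effect absorbing between-study
  heterogeneity, mirroring the convention for this kind of meta-table.
- The exact covariate coding used by published fits of comparable tables is
  rarely stated; z-scoring is an assumption, and coefficients for age and
  % male are only comparable across parameterizations up to that scaling.
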