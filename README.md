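# cfikit

Circadian function and cross-cultural sleep modelling in R.

Sleep researchers comparing populations face two recurring tasks. First,
turning raw wrist-actigraphy time series into interpretable circadian
statistics: interdaily stability (IS), intradaily variability (IV), relative
amplitude (RA via the M10/L5 windows), and the composite **circadian function
index (CFI)**, which summarizes rhythm stability, fragmentation and amplitude
on a single 0–1 scale. Second, modelling population-level sleep quotas
(duration in hours, efficiency in percent) across heterogeneous studies with
a **Bayesian hierarchical model** that respects the nesting of studies within
countries and reports evidence as posterior probabilities rather than
p-values. `cfikit` implements both, plus the supporting cast: a permutation
Moran's *I* diagnostic for spatial autocorrelation in country-level random
intercepts, leave-one-out model comparison, and seed-deterministic simulators
for actigraphy cohorts and study meta-tables so every stage can be exercised
without access-restricted data.

## The statistics

For an activity series binned into *p* bins/day over *d* complete days
(*n = pd* values, grand mean x̄, bin-of-day means x̄ₕ):

- **IS** = [Σₕ (x̄ₕ − x̄)² / p] ⁄ [Σᵢ (xᵢ − x̄)² / n] — 1 for a perfectly
  repeating daily profile, near 0 for noise.
- **IV** = [Σᵢ (xᵢ − xᵢ₋₁)² / (n−1)] ⁄ [Σᵢ (xᵢ − x̄)² / n] — near 0 for a
  smooth sinusoid, near 2 for white noise, above 2 for anti-correlated
  alternation.
- **RA** = (M10 − L5)/(M10 + L5), where M10 and L5 are the largest 10-h and
  smallest 5-h circular window means of the average 24-h profile.
- **CFI** = (IS + clip(1 − IV/2, 0, 1) + RA) / 3.

The population-level sleep model is

```
y_j = β₀ + β_s·I(non-industrial_j) + β_a·z(age_j) + β_m·z(%male_j) + u_c(j) + ε_j,
u_c ~ N(0, τ),  ε_j ~ N(0, σ)
```

with informative intercept priors — N(8, 1) h for duration, N(85, 10) for
efficiency, N(0.58, 0.1) for the subject-level CFI model — and weakly
informative N(0, 2·sd(y)) slope and half-normal scale priors. Posteriors are
summarized with dual 89%/95% equal-tailed credible intervals, the percentage
of draws in the predicted (negative) direction, and the support bands
weak (85–90%], support (90–95%], strong (>95%).

## Worked example

```r
library(cfikit)

## simulate one week of 1-min actigraphy and score it
rec <- simulateRecording(mesor = 40, amplitude = 35, noiseSd = 18,
                         phaseJitterSdHours = 0.8, fragmentationRate = 0.003,
                         nightFloor = 4, days = 7, seed = 7, subjectId = "demo")
npcra(rec)
#> NPCRAResult 'demo' (7 days)
#>   IS = 0.667  IV = 0.198 (inv-norm 0.901)  RA = 0.578
#>   M10 = 63.6 @ 08:00  L5 = 17.0 @ 23:00
#>   CFI = 0.715
```

IS of 0.67 says about two-thirds of the variance lies in the repeating daily
profile; IV of 0.20 is far below the noise level of 2, so hour-to-hour
fragmentation is mild; RA of 0.58 reflects the day–night contrast after the
nocturnal floor; averaging IS, inverted-normalized IV and RA gives CFI 0.72 —
a reasonably robust rhythm.

```r
## a 54-study meta-table from the generative model, then the duration fit
tab <- simulateStudyTable(seed = 2026)       # default published-mean truths
fit <- fitSleepModel(tab, "duration", seed = 2027)
posteriorSummary(fit)[2, c("parameter", "estimate", "se", "pct_negative", "support")]
#>                      parameter estimate    se pct_negative support
#> society_scale_non_industrial    -0.679 0.303         98.6  strong

moranOnRanef(fit, seed = 2028)
#> Moran's I: -0.0473 (null expectation -0.0500), p = 0.9542
#>   21 units, weights: inverse haversine distance, row-standardized, 9999 permutations
```

The simulated truth for the society-scale coefficient is −0.75 h; the fit
recovers −0.68 ± 0.30 with 98.6% of draws negative ("strong" support), and
the Moran screen finds no spatial clustering in the country intercepts
(p ≈ 0.95), as expected when geography played no role in the generative
model.

A command-line wrapper over the same functions is installed at
`system.file("cli", "cfikit", package = "cfikit")` with subcommands
`simulate-actigraphy`, `simulate-studies`, `npcra`, `fit`, `moran` and
`report`.

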